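# STRING-dialect network construction: cutoff semantics, duplicate
# collapsing, isolated-node removal, induced subgraphs, round-trips.

write_edge_file <- function(df, path = withr::local_tempfile(
                              fileext = ".tsv",
                              .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

test_that("confidence cutoff is inclusive and reversed duplicates collapse", {
  f <- write_edge_file(data.frame(
    protein1 = c("A", "A", "A"), protein2 = c("B", "C", "D"),
    combined_score = c(950, 850, 900)))
  net <- read_string_edges(f, min_score = 900)
  expect_equal(n_edges(net), 2L)
  expect_setequal(net$edges$to, c("B", "D"))

  f2 <- write_edge_file(data.frame(
    protein1 = c("A", "B"), protein2 = c("B", "A"),
    combined_score = c(950, 960)))
  net2 <- read_string_edges(f2, min_score = 900)
  expect_equal(n_edges(net2), 1L)
  expect_equal(net2$edges$score, 960L)
})

test_that("0-1 scores scale, self-loops drop, malformed input errors", {
  f <- write_edge_file(data.frame(
    protein1 = c("A", "B"), protein2 = c("B", "C"),
    combined_score = c(0.95, 0.40)))
  net <- read_string_edges(f, min_score = 900)
  expect_equal(net$edges$score, 950L)

  expect_warning(
    net2 <- ppi_network(data.frame(from = c("A", "B"), to = c("A", "C"),
                                   score = c(950L, 930L))),
    "self-loop")
  expect_equal(n_edges(net2), 1L)

  f3 <- write_edge_file(data.frame(
    protein1 = c("A", "B"), protein2 = c("B", "C"),
    combined_score = c("950", "9x0")))
  expect_error(read_string_edges(f3), "line 2")

  f4 <- write_edge_file(data.frame(p1 = "A", p2 = "B", score = 900))
  expect_error(read_string_edges(f4), "protein1")
})

test_that("drop_isolated leaves only degree >= 1 nodes", {
  net <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                     nodes = c("A", "B", "C", "LONER"))
  kept <- drop_isolated(net)
  expect_setequal(kept$nodes, c("A", "B", "C"))
  expect_identical(attr(kept, "removed"), "LONER")
  empty <- drop_isolated(ppi_network(nodes = c("X", "Y")))
  expect_length(empty$nodes, 0L)
})

test_that("induced subgraph equals brute-force edge filtering", {
  tri <- ppi_network(data.frame(from = c("A", "A", "B"),
                                to = c("B", "C", "C")))
  ab <- induced_subgraph(tri, c("A", "B"))
  expect_identical(ab$nodes, c("A", "B"))
  expect_equal(n_edges(ab), 1L)
  expect_identical(induced_subgraph(tri, tri$nodes)$edges, tri$edges)

  withr::with_seed(21, {
    for (rep in 1:5) {
      net <- er_net(12, 0.3, seed = sample.int(1e6, 1))
      keep <- sample(net$nodes, 6)
      sub <- induced_subgraph(net, keep)
      manual <- net$edges[net$edges$from %in% keep &
                            net$edges$to %in% keep, ]
      rownames(manual) <- NULL
      expect_identical(sub$edges, manual)
      # composition: inducing on A then B equals inducing on A intersect B
      other <- sample(net$nodes, 8)
      expect_identical(
        induced_subgraph(induced_subgraph(net, keep), other)$edges,
        induced_subgraph(net, intersect(keep, other))$edges)
    }
  })
})

test_that("edge lists round-trip bit-identically and ignore row order", {
  net <- er_net(15, 0.3, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_string_edges(net, f1)
  reread <- read_string_edges(f1, min_score = 0)
  expect_identical(reread$edges, net$edges)
  write_string_edges(reread, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  # shuffled input rows give the same network
  df <- utils::read.delim(f1)
  shuffled <- write_edge_file(df[rev(seq_len(nrow(df))), ])
  expect_identical(read_string_edges(shuffled, min_score = 0)$edges,
                   net$edges)
})
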