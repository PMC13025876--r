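# Degree, betweenness and closeness centralities, and the iterative
# median-threshold screen.

test_that("centralities reproduce hand-computed values on named graphs", {
  star <- star_net(4)
  expect_equal(degree_centrality(star)[["HUB"]], 4)
  expect_equal(unname(degree_centrality(star)[paste0("LEAF", 1:4)]),
               rep(1, 4))
  # all C(4,2) leaf pairs route through the hub
  expect_equal(betweenness_centrality(star)[["HUB"]], 6)
  expect_equal(sum(betweenness_centrality(star)) , 6)

  k3 <- complete_net(3)
  expect_equal(unname(degree_centrality(k3)), rep(2, 3))
  expect_equal(unname(betweenness_centrality(k3)), rep(0, 3))
  expect_equal(unname(closeness_centrality(k3)), rep(1, 3))

  p3 <- path_net(c("A", "B", "C"))
  bc <- betweenness_centrality(p3)
  expect_equal(bc[["B"]], 1)
  expect_equal(bc[["A"]], 0)
  cc <- closeness_centrality(p3)
  expect_equal(cc[["B"]], 1)
  expect_equal(cc[["A"]], 2 / 3)

  # per-component closeness: two disjoint edges all score 1
  two <- ppi_network(data.frame(from = c("A", "C"), to = c("B", "D")))
  expect_equal(unname(closeness_centrality(two)), rep(1, 4))
  # isolated node scores 0
  iso <- ppi_network(data.frame(from = "A", to = "B"), nodes = "LONE")
  expect_equal(closeness_centrality(iso)[["LONE"]], 0)
})

test_that("centralities match the path-enumeration oracle exhaustively", {
  for (bits in seq_len(2^6) - 1L) {
    net <- graph_from_bits(4L, bits)
    got <- centrality_table(net)
    want <- oracle_centralities(net)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("centralities match oracles on random graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(31, {
    for (rep in 1:10) {
      net <- er_net(sample(5:7, 1), runif(1, 0.2, 0.7),
                    seed = sample.int(1e6, 1))
      expect_equal(centrality_table(net), oracle_centralities(net),
                   tolerance = 1e-12)
    }
    for (rep in 1:5) {
      net <- er_net(sample(15:30, 1), runif(1, 0.08, 0.3),
                    seed = sample.int(1e6, 1))
      g <- net_to_igraph(net)
      expect_equal(unname(betweenness_centrality(net)),
                   unname(igraph::betweenness(g)), tolerance = 1e-9)
      expect_equal(unname(degree_centrality(net)),
                   unname(igraph::degree(g)))
    }
  })
})

test_that("median screen keeps the star hub and records its thresholds", {
  tr <- median_screen(star_net(4), rounds = 1)
  expect_identical(tr$final$symbols, "HUB")
  r1 <- tr$rounds[[1]]
  expect_equal(r1$population, 5L)
  expect_equal(r1$median_DC, 1)
  expect_equal(r1$median_BC, 0)
  expect_equal(r1$median_CC, 4 / 7, tolerance = 1e-12)
})

test_that("vertex-transitive graphs leave no survivors, with a warning", {
  expect_warning(tr <- median_screen(cycle_net(6), rounds = 2),
                 "no survivors")
  expect_length(tr$final$symbols, 0L)
  expect_length(tr$rounds, 1L)
})

test_that("survivor sets nest strictly and screening ignores labels", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      net <- er_net(40, 0.12, seed = sample.int(1e6, 1))
      net <- drop_isolated(net)
      tr <- suppressWarnings(median_screen(net, rounds = 3))
      pops <- c(length(net$nodes),
                vapply(tr$rounds, function(r) length(r$survivors),
                       integer(1)))
      expect_true(all(diff(pops) < 0) ||
                    pops[length(pops)] == 0 && all(diff(pops) <= 0))
      for (r in seq_along(tr$rounds)[-1]) {
        expect_true(all(tr$rounds[[r]]$survivors$symbols %in%
                          tr$rounds[[r - 1]]$survivors$symbols))
      }
      # relabeling invariance
      rl <- relabel_net(net, seed = rep)
      tr2 <- suppressWarnings(median_screen(rl$net, rounds = 3))
      expect_identical(sort(unname(rl$map[tr$final$symbols])),
                       tr2$final$symbols)
    }
  })
  expect_error(median_screen(ppi_network(nodes = "A")), "2 connected")
})

test_that("screening trace serialises the applied thresholds", {
  tr <- median_screen(star_net(6), rounds = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_screening_trace(tr, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$rounds$median_DC, 1)
  expect_identical(parsed$final, "HUB")
})
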