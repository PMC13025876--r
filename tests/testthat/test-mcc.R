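# Maximal clique enumeration (Bron-Kerbosch) and maximal clique
# centrality scoring with exact factorial arithmetic.

test_that("maximal cliques are found on canonical graphs", {
  expect_identical(maximal_cliques(complete_net(4)),
                   list(sprintf("K%02d", 1:4)))
  p3 <- path_net(c("A", "B", "C"))
  expect_identical(maximal_cliques(p3), list(c("A", "B"), c("B", "C")))
  iso <- ppi_network(nodes = c("X", "Y"))
  expect_identical(maximal_cliques(iso), list("X", "Y"))
})

test_that("clique enumeration matches subset enumeration and igraph", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      net <- er_net(12, runif(1, 0.3, 0.6), seed = sample.int(1e6, 1))
      mine <- maximal_cliques(net)
      expect_identical(mine, oracle_max_cliques(net))
      if (requireNamespace("igraph", quietly = TRUE)) {
        ig <- igraph::max_cliques(net_to_igraph(net), min = 1)
        ig <- lapply(ig, function(cl) sort(names(cl)))
        key <- vapply(ig, paste, character(1), collapse = "\r")
        expect_identical(mine, ig[order(key, method = "radix")])
      }
    }
  })
})

test_that("MCC scores follow the factorial formula", {
  expect_equal(mcc_scores(complete_net(3))$MCC, rep(2, 3))
  expect_equal(mcc_scores(complete_net(4))$MCC, rep(6, 4))
  p3 <- mcc_scores(path_net(c("A", "B", "C")))
  expect_equal(p3$MCC[p3$node == "B"], 2)
  expect_equal(p3$MCC[p3$node %in% c("A", "C")], c(1, 1))
  expect_equal(p3$clique_count[p3$node == "B"], 2L)
  # isolated nodes score (1-1)! = 1 via their singleton maximal clique
  iso <- mcc_scores(ppi_network(data.frame(from = "A", to = "B"),
                                nodes = "LONE"))
  expect_equal(iso$MCC[iso$node == "LONE"], 1)
})

test_that("MCC is exact beyond double factorial resolution", {
  # a 25-clique scores 24! per member; frozen digits verified by exact
  # integer arithmetic (24! = 620448401733239439360000)
  k25 <- complete_net(25)
  tab <- mcc_scores(k25)
  expect_identical(unique(tab$MCC_exact), "620448401733239439360000")
  expect_equal(unique(tab$clique_count), 1L)
})

test_that("clique-count bookkeeping and relabeling invariance hold", {
  withr::with_seed(81, {
    for (rep in 1:5) {
      net <- er_net(10, 0.4, seed = sample.int(1e6, 1))
      tab <- mcc_scores(net)
      cliques <- maximal_cliques(net)
      expect_equal(sum(tab$clique_count),
                   sum(lengths(cliques)))
      rl <- relabel_net(net, seed = rep)
      tab2 <- mcc_scores(rl$net)
      inv <- stats::setNames(names(rl$map), rl$map)
      expect_equal(tab$MCC[match(inv[tab2$node], tab$node)], tab2$MCC)
    }
  })
})

test_that("top-k selection honours the tie policy", {
  # scores A:6, B:2, C:2, D:1 via K4 + two pendant triangles... simpler:
  # build the table directly through a crafted graph
  net <- ppi_network(data.frame(
    from = c("A", "A", "A", "B", "C", "D"),
    to = c("B", "C", "D", "C", "D", "E")))
  tab <- mcc_scores(net)
  top <- mcc_top(tab, k = 2)
  expect_true(all(c("A") %in% top$symbols))
  # boundary ties are all included by default
  scores <- stats::setNames(tab$MCC, tab$node)
  kth <- sort(scores, decreasing = TRUE)[2]
  expect_setequal(top$symbols, tab$node[tab$MCC >= kth])
  trunc <- mcc_top(tab, k = 2, ties = "truncate")
  expect_length(trunc$symbols, 2L)
  expect_warning(all_nodes <- mcc_top(tab, k = 99), "exceeds node count")
  expect_setequal(all_nodes$symbols, net$nodes)
})
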