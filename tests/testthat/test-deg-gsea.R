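# Differential expression (Welch on log2(x+1)) and preranked GSEA.

test_that("identical groups give zero log2FC and no flags", {
  withr::with_seed(121, {
    half <- matrix(rexp(50 * 4, 0.1), nrow = 50,
                   dimnames = list(sprintf("G%02d", 1:50), NULL))
    mat <- cbind(half, half)
    colnames(mat) <- c(sprintf("A%d", 1:4), sprintf("B%d", 1:4))
    grp <- stats::setNames(rep(c("A", "B"), each = 4), colnames(mat))
    d <- differential_expression(mat, grp, alpha = 0.05)
    expect_equal(d$log2FC, rep(0, 50))
    expect_true(all(d$flag == "ns"))
  })
})

test_that("noiseless fold change follows the +1 offset closed form", {
  mat <- matrix(rep(c(16, 4), each = 3), nrow = 1, byrow = TRUE,
                dimnames = list("G1", sprintf("S%d", 1:6)))
  grp <- stats::setNames(rep(c("A", "B"), each = 3), colnames(mat))
  expect_warning(d <- differential_expression(mat, grp, alpha = 0.05),
                 "zero variance")
  expect_equal(d$log2FC, log2(17 / 5), tolerance = 1e-12)
  expect_true(is.na(d$p))
  expect_identical(d$flag, "ns")
})

test_that("welch statistics agree with stats::t.test per gene", {
  withr::with_seed(131, {
    mat <- matrix(rexp(20 * 12, 0.05), nrow = 20,
                  dimnames = list(sprintf("G%02d", 1:20),
                                  sprintf("S%02d", 1:12)))
    grp <- stats::setNames(rep(c("A", "B"), each = 6), colnames(mat))
    d <- differential_expression(mat, grp, alpha = 0.05)
    x <- log2(mat + 1)
    for (i in c(1, 7, 20)) {
      tt <- stats::t.test(x[i, 1:6], x[i, 7:12])
      expect_equal(d$p[i], tt$p.value, tolerance = 1e-12)
      expect_equal(d$t[i], unname(tt$statistic), tolerance = 1e-12)
    }
  })
})

test_that("planted DE genes are recovered at the stated design", {
  ex <- make_expression(1000, 20, 50, effect_log2 = 2, sigma = 0.5,
                        seed = 141)
  d <- differential_expression(ex$mat, ex$groups, alpha = 0.01)
  flagged <- d$gene[d$flag != "ns"]
  expect_gte(sum(ex$truth$de_genes %in% flagged), 45L)
  expect_lte(sum(!(flagged %in% ex$truth$de_genes)), 5L)
  expect_true(all(d$gene[d$flag == "up"] %in%
                    d$gene[d$log2FC > 1 & d$p < 0.01]))
})

test_that("gene ranking is descending with lexicographic ties", {
  deg <- data.frame(gene = c("A", "B", "C"), log2FC = c(2, -1, 0.5))
  expect_identical(names(rank_genes(deg)), c("A", "C", "B"))
  ties <- data.frame(gene = c("C", "A", "B"), log2FC = c(1, 1, 1))
  expect_identical(names(rank_genes(ties)), c("A", "B", "C"))
  rev <- data.frame(gene = c("A", "B", "C"), log2FC = c(-2, 1, -0.5))
  expect_identical(names(rank_genes(rev)),
                   rev(names(rank_genes(
                     transform(rev, log2FC = -log2FC)))))
})

test_that("enrichment score reproduces hand computations", {
  # weight 0 with every member at the head of the list peaks at 1
  rk <- stats::setNames(c(5, 4, 3, 2, 1), sprintf("X%d", 1:5))
  expect_equal(enrichment_score(rk, c("X1", "X2"), weight = 0)$ES, 1)
  # four-gene worked example: running sum 0.75, 0.25, 0.5, 0
  rk4 <- stats::setNames(c(3, 2, 1, -1), sprintf("g%d", 1:4))
  es <- enrichment_score(rk4, c("g1", "g3"), weight = 1)
  expect_equal(es$running, c(0.75, 0.25, 0.5, 0), tolerance = 1e-12)
  expect_equal(es$ES, 0.75)
  expect_identical(es$leading_edge$symbols, "G1")
  expect_error(enrichment_score(rk4, "nope"), "no genes")
})

test_that("ES matches the independent walk oracle and its invariances", {
  withr::with_seed(151, {
    for (rep in 1:10) {
      N <- sample(20:200, 1)
      rk <- sort(rnorm(N), decreasing = TRUE)
      names(rk) <- sprintf("G%03d", sample.int(999, N))
      members <- sample(names(rk), sample(3:15, 1))
      w <- sample(c(0, 1, 1.5), 1)
      es <- enrichment_score(rk, members, weight = w)$ES
      expect_equal(es, oracle_es(rk, members, weight = w),
                   tolerance = 1e-12)
      # invariant to uniform positive scaling of the metric
      expect_equal(enrichment_score(rk * 7, members, weight = w)$ES, es,
                   tolerance = 1e-12)
      # weight 0: reversing the list negates ES
      es0 <- enrichment_score(rk, members, weight = 0)$ES
      flipped <- stats::setNames(rev(rk), rev(names(rk)))
      expect_equal(enrichment_score(flipped, members, weight = 0)$ES,
                   -es0, tolerance = 1e-12)
    }
  })
})

test_that("ES agrees with fgsea on a shared instance", {
  skip_if_not_installed("fgsea")
  withr::with_seed(161, {
    rk <- sort(rnorm(300), decreasing = TRUE)
    names(rk) <- sprintf("G%04d", sample.int(9999, 300))
    sets <- list(S1 = sample(names(rk), 20), S2 = sample(names(rk), 40))
    fg <- suppressWarnings(
      fgsea::fgsea(sets, rk, nperm = 100, gseaParam = 1))
    for (nm in names(sets)) {
      expect_equal(enrichment_score(rk, sets[[nm]], weight = 1)$ES,
                   fg$ES[fg$pathway == nm], tolerance = 1e-9)
    }
  })
})

test_that("permutation GSEA is seeded, deterministic and sign-consistent", {
  ex <- make_expression(400, 10, 40, effect_log2 = 2, sigma = 0.5,
                        seed = 171)
  d <- differential_expression(ex$mat, ex$groups, alpha = 0.01)
  rk <- rank_genes(d)
  r1 <- gsea_preranked(rk, ex$collection, n_perm = 100, seed = 9)
  r2 <- gsea_preranked(rk, ex$collection, n_perm = 100, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(
    r1$p, gsea_preranked(rk, ex$collection, n_perm = 100, seed = 10)$p))
  expect_true(all(sign(r1$NES) == sign(r1$ES)))
  expect_true(all(r1$p >= 1 / 101 - 1e-12))
  expect_true(all(abs(r1$ES) <= 1))
  expect_error(gsea_preranked(rk, ex$collection, n_perm = 5, seed = 1),
               "at least 10")
})

test_that("a set occupying the top decile attains the minimal p-value", {
  withr::with_seed(181, {
    N <- 1000
    rk <- sort(rnorm(N, sd = 1) + seq(3, 0, length.out = N),
               decreasing = TRUE)
    names(rk) <- sprintf("G%04d", 1:N)
    planted <- names(rk)[1:50] # entire set inside the top decile
    res <- gsea_preranked(rk, list(TOP = planted), n_perm = 1000,
                          seed = 5)
    expect_gt(res$NES, 1.5)
    # no permutation is as extreme: p = 1/(n_pos + 1) <= 1/(0.4 n_perm)
    expect_lte(res$p, 1 / (0.4 * 1000))
  })
})

test_that("size bounds skip sets with a log entry", {
  rk <- stats::setNames(seq(2, -2, length.out = 100),
                        sprintf("G%03d", 1:100))
  sets <- list(TINY = names(rk)[1:2], OK = names(rk)[seq(1, 60, 3)])
  expect_message(res <- gsea_preranked(rk, sets, n_perm = 50, seed = 3,
                                       min_size = 5),
                 "outside size bounds")
  expect_identical(res$term, "OK")
})
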