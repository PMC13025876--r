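# Preranked gene set enrichment analysis: weighted Kolmogorov-Smirnov
# enrichment score, gene-set permutation null, sign-matched NES,
# permutation p-values and sign-separated FDR.

#' Weighted KS enrichment score with running sum
#'
#' Walks the ranked list top to bottom. Hits (set members) increment the
#' running sum by `|r|^weight / N_R` (`N_R` = sum of `|r|^weight` over the
#' hits); misses decrement by `1 / (N - N_H)`. ES is the running-sum value
#' of maximum absolute deviation from zero, signed. The leading edge is
#' the set members at or before the maximum for positive ES, and at or
#' after the minimum for negative ES.
#'
#' @param ranked Named numeric vector from [rank_genes()] (metric values,
#'   descending, names = genes).
#' @param gene_set A [gene_set()] or character vector; its intersection
#'   with `ranked` must be nonempty.
#' @param weight Exponent on the metric (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return List with `ES`, `running` (numeric vector along the list),
#'   `hits` (positions of set members), `peak` (position of the
#'   extremum), and `leading_edge` ([gene_set()]).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  members <- as_gene_set(gene_set)$symbols
  hit <- toupper(trimws(genes)) %in% members
  if (!any(hit)) stop("gene set has no genes in the ranked list")
  N <- length(ranked)
  NH <- sum(hit)
  if (NH == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked)^weight
  NR <- sum(w[hit])
  inc <- numeric(N)
  if (NR > 0) {
    inc[hit] <- w[hit] / NR
  } else {
    inc[hit] <- 1 / NH  # all-hit weights zero: fall back to equal steps
  }
  inc[!hit] <- -1 / (N - NH)
  running <- cumsum(inc)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max]
        else running[i_min]
  peak <- if (es >= 0) i_max else i_min
  le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
        else genes[peak:N][hit[peak:N]]
  list(ES = es, running = running, hits = which(hit), peak = peak,
       leading_edge = gene_set(le, label = "leading edge"))
}

# ES only, from hit positions: O(N_H) once weights are extracted.
# Identical by construction to the signed max deviation of the full
# running sum (deviation maxima occur at hit positions, minima just
# before hits or at the end of the list).
es_from_hits <- function(w_list, hit_idx, N) {
  NH <- length(hit_idx)
  wh <- w_list[hit_idx]
  NR <- sum(wh)
  hit_cum <- if (NR > 0) cumsum(wh) / NR else seq_len(NH) / NH
  miss_step <- 1 / (N - NH)
  before <- (hit_idx - seq_len(NH)) * miss_step        # misses before each hit
  at_hit <- hit_cum - before                           # value right after hit
  pre_hit <- c(0, hit_cum[-NH]) - before               # value just before hit
  hi <- max(at_hit)
  lo <- min(pre_hit, hit_cum[NH] - (N - NH) * miss_step)
  if (hi >= -lo) hi else lo
}

#' Preranked GSEA over a collection
#'
#' Tests each gene set against a ranked list using [enrichment_score()],
#' with a gene-set permutation null: for each set, `n_perm` random member
#' sets of equal size are drawn (seeded) from the ranked genes. The
#' normalised enrichment score divides ES by the mean |ES| of
#' sign-matched permutations; the nominal p-value is
#' `(number of sign-matched permutation ES at least as extreme + 1) /
#' (number of sign-matched permutations + 1)`; FDR q-values pool
#' normalised permutation scores separately by sign, in the style of the
#' original GSEA procedure.
#'
#' @param ranked Named numeric vector from [rank_genes()].
#' @param collection A [read_gmt()] collection or named list of character
#'   vectors.
#' @param n_perm Number of permutations (default 1000; minimum 10).
#' @param seed Integer seed for the permutation draws.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked list; sets outside are skipped with a message.
#' @param weight Metric exponent (default 1).
#' @return Data frame with columns `term`, `size`, `ES`, `NES`, `p`, `q`,
#'   `leading_edge` (comma-separated symbols), sorted by ascending `p`;
#'   full leading-edge gene sets attached as attribute
#'   `"leading_edges"`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000L, seed = 1L,
                           min_size = 5L, max_size = 500L, weight = 1) {
  if (n_perm < 10L) stop("n_perm must be at least 10")
  if (inherits(collection, "gene_set_collection")) {
    sets <- lapply(collection$terms, `[[`, "members")
  } else {
    stopifnot(is.list(collection), !is.null(names(collection)))
    sets <- lapply(collection, function(m) as_gene_set(m)$symbols)
  }
  genes <- names(ranked)
  N <- length(ranked)
  w_list <- abs(ranked)^weight
  sets <- lapply(sets, normalize_symbols)
  sizes <- vapply(sets, function(m)
    sum(toupper(trimws(genes)) %in% m), integer(1))
  usable <- sizes >= min_size & sizes <= max_size
  skipped <- names(sets)[!usable]
  if (length(skipped))
    message(length(skipped), " gene set(s) outside size bounds skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
  sets <- sets[usable]
  sizes <- sizes[usable]
  if (!length(sets)) stop("no gene set within size bounds")

  # one permutation block per distinct set size, shared across sets
  seeds <- derive_seeds(seed, length(sets))
  obs <- vapply(names(sets), function(nm) {
    enrichment_score(ranked, sets[[nm]], weight = weight)$ES
  }, numeric(1))
  le_list <- lapply(names(sets), function(nm)
    enrichment_score(ranked, sets[[nm]], weight = weight)$leading_edge)
  names(le_list) <- names(sets)

  nes <- numeric(length(sets))
  pval <- numeric(length(sets))
  perm_nes_pos <- list()
  perm_nes_neg <- list()
  for (i in seq_along(sets)) {
    m <- sizes[[i]]
    perm_es <- local_seed(seeds[i], {
      vapply(seq_len(n_perm), function(j) {
        idx <- sort(sample.int(N, m))
        es_from_hits(w_list, idx, N)
      }, numeric(1))
    })
    pos <- perm_es[perm_es >= 0]
    neg <- perm_es[perm_es < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (obs[i] >= 0) {
      nes[i] <- if (is.na(mean_pos) || mean_pos == 0) NA_real_
                else obs[i] / mean_pos
      pval[i] <- (sum(pos >= obs[i]) + 1) / (length(pos) + 1)
    } else {
      nes[i] <- if (is.na(mean_neg) || mean_neg == 0) NA_real_
                else -abs(obs[i]) / mean_neg
      pval[i] <- (sum(neg <= obs[i]) + 1) / (length(neg) + 1)
    }
    perm_nes_pos[[i]] <- if (!is.na(mean_pos) && mean_pos > 0)
      pos / mean_pos else numeric(0)
    perm_nes_neg[[i]] <- if (!is.na(mean_neg) && mean_neg > 0)
      neg / mean_neg else numeric(0)
  }

  pool_pos <- unlist(perm_nes_pos, use.names = FALSE)
  pool_neg <- unlist(perm_nes_neg, use.names = FALSE)
  qval <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= nes[i]) else 0
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= nes[i]) else 0
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(term = names(sets), size = unname(sizes),
                    ES = unname(obs), NES = nes, p = pval, q = qval,
                    leading_edge = vapply(le_list, function(le)
                      paste(le$symbols, collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "leading_edges") <- le_list
  out
}
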