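# Two-group differential expression on log2(x + 1)-transformed values:
# per-gene Welch t-tests (vectorised) and |log2FC| / p-value flagging.

#' Named alpha presets for the DEG screen
#'
#' Two significance levels circulate for this screen (0.05 and 0.01);
#' neither is assumed silently — `alpha` must be chosen explicitly, and
#' these presets name the two conventional values.
#' @export
deg_alpha_presets <- c(lenient = 0.05, strict = 0.01)

#' Read an expression matrix
#'
#' Headered TSV with gene symbols in the first column and one column per
#' sample.
#'
#' @param path Matrix file path.
#' @return Numeric matrix, rownames = gene symbols.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- normalize_symbols(df[[1L]])
  m
}

#' Read a two-column sample annotation
#'
#' Headered TSV: `sample`, `group` (exactly two levels).
#'
#' @param path Annotation file path.
#' @return Named character vector, sample -> group.
#' @export
read_groups <- function(path) {
  df <- read_tsv(path)
  stopifnot(ncol(df) >= 2L)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' Differential expression between two groups
#'
#' Transforms expression to `log2(x + 1)` (tolerating zeros), computes
#' `log2FC = mean(group A) - mean(group B)` on that scale, and a
#' two-sided Welch t-test per gene on the same transformed values. Genes
#' are flagged `up`/`down` when `|log2FC| > lfc` and `p < alpha`. Genes
#' with zero variance in both groups get `p = NA`, are excluded from the
#' flags, and trigger one warning.
#'
#' @param mat Non-negative numeric matrix, genes x samples.
#' @param groups Named character vector (sample -> group) or factor/vector
#'   aligned with `colnames(mat)`; exactly two levels.
#' @param alpha Significance threshold; no default — pass one of
#'   [deg_alpha_presets] or an explicit value.
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param group_a Which level is the "A" (e.g. disease) group; defaults
#'   to the first sorted level.
#' @return Data frame with columns `gene`, `mean_a`, `mean_b`, `log2FC`,
#'   `t`, `df`, `p`, `flag` (`"up"`, `"down"` or `"ns"`), ordered as the
#'   input rows.
#' @export
differential_expression <- function(mat, groups, alpha, lfc = 1,
                                    group_a = NULL) {
  stopifnot(is.matrix(mat), !missing(alpha), alpha > 0, alpha < 1)
  if (any(mat < 0)) stop("expression values must be non-negative")
  if (!is.null(names(groups)) && !is.null(colnames(mat)))
    groups <- groups[colnames(mat)]
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two sample groups are required")
  a <- group_a %||% lev[1L]
  b <- setdiff(lev, a)
  ia <- which(groups == a)
  ib <- which(groups == b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least 2 samples")
  x <- log2(mat + 1)
  xa <- x[, ia, drop = FALSE]
  xb <- x[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) with zero variance in both groups: p set to NA")
    tstat[degenerate] <- NA_real_
    dfree[degenerate] <- NA_real_
    p[degenerate] <- NA_real_
  }
  lfc_val <- ma - mb
  flag <- rep("ns", nrow(mat))
  ok <- !is.na(p) & p < alpha & abs(lfc_val) > lfc
  flag[ok & lfc_val > 0] <- "up"
  flag[ok & lfc_val < 0] <- "down"
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             mean_a = unname(ma), mean_b = unname(mb),
             log2FC = unname(lfc_val), t = unname(tstat),
             df = unname(dfree), p = unname(p), flag = flag,
             stringsAsFactors = FALSE)
}

#' Rank genes for preranked GSEA
#'
#' Orders genes by a chosen metric, descending, breaking ties
#' lexicographically by symbol for determinism.
#'
#' @param deg A [differential_expression()] table, or any data frame with
#'   a `gene` column and the metric column.
#' @param metric Column to rank on (default `"log2FC"`).
#' @return Named numeric vector: metric values named by gene, sorted
#'   descending.
#' @export
rank_genes <- function(deg, metric = "log2FC") {
  stopifnot(metric %in% names(deg), "gene" %in% names(deg))
  v <- deg[[metric]]
  if (any(is.na(v))) stop("missing values in ranking metric")
  ord <- order(-v, deg$gene, method = "radix")
  stats::setNames(v[ord], deg$gene[ord])
}
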