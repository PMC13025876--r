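# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write a data.frame as headered TSV without quoting or row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
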