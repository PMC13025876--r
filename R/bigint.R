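# Minimal arbitrary-precision non-negative integers, used so that MCC
# scores (sums of factorials) stay exact for cliques larger than the
# double-precision factorial range. Representation: numeric vector of
# base-1e4 digits, little-endian, no trailing zero limbs.

BI_BASE <- 1e4

bi_norm <- function(d) {
  carry <- 0
  i <- 1L
  while (i <= length(d) || carry > 0) {
    if (i > length(d)) d[i] <- 0
    v <- d[i] + carry
    d[i] <- v %% BI_BASE
    carry <- v %/% BI_BASE
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% BI_BASE)
    x <- x %/% BI_BASE
    if (x == 0) break
  }
  d
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# multiply by a small scalar (s * BASE must stay exact in doubles)
bi_mul_small <- function(a, s) {
  stopifnot(s >= 0, s < 2^40)
  if (s == 0) return(bi(0))
  bi_norm(a * s)
}

# factorial(n) as a bignum, with memoisation across calls
bi_factorial <- local({
  cache <- list(`0` = bi(1))
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    known <- max(as.numeric(names(cache)))
    acc <- cache[[as.character(known)]]
    for (k in seq(known + 1, n)) {
      acc <- bi_mul_small(acc, k)
      cache[[as.character(k)]] <<- acc
    }
    acc
  }
})

bi_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

bi_to_double <- function(a) sum(a * BI_BASE^(seq_along(a) - 1))

bi_format <- function(a) {
  digits <- rev(a)
  paste0(as.character(digits[1L]),
         paste(sprintf("%04d", digits[-1L]), collapse = ""))
}
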