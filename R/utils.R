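# small numeric utilities shared across modules

#' Round half away from zero
#'
#' Report tables use 1-decimal rounding with halves away from zero (so
#' 31.35 -> 31.4), unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classic between/within variance
#' ratio is computed over the resulting 2m half-chains. Values near 1
#' indicate the chains agree; fits in this package require the maximum
#' over monitored parameters to stay below a threshold (default 1.05).
#'
#' @param chains A list of numeric matrices (iterations x parameters),
#'   one per chain, with identical column names.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
split_rhat <- function(chains) {
  stopifnot(length(chains) >= 1)
  halves <- list()
  for (ch in chains) {
    ch <- as.matrix(ch)
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  m <- length(halves)
  p <- ncol(halves[[1]])
  out <- vapply(seq_len(p), function(j) {
    xs <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vs <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vs)
    B <- n * stats::var(xs)
    if (!is.finite(W) || W <= .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(out) <- colnames(halves[[1]])
  out
}

# deterministic child seed: fold a label into a parent seed, staying < 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

assert_scalar_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a positive integer, got %s", name,
                 paste(x, collapse = ",")))
  }
  invisible(as.integer(x))
}
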