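# shared numeric helpers

#' Nearest-rank quantile
#'
#' Quantile by the nearest-rank definition: the `ceiling(q * n)`-th smallest
#' value. No interpolation, so thresholds are exactly reproducible across
#' platforms.
#'
#' @param x numeric vector (no NAs).
#' @param q quantile in (0, 1].
#' @return a single element of `x`.
#' @export
nearest_rank_quantile <- function(x, q) {
  stopifnot(is.numeric(x), length(x) > 0L, !anyNA(x), q > 0, q <= 1)
  sort(x)[ceiling(q * length(x))]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)   # x first: keeps dim attributes

# population (1/n) variance / covariance; descriptive convention used
# throughout the package
pop_var <- function(x) mean((x - mean(x))^2)
pop_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)

# spot labels A, B, ..., Z, AA, AB, ...
spot_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- n - 26L
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS)[seq_len(extra)])
}

# derive a sub-seed from a master seed; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 12289 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
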