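#' Gene-set Z score (GSZ) per sample
#'
#' Standardized deviation of a set's summed value from its expectation under
#' hypergeometric sampling of `n` genes out of the sample's `N` gene values:
#' for sample `s` with values `e` (mean `mu`, population variance `sig2`),
#' `score = (sum_set e - n * mu) / sqrt(n * sig2 * (N - n) / (N - 1))`.
#' A zero-variance sample scores 0 by convention. Under random sets the
#' score has mean 0 and variance 1 exactly.
#'
#' @param set character vector of gene ids (the intersection with the matrix
#'   genes is used) or a named list of such vectors.
#' @param m gene x sample matrix, typically centered expression.
#' @return named numeric vector of per-sample scores, or a set x sample
#'   matrix when `set` is a list.
#' @export
gsz_score <- function(set, m) {
  if (is.list(set)) {
    out <- t(vapply(set, gsz_score, numeric(ncol(m)), m = m))
    colnames(out) <- colnames(m)
    return(out)
  }
  genes <- intersect(set, rownames(m))
  if (!length(genes)) stop("gene set has no genes in the matrix")
  N <- nrow(m); n <- length(genes)
  mu <- colMeans(m)
  sig2 <- colMeans(m^2) - mu^2
  ssum <- if (n == 1L) m[genes, ] else colSums(m[genes, , drop = FALSE])
  denom2 <- n * sig2 * (N - n) / (N - 1)
  score <- ifelse(denom2 > 0, (ssum - n * mu) / sqrt(pmax(denom2, 0)), 0)
  stats::setNames(as.numeric(score), colnames(m))
}

#' Gene-set map over the SOM grid
#'
#' Counts, per unit, how many of the set's genes have that unit as their
#' BMU — the dot-accumulation view of where a signature lives on the map.
#'
#' @param set character vector of gene ids.
#' @param model a `som_model`.
#' @return matrix of per-unit counts with the model's grid shape; counts
#'   sum to the size of the intersection with the model's genes.
#' @export
gene_set_map <- function(set, model) {
  shared <- intersect(set, names(model$bmu))
  counts <- tabulate(model$bmu[shared], prod(model$grid_dims))
  matrix(counts, nrow = model$grid_dims[1L])
}

#' Fisher overlap test between two gene sets
#'
#' One-sided enrichment p-value: the upper tail of
#' Hypergeometric(N, |a|, |b|) at the observed overlap, i.e. the probability
#' of an overlap at least as large under random draws from a universe of
#' `universe_size` genes. The odds ratio comes from the 2x2 table, with a
#' 0.5 Haldane correction when any cell is zero.
#'
#' @param a,b character vectors of gene ids (or integer counts via
#'   `overlap`).
#' @param universe_size number of genes in the universe.
#' @param overlap observed overlap; computed from `a` and `b` when they are
#'   id vectors.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#'   (delegated to [stats::fisher.test()]).
#' @return list with `overlap`, `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(a, b, universe_size, overlap = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.character(a)) {
    a <- unique(a); b <- unique(b)
    if (is.null(overlap)) overlap <- length(intersect(a, b))
    na <- length(a); nb <- length(b)
  } else {
    na <- a; nb <- b
    if (is.null(overlap)) stop("give 'overlap' with count inputs")
  }
  N <- universe_size
  if (na > N || nb > N || overlap > min(na, nb) ||
      na + nb - overlap > N)
    stop("inconsistent counts for a universe of ", N)
  k <- overlap
  tab <- matrix(c(k, na - k, nb - k, N - na - nb + k), 2L)
  if (alternative == "two.sided") {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    p <- ft$p.value
  } else {
    p <- stats::phyper(k - 1, na, N - na, nb, lower.tail = FALSE)
  }
  h <- if (any(tab == 0L)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
        ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(overlap = k, odds_ratio = or, p = p)
}
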