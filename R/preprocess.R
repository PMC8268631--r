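#' Quantile normalization
#'
#' Forces every sample column to share the same multiset of values: the
#' across-sample mean of order statistics, assigned back by within-column
#' rank. Tied values receive the mean of the normalized values over their
#' tied ranks, so the operation is rank-preserving and idempotent.
#'
#' @param m omics matrix (complete; errors on missing values).
#' @return normalized matrix, same dimnames and layer.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m))
    stop("matrix contains missing values; impute upstream before ",
         "quantile normalization")
  ref <- rowMeans(apply(m, 2L, sort, method = "radix"))
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    v <- (ref[lo] + ref[hi]) / 2
    # ties of length > 2 give an average rank whose floor/ceiling midpoint
    # is not the mean over all tied ranks; fix those groups exactly
    if (anyDuplicated(col)) {
      for (d in unique(col[duplicated(col)])) {
        idx <- which(col == d)
        rr <- sort(rank(col, ties.method = "first")[idx])
        v[idx] <- mean(ref[rr])
      }
    }
    v
  })
  dimnames(out) <- dimnames(m)
  attr(out, "layer") <- omics_layer(m)
  out
}

#' Aggregate CpG betas to gene promoters
#'
#' Averages CpG beta values inside each gene's promoter window — 2 kb
#' upstream to 200 bp downstream of the TSS, strand-aware, closed 1-based
#' interval: `[tss-2000, tss+200]` on `+`, `[tss-200, tss+2000]` on `-`.
#' CpGs with a missing beta in a sample are excluded from that sample's mean
#' (pairwise deletion). Genes with no CpG in their window are dropped and
#' reported via the `"dropped_genes"` attribute.
#'
#' @param cpgs a [cpg_table()].
#' @param ann a [gene_annotation()].
#' @return omics matrix (layer `methylation_beta`), one row per gene with at
#'   least one promoter CpG and at least one non-missing beta per sample.
#' @export
promoter_beta <- function(cpgs, ann) {
  if (!inherits(cpgs, "cpg_table")) stop("'cpgs' must be a cpg_table")
  if (!length(intersect(unique(ann$chromosome), unique(cpgs$info$chromosome))))
    stop("gene annotation and CpG table share no chromosomes")
  win <- promoter_window(ann$tss, ann$strand)
  # index CpGs by chromosome once; per gene, window membership by position
  by_chr <- split(seq_len(nrow(cpgs$info)), cpgs$info$chromosome)
  n_s <- ncol(cpgs$betas)
  vals <- matrix(NA_real_, nrow(ann), n_s,
                 dimnames = list(ann$gene_id, colnames(cpgs$betas)))
  keep <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    cand <- by_chr[[ann$chromosome[i]]]
    if (is.null(cand)) next
    p <- cpgs$info$position[cand]
    inside <- cand[p >= win[i, 1L] & p <= win[i, 2L]]
    if (!length(inside)) next
    b <- cpgs$betas[inside, , drop = FALSE]
    mb <- colMeans(b, na.rm = TRUE)
    if (anyNA(mb) || any(is.nan(mb))) next   # some sample with no usable CpG
    vals[i, ] <- mb
    keep[i] <- TRUE
  }
  dropped <- ann$gene_id[!keep]
  if (length(dropped))
    message(length(dropped), " gene(s) without promoter CpG coverage dropped")
  out <- omics_matrix(vals[keep, , drop = FALSE], "methylation_beta")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Exclude genes on the sex chromosomes
#'
#' Removes genes annotated on chrX or chrY (case-insensitive, with or
#' without the `chr` prefix) to avoid a sex bias in downstream maps.
#'
#' @param m omics matrix.
#' @param ann a [gene_annotation()] covering the matrix genes.
#' @return filtered matrix; number of removed genes in attribute
#'   `"n_removed"`.
#' @export
drop_sex_chromosomes <- function(m, ann) {
  chr <- stats::setNames(ann$chromosome, ann$gene_id)[rownames(m)]
  if (anyNA(chr))
    stop("annotation missing for ", sum(is.na(chr)), " gene(s)")
  sexchr <- sub("^chr", "", tolower(chr)) %in% c("x", "y")
  if (any(sexchr))
    message("removed ", sum(sexchr), " gene(s) on chrX/chrY")
  out <- m[!sexchr, , drop = FALSE]
  attr(out, "layer") <- omics_layer(m)
  attr(out, "n_removed") <- sum(sexchr)
  out
}

#' Center each gene across samples
#'
#' Subtracts the gene's mean so portraits show up- (positive) and
#' down-regulation (negative) relative to the cohort mean. Keep the original
#' matrix for scatter and covariance stages.
#'
#' @param m omics matrix.
#' @return centered matrix (layer `centered`).
#' @export
center_genes <- function(m) {
  out <- m - rowMeans(m)
  attr(out, "layer") <- "centered"
  out
}

#' Log-transform raw intensities
#'
#' `log10(x + 1)`, the guard offset protecting nonpositive raw intensities.
#' Only needed when raw-scale values are supplied; synthetic cohorts are
#' generated on log scale already.
#'
#' @param m matrix of raw intensities (>= 0 recommended).
#' @return log10-scale omics matrix.
#' @export
log10_transform <- function(m) {
  out <- log10(m + 1)
  attr(out, "layer") <- "expression_log10"
  out
}
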