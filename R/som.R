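#' Batch SOM training parameters
#'
#' @param grid_k grid side length (scalar, K x K) or `c(rows, cols)`.
#'   30 x 30 suits cohorts up to ~10k genes; 50 x 50 for large cohorts.
#' @param epochs number of batch epochs (assignment + codebook update).
#' @param radius_start,radius_end Gaussian neighborhood radius in grid
#'   units, linearly annealed across epochs. Defaults: half the larger grid
#'   side down to 0.5.
#' @param freeze_epochs number of final epochs run at the frozen
#'   `radius_end` (the annealing spans the first `epochs - freeze_epochs`
#'   epochs); quantization error is expected to settle monotonically over
#'   this tail.
#' @param init `"pca_linear"` (deterministic, codebook spanned by the first
#'   two principal axes of the gene cloud) or `"random"` (gene profiles
#'   sampled under `seed`).
#' @param seed integer seed (used by random init; training itself is
#'   deterministic).
#' @return validated list of class `som_params`.
#' @export
som_params <- function(grid_k = 30L, epochs = 40L,
                       radius_start = NULL, radius_end = 0.5,
                       freeze_epochs = 5L,
                       init = c("pca_linear", "random"), seed = 1L) {
  init <- match.arg(init)
  dims <- if (length(grid_k) == 1L) c(grid_k, grid_k) else grid_k[1:2]
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("grid dimensions must be >= 1")
  if (is.null(radius_start)) radius_start <- max(dims) / 2
  if (radius_start < radius_end || radius_end < 0)
    stop("need radius_start >= radius_end >= 0")
  freeze_epochs <- min(as.integer(freeze_epochs), as.integer(epochs))
  structure(list(grid_dims = dims, epochs = as.integer(epochs),
                 radius_start = radius_start, radius_end = radius_end,
                 freeze_epochs = freeze_epochs,
                 init = init, seed = as.integer(seed)),
            class = "som_params")
}

# unit u <-> (row, col): u = (col-1)*rows + row (column-major, matching
# matrix(v, nrow = rows))
unit_coords <- function(dims) {
  u <- seq_len(prod(dims))
  cbind(row = ((u - 1L) %% dims[1L]) + 1L,
        col = ((u - 1L) %/% dims[1L]) + 1L)
}

# squared distance gene x unit, via the expansion trick (BLAS-bound)
dist2_to_codebook <- function(x, cb) {
  d2 <- outer(rowSums(x^2), rowSums(cb^2), "+") - 2 * tcrossprod(x, cb)
  d2[d2 < 0] <- 0
  d2
}

som_init_codebook <- function(x, p) {
  U <- prod(p$grid_dims)
  mu <- colMeans(x)
  if (p$init == "random") {
    set.seed(p$seed)
    return(x[sample.int(nrow(x), U, replace = nrow(x) < U), , drop = FALSE])
  }
  # deterministic linear init on the first two principal axes
  xc <- sweep(x, 2L, mu)
  k <- min(2L, ncol(x), nrow(x))
  sv <- svd(xc, nu = 0L, nv = k)
  cb <- matrix(rep(mu, each = U), U, ncol(x))
  co <- unit_coords(p$grid_dims)
  ax <- if (p$grid_dims[1L] >= p$grid_dims[2L]) c(1L, 2L) else c(2L, 1L)
  for (a in 1:2) {                                  # PC1 along the longer side
    if (a > k || sv$d[a] < 1e-12) next
    v <- sv$v[, a]
    if (v[which.max(abs(v))] < 0) v <- -v           # sign fixed for determinism
    sdev <- sv$d[a] / sqrt(max(1L, nrow(x) - 1L))
    nlev <- p$grid_dims[ax[a]]
    coord <- co[, ax[a]]
    pos <- if (nlev == 1L) rep(0, U) else 2 * (2 * (coord - 1) / (nlev - 1) - 1)
    cb <- cb + outer(pos * sdev, v)
  }
  cb
}

#' Train a batch self-organizing map on gene profiles
#'
#' Genes are points in sample space; the SOM compresses them into a grid of
#' metagenes (codebook vectors). Each epoch assigns every gene to its
#' Euclidean best-matching unit (BMU, ties broken toward the lowest unit
#' index), then replaces each codebook vector by the
#' Gaussian-neighborhood-weighted mean of the gene profiles, with the kernel
#' radius annealed linearly from `radius_start` to `radius_end`. At radius 0
#' the update degenerates to the k-means step. Empty units keep their
#' codebook vector. Training is deterministic given the data, parameters and
#' seed.
#'
#' @param m centered gene x sample omics matrix (see [center_genes()]).
#' @param p a [som_params()].
#' @return object of class `som_model`: `codebook` (units x samples),
#'   `bmu` (named unit index per gene), `unit_genes` (genes per unit),
#'   `qe_history` (mean squared gene-to-BMU distance per epoch, plus one
#'   final post-update value), `params`, `grid_dims`, `coords`.
#' @seealso [portrait()], [detect_spots()], [prognostic_map()]
#' @export
train_som <- function(m, p = som_params()) {
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L)
    stop("'m' must be a non-empty gene x sample matrix")
  if (anyNA(m) || !all(is.finite(m)))
    stop("'m' contains missing or non-finite values")
  U <- prod(p$grid_dims)
  if (nrow(m) < U / 4)
    warning("fewer genes (", nrow(m), ") than grid_k^2/4 (", U / 4,
            "); consider a smaller grid")
  coords <- unit_coords(p$grid_dims)
  d2grid <- as.matrix(stats::dist(coords))^2
  cb <- som_init_codebook(m, p)
  qe <- numeric(p$epochs + 1L)
  bmu <- NULL
  n_anneal <- p$epochs - p$freeze_epochs
  for (e in seq_len(p$epochs)) {
    sigma <- if (e > n_anneal || n_anneal <= 1L) p$radius_end else
      p$radius_start + (p$radius_end - p$radius_start) * (e - 1) / (n_anneal - 1)
    d2 <- dist2_to_codebook(m, cb)
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(d2[cbind(seq_len(nrow(m)), bmu)])
    counts <- tabulate(bmu, U)
    ssum <- matrix(0, U, ncol(m))
    rs <- rowsum(m, bmu)
    ssum[as.integer(rownames(rs)), ] <- rs
    if (sigma <= 0) {
      nz <- counts > 0L
      cb[nz, ] <- ssum[nz, , drop = FALSE] / counts[nz]
    } else {
      h <- exp(-d2grid / (2 * sigma^2))
      den <- as.numeric(h %*% counts)
      ok <- den > 1e-300
      cb[ok, ] <- (h %*% ssum)[ok, , drop = FALSE] / den[ok]
    }
  }
  # the stored assignment is the one that produced the final codebook, so
  # unit means and member genes are mutually consistent (k-means sense);
  # the appended QE value is the objective after the last update
  d2 <- dist2_to_codebook(m, cb)
  qe[p$epochs + 1L] <- mean(d2[cbind(seq_len(nrow(m)), bmu)])
  names(bmu) <- rownames(m)
  ug <- split(rownames(m), factor(bmu, levels = seq_len(U)))
  names(ug) <- NULL
  dimnames(cb) <- list(NULL, colnames(m))
  structure(list(codebook = cb, bmu = bmu, unit_genes = ug,
                 qe_history = qe, params = p, grid_dims = p$grid_dims,
                 coords = coords, n_genes = nrow(m)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("Batch SOM:", x$grid_dims[1L], "x", x$grid_dims[2L], "grid,",
      x$n_genes, "genes,", ncol(x$codebook), "samples\n")
  cat("  epochs:", x$params$epochs, " radius:", x$params$radius_start,
      "->", x$params$radius_end, " init:", x$params$init, "\n")
  cat("  final quantization error:",
      format(utils::tail(x$qe_history, 1L), digits = 5), "\n")
  invisible(x)
}

#' @export
summary.som_model <- function(object, ...) {
  occ <- lengths(object$unit_genes)
  cat("Batch SOM summary\n")
  print(object)
  cat("  occupied units:", sum(occ > 0L), "/", length(occ),
      " (genes per occupied unit: median", stats::median(occ[occ > 0L]),
      ", max", max(occ), ")\n")
  invisible(list(occupancy = occ, qe = object$qe_history))
}

#' Map gene profiles to best-matching units of a trained SOM
#'
#' @param object a `som_model`.
#' @param newdata gene x sample matrix over the model's samples.
#' @param ... unused.
#' @return named integer vector of unit indices.
#' @export
predict.som_model <- function(object, newdata, ...) {
  if (!identical(ncol(newdata), ncol(object$codebook)))
    stop("newdata must have the model's ", ncol(object$codebook), " samples")
  d2 <- dist2_to_codebook(newdata, object$codebook)
  stats::setNames(max.col(-d2, ties.method = "first"), rownames(newdata))
}

#' Metagene portrait of one sample
#'
#' The K x K image of a sample's metagene values: grid cell (r, c) is that
#' sample's component of the unit's codebook vector. Positive (red) pixels
#' mark up-regulation relative to the gene means, negative (blue)
#' down-regulation.
#'
#' @param model a `som_model`.
#' @param sample a sample id present in the model.
#' @return matrix of class `som_portrait` with a `label` attribute.
#' @export
portrait <- function(model, sample) {
  if (!sample %in% colnames(model$codebook))
    stop("unknown sample id: ", sample)
  as_portrait(model$codebook[, sample], model, label = sample)
}

as_portrait <- function(v, model, label) {
  g <- matrix(v, nrow = model$grid_dims[1L])
  attr(g, "label") <- label
  class(g) <- c("som_portrait", class(g))
  g
}

#' Group-mean portrait
#'
#' Pixel-wise mean of the member samples' portraits — the subtype-specific
#' mean portrait when `labels` carries subtype assignments.
#'
#' @param model a `som_model`.
#' @param labels group label per sample (named by sample id, or aligned with
#'   the model's sample order).
#' @param group the group to average.
#' @return a `som_portrait`.
#' @export
group_mean_portrait <- function(model, labels, group) {
  members <- group_samples(model, labels, group)
  if (!length(members)) stop("empty group: ", group)
  as_portrait(rowMeans(model$codebook[, members, drop = FALSE]), model,
              label = paste0("mean(", group, ")"))
}

group_samples <- function(model, labels, group) {
  sam <- colnames(model$codebook)
  lab <- if (!is.null(names(labels))) labels[sam] else
    stats::setNames(rep_len(labels, length(sam)), sam)
  sam[!is.na(lab) & lab == group]
}

#' Difference portrait
#'
#' Pixel-wise difference `a - b` between two portraits from the same model,
#' highlighting regions up in `a` relative to `b` (e.g. a subtype versus a
#' reference group).
#'
#' @param a,b `som_portrait`s of identical shape.
#' @return a `som_portrait` labeled `"A - B"`.
#' @export
difference_portrait <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("portrait shapes differ")
  d <- unclass(a) - unclass(b)
  attr(d, "label") <- paste(attr(a, "label"), "-", attr(b, "label"))
  class(d) <- c("som_portrait", class(d))
  d
}

#' @export
print.som_portrait <- function(x, ...) {
  cat("SOM portrait '", attr(x, "label"), "': ", nrow(x), " x ", ncol(x),
      ", range [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Plot a portrait or a model's sample portrait
#'
#' Heatmap in the field's blue-white-red convention; the grid is drawn with
#' row 1 at the bottom.
#'
#' @param x a `som_portrait` (or `som_model` for `plot.som_model`).
#' @param ... passed to [graphics::image()].
#' @export
plot.som_portrait <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  lim <- max(abs(range(x)), .Machine$double.eps)
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)), t(unclass(x)),
                  zlim = c(-lim, lim), col = pal, xlab = "", ylab = "",
                  main = attr(x, "label"), asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' @rdname plot.som_portrait
#' @param sample sample id to portray (default: the first sample).
#' @export
plot.som_model <- function(x, sample = colnames(x$codebook)[1L], ...) {
  plot(portrait(x, sample), ...)
}
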