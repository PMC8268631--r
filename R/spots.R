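#' Overexpression summary map
#'
#' Pixel-wise maximum over the group-mean portraits: an overview of all
#' spots upregulated in any of the groups. With `direction = "under"` the
#' pixel-wise minimum instead, summarizing regions downregulated (or, on a
#' methylation map, hypo-methylated) in any group; pair it with
#' `detect_spots(..., direction = "under")`.
#'
#' @param model a `som_model`.
#' @param labels group label per sample (named by sample id or aligned with
#'   the model's sample order).
#' @param direction `"over"` (max) or `"under"` (min).
#' @return a `som_portrait`.
#' @export
overexpression_summary_map <- function(model, labels,
                                       direction = c("over", "under")) {
  direction <- match.arg(direction)
  groups <- unique(stats::na.omit(
    if (!is.null(names(labels))) labels[colnames(model$codebook)] else labels))
  if (!length(groups)) stop("need at least one group")
  g <- lapply(groups, function(gr)
    unclass(group_mean_portrait(model, labels, gr)))
  as_portrait(do.call(if (direction == "over") pmax else pmin, g), model,
              label = paste0(direction, "expression summary"))
}

# 4/8-connected component labeling on a logical grid (BFS)
label_components <- function(sel, connectivity = 8L) {
  nr <- nrow(sel); nc <- ncol(sel)
  off <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))[-5L, , drop = FALSE]
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(sel)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      r <- ((u - 1L) %% nr) + 1L; c0 <- ((u - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1L]; cc <- c0 + off[k, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        v <- (cc - 1L) * nr + rr
        if (sel[v] && lab[v] == 0L) {
          lab[v] <- cur
          queue <- c(queue, v)
        }
      }
    }
  }
  lab
}

#' Detect spot modules on a summary portrait
#'
#' Units whose value lies strictly above the nearest-rank `q`-quantile of
#' all unit values are grouped into connected components (8-connectivity by
#' default); components smaller than `min_size` units are discarded.
#' Surviving spots are labeled A, B, ... by descending component peak value.
#' Set `direction = "under"` to segment under-expression spots (the
#' portrait is negated).
#'
#' @param summary a `som_portrait` (typically [overexpression_summary_map()]).
#' @param model the `som_model` the portrait came from (provides member
#'   genes and spot profiles).
#' @param q selection quantile in (0, 1).
#' @param min_size minimum spot size in units.
#' @param connectivity 4 or 8.
#' @param direction `"over"` or `"under"`.
#' @return object of class `som_spots`: list with `spots` (per spot: id,
#'   unit indices, member genes, peak value, per-sample profile),
#'   `profiles` (spot x sample matrix of mean metagene values), `threshold`,
#'   and the call parameters. A flat map yields zero spots.
#' @export
detect_spots <- function(summary, model, q = 0.98, min_size = 3L,
                         connectivity = c(8L, 4L),
                         direction = c("over", "under")) {
  direction <- match.arg(direction)
  connectivity <- as.integer(connectivity)[1L]
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  v <- as.numeric(summary)
  if (direction == "under") v <- -v
  thr <- nearest_rank_quantile(v, q)
  sel <- matrix(v > thr, nrow(summary), ncol(summary))
  empty <- structure(list(spots = list(),
                          profiles = matrix(0, 0L, ncol(model$codebook),
                                            dimnames = list(NULL,
                                              colnames(model$codebook))),
                          threshold = thr, q = q, min_size = min_size,
                          connectivity = connectivity,
                          direction = direction,
                          grid_dims = model$grid_dims),
                     class = "som_spots")
  if (!any(sel)) return(empty)
  lab <- label_components(sel, connectivity)
  comp <- split(which(lab > 0L), lab[lab > 0L])
  comp <- comp[lengths(comp) >= min_size]
  if (!length(comp)) return(empty)
  peaks <- vapply(comp, function(u) max(v[u]), numeric(1L))
  comp <- comp[order(peaks, decreasing = TRUE)]
  ids <- spot_labels(length(comp))
  spots <- vector("list", length(comp))
  prof <- matrix(0, length(comp), ncol(model$codebook),
                 dimnames = list(ids, colnames(model$codebook)))
  for (i in seq_along(comp)) {
    units <- as.integer(comp[[i]])
    genes <- unlist(model$unit_genes[units], use.names = FALSE)
    prof[i, ] <- colMeans(model$codebook[units, , drop = FALSE])
    spots[[i]] <- list(spot_id = ids[i], units = units, genes = genes,
                       peak = max(v[units]), n_units = length(units))
  }
  names(spots) <- ids
  structure(list(spots = spots, profiles = prof, threshold = thr, q = q,
                 min_size = min_size, connectivity = connectivity,
                 direction = direction, grid_dims = model$grid_dims),
            class = "som_spots")
}

#' @export
print.som_spots <- function(x, ...) {
  cat(length(x$spots), " spot(s) (", x$direction, "expression, q = ", x$q,
      ", min_size = ", x$min_size, ", ", x$connectivity,
      "-connectivity)\n", sep = "")
  for (s in x$spots)
    cat("  ", s$spot_id, ": ", s$n_units, " units, ", length(s$genes),
        " genes, peak ", format(s$peak, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Spot membership as a gene-set list
#'
#' @param x a `som_spots`.
#' @return named list of gene id vectors, one per spot.
#' @export
spot_gene_sets <- function(x) {
  lapply(x$spots, function(s) s$genes)
}

#' Per-sample spot calls
#'
#' A spot is called in a sample when the sample's mean metagene value over
#' the spot's units exceeds the nearest-rank 0.90 quantile of that sample's
#' own unit values — a rank-based threshold invariant to per-sample shifts.
#'
#' @param spots a `som_spots`.
#' @param model the `som_model` they were detected on.
#' @param q_sample per-sample quantile threshold.
#' @return logical spot x sample matrix.
#' @export
call_spots <- function(spots, model, q_sample = 0.90) {
  sam <- colnames(model$codebook)
  calls <- matrix(FALSE, length(spots$spots), length(sam),
                  dimnames = list(names(spots$spots), sam))
  if (!length(spots$spots)) return(calls)
  sgn <- if (spots$direction == "under") -1 else 1
  for (s in sam) {
    vs <- sgn * model$codebook[, s]
    thr <- nearest_rank_quantile(vs, q_sample)
    for (i in seq_along(spots$spots))
      calls[i, s] <- mean(vs[spots$spots[[i]]$units]) > thr
  }
  calls
}

#' Spot-number distribution per group
#'
#' Histogram of spots called per sample, a measure of portrait
#' heterogeneity within each group.
#'
#' @param calls logical spot x sample matrix from [call_spots()].
#' @param labels group label per sample (named or aligned with columns).
#' @return integer matrix group x count (columns `0..n_spots`); each row
#'   sums to the group size.
#' @export
spot_number_distribution <- function(calls, labels) {
  lab <- if (!is.null(names(labels))) labels[colnames(calls)] else
    rep_len(labels, ncol(calls))
  nsp <- nrow(calls)
  counts <- colSums(calls)
  groups <- sort(unique(lab))
  out <- t(vapply(groups, function(g)
    tabulate(counts[lab == g] + 1L, nsp + 1L), integer(nsp + 1L)))
  dimnames(out) <- list(groups, as.character(0:nsp))
  out
}

#' Spot implication edges within a group
#'
#' Association-rule confidences between spot calls:
#' `conf(A -> B) = |A and B| / |A|` over the group's samples. An undirected
#' edge is emitted when both directional confidences exceed `conf_min`.
#' Spots never called in the group take part in no edge and are listed
#' separately.
#'
#' @param calls logical spot x sample call matrix.
#' @param samples samples forming the group (default: all).
#' @param conf_min confidence threshold (strict).
#' @return list with `edges` (data.frame spot_a, spot_b, conf_ab, conf_ba)
#'   and `uncalled` (spot ids never called in the group).
#' @export
spot_implication <- function(calls, samples = colnames(calls),
                             conf_min = 0.5) {
  if (!length(samples)) stop("group is empty")
  cc <- calls[, samples, drop = FALSE]
  n_called <- rowSums(cc)
  uncalled <- rownames(cc)[n_called == 0L]
  active <- which(n_called > 0L)
  res <- list()
  if (length(active) >= 2L) {
    co <- tcrossprod(cc[active, , drop = FALSE] * 1)
    for (i in seq_along(active)[-length(active)])
      for (j in (i + 1L):length(active)) {
        ai <- active[i]; aj <- active[j]
        cab <- co[i, j] / n_called[ai]
        cba <- co[i, j] / n_called[aj]
        if (min(cab, cba) > conf_min)
          res[[length(res) + 1L]] <- data.frame(
            spot_a = rownames(cc)[ai], spot_b = rownames(cc)[aj],
            conf_ab = cab, conf_ba = cba, stringsAsFactors = FALSE)
      }
  }
  edges <- if (length(res)) do.call(rbind, res) else
    data.frame(spot_a = character(), spot_b = character(),
               conf_ab = numeric(), conf_ba = numeric(),
               stringsAsFactors = FALSE)
  list(edges = edges, uncalled = uncalled)
}

#' Spot-wise expression versus methylation scatter
#'
#' For one spot, the group-averaged mean expression and mean promoter beta
#' over the spot's genes — the per-group points of the E-versus-M scatter.
#' Genes are restricted to those present in both matrices; samples to those
#' shared by both (per group).
#'
#' @param spot one element of `som_spots$spots` (or a `som_spots` plus
#'   `spot_id`).
#' @param expr expression omics matrix (original scale, not centered).
#' @param meth gene-level promoter beta omics matrix.
#' @param labels group label per sample.
#' @param spot_id spot to use when `spot` is a `som_spots`.
#' @return data.frame with group, mean_expr, mean_beta, n_genes, n_samples.
#' @export
spot_expression_methylation_scatter <- function(spot, expr, meth, labels,
                                                spot_id = NULL) {
  if (inherits(spot, "som_spots")) {
    if (is.null(spot_id)) stop("give 'spot_id' when passing a som_spots")
    spot <- spot$spots[[spot_id]]
  }
  genes <- intersect(spot$genes, intersect(rownames(expr), rownames(meth)))
  if (!length(genes))
    stop("no spot genes shared by the expression and methylation matrices")
  sam <- intersect(colnames(expr), colnames(meth))
  lab <- if (!is.null(names(labels))) labels[sam] else
    stats::setNames(rep_len(labels, length(sam)), sam)
  groups <- sort(unique(stats::na.omit(lab)))
  out <- lapply(groups, function(g) {
    gs <- sam[!is.na(lab) & lab == g]
    data.frame(group = g,
               mean_expr = mean(expr[genes, gs]),
               mean_beta = mean(meth[genes, gs]),
               n_genes = length(genes), n_samples = length(gs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-map genes into another trained SOM
#'
#' Where do the member genes of one layer's spot land on the other layer's
#' map? Returns the per-unit density of the genes' BMUs in the target model
#' and a dispersion score: the Shannon entropy of the gene distribution over
#' bins — one bin per target spot plus one bin per background (non-spot)
#' unit — normalized by the log of the bin count (0 = all genes in one bin,
#' 1 = uniform over all bins). Genes of a module co-regulated on both
#' layers collapse into a single spot bin (low dispersion, the "melting"
#' signature); genes without structure on the target layer scatter over the
#' background units (high dispersion).
#'
#' @param genes gene ids to map (intersection with the target model's genes
#'   is used).
#' @param target a `som_model`.
#' @param target_spots a `som_spots` detected on the target model.
#' @return list with `density` (counts per target unit), `bin_counts`
#'   (per spot and background), `dispersion`, `n_genes`.
#' @export
crossmap_genes <- function(genes, target, target_spots) {
  shared <- intersect(genes, names(target$bmu))
  if (!length(shared)) stop("no genes shared with the target model")
  units <- target$bmu[shared]
  U <- prod(target$grid_dims)
  density <- tabulate(units, U)
  n_spots <- length(target_spots$spots)
  bin_of_unit <- seq_len(U) + n_spots        # background units: own bins
  for (i in seq_len(n_spots))
    bin_of_unit[target_spots$spots[[i]]$units] <- i
  spot_units <- if (n_spots) unlist(lapply(target_spots$spots,
                                           function(s) s$units))
                else integer()
  nbins <- n_spots + (U - length(spot_units))
  counts <- tabulate(bin_of_unit[units], n_spots + U)
  spot_counts <- counts[seq_len(n_spots)]
  names(spot_counts) <- names(target_spots$spots)
  p <- counts[counts > 0] / length(shared)
  h <- -sum(p * log(p))
  disp <- if (nbins > 1L) h / log(nbins) else 0
  list(density = density,
       bin_counts = c(spot_counts,
                      background = length(shared) - sum(spot_counts)),
       dispersion = disp, n_genes = length(shared))
}
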