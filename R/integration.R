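#' Expression–methylation covariance map
#'
#' For each unit of the host SOM, the mean over its member genes of the
#' population (1/n) covariance across shared samples between the gene's
#' expression and its promoter beta. Negative pixels mark regions where
#' promoter methylation moves against expression. Units with no gene
#' present in both matrices are flagged invalid.
#'
#' @param host a `som_model` (either layer's map).
#' @param expr gene x sample expression matrix.
#' @param meth gene x sample promoter beta matrix.
#' @return object of class `covariance_map`: `grid` (per-unit mean
#'   covariance), `n_genes` (per-unit shared gene count), `valid`.
#' @export
covariance_map <- function(host, expr, meth) {
  sam <- intersect(colnames(expr), colnames(meth))
  if (length(sam) < 3L) stop("need >= 3 shared samples")
  genes <- intersect(names(host$bmu),
                     intersect(rownames(expr), rownames(meth)))
  if (!length(genes)) stop("no genes shared by host model and both layers")
  e <- expr[genes, sam, drop = FALSE]
  b <- meth[genes, sam, drop = FALSE]
  # per-gene population covariance, vectorized
  gcov <- rowMeans(e * b) - rowMeans(e) * rowMeans(b)
  U <- prod(host$grid_dims)
  val <- rep(NA_real_, U); ng <- integer(U); ok <- logical(U)
  bmu <- host$bmu[genes]
  agg <- rowsum(gcov, bmu)
  cnt <- table(bmu)
  idx <- as.integer(rownames(agg))
  val[idx] <- agg / as.integer(cnt)
  ng[idx] <- as.integer(cnt)
  ok[idx] <- TRUE
  structure(list(grid = matrix(val, host$grid_dims[1L]),
                 n_genes = matrix(ng, host$grid_dims[1L]),
                 valid = matrix(ok, host$grid_dims[1L]),
                 grid_dims = host$grid_dims),
            class = "covariance_map")
}

#' @export
print.covariance_map <- function(x, ...) {
  v <- x$grid[x$valid]
  cat("Expression-methylation covariance map: ", x$grid_dims[1L], " x ",
      x$grid_dims[2L], ", ", sum(x$valid), " valid units, range [",
      format(min(v), digits = 4), ", ", format(max(v), digits = 4),
      "]\n", sep = "")
  invisible(x)
}

#' Coupled expression–methylation spot network
#'
#' Candidate edges are all pairs of one expression spot and one methylation
#' spot. An edge is kept when the spots' gene sets overlap more than
#' expected by chance (one-sided Fisher test, `p < p_max`) AND their
#' per-sample profiles are anti-correlated (`Pearson r < r_max`, default:
#' any negative correlation). All three statistics are reported per kept
#' edge.
#'
#' @param e_spots,m_spots `som_spots` from the expression and methylation
#'   maps.
#' @param universe_size gene universe for the Fisher test (genes present in
#'   both trained models).
#' @param p_max overlap p-value threshold.
#' @param r_max profile correlation threshold.
#' @return object of class `em_network`: `edges` (data.frame e_spot,
#'   m_spot, overlap, odds_ratio, p, r), `candidates` (all pairs with
#'   statistics), `nodes`.
#' @export
build_em_network <- function(e_spots, m_spots, universe_size,
                             p_max = 1e-3, r_max = 0.0) {
  sam <- intersect(colnames(e_spots$profiles), colnames(m_spots$profiles))
  if (!length(sam)) stop("no samples shared between the two layers")
  rows <- list()
  for (ei in names(e_spots$spots))
    for (mi in names(m_spots$spots)) {
      eg <- e_spots$spots[[ei]]$genes
      mg <- m_spots$spots[[mi]]$genes
      fo <- fisher_overlap(eg, mg, universe_size)
      r <- stats::cor(e_spots$profiles[ei, sam], m_spots$profiles[mi, sam])
      rows[[length(rows) + 1L]] <- data.frame(
        e_spot = ei, m_spot = mi, overlap = fo$overlap,
        odds_ratio = fo$odds_ratio, p = fo$p, r = r,
        stringsAsFactors = FALSE)
    }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(e_spot = character(), m_spot = character(),
               overlap = integer(), odds_ratio = numeric(),
               p = numeric(), r = numeric(), stringsAsFactors = FALSE)
  keep <- cand[cand$p < p_max & !is.na(cand$r) & cand$r < r_max, ,
               drop = FALSE]
  rownames(keep) <- NULL
  structure(list(edges = keep, candidates = cand,
                 nodes = data.frame(
                   node = c(paste0("E:", names(e_spots$spots)),
                            paste0("M:", names(m_spots$spots))),
                   layer = rep(c("E", "M"),
                               c(length(e_spots$spots),
                                 length(m_spots$spots))),
                   stringsAsFactors = FALSE),
                 p_max = p_max, r_max = r_max,
                 universe_size = universe_size),
            class = "em_network")
}

#' @export
print.em_network <- function(x, ...) {
  cat("E-M spot network:", nrow(x$edges), "edge(s) kept of",
      nrow(x$candidates), "candidate pair(s) (p <", x$p_max, ", r <",
      x$r_max, ")\n")
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Convert the E–M network to an igraph object / GraphML
#'
#' @param x an `em_network`.
#' @return `em_network_graph`: an igraph graph with layer-tagged vertices.
#' @export
em_network_graph <- function(x) {
  edges <- x$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("E:", edges$e_spot),
               to = paste0("M:", edges$m_spot),
               overlap = edges$overlap, p = edges$p, r = edges$r),
    directed = FALSE, vertices = x$nodes)
  g
}

#' @rdname em_network_graph
#' @param path output GraphML path.
#' @export
write_em_graphml <- function(x, path) {
  igraph::write_graph(em_network_graph(x), path, format = "graphml")
  invisible(path)
}

#' Consensus coupling modules
#'
#' Connected components of the E–M network: the combined regulatory modes
#' linking co-expression and co-methylation spots.
#'
#' @param x an `em_network`.
#' @return list of character vectors of node names, one per component with
#'   at least one edge.
#' @export
em_components <- function(x) {
  if (!nrow(x$edges)) return(list())
  g <- em_network_graph(x)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  cl <- igraph::components(g)
  split(names(cl$membership), cl$membership)
}

#' Sample similarity from metagene vectors
#'
#' Pairwise Pearson correlation between the samples' metagene (codebook
#' column) vectors, an average-linkage dendrogram on `1 - r` for heatmap
#' ordering, and a correlation network connecting each sample to its top-k
#' positively correlated neighbors.
#'
#' @param model a `som_model`.
#' @param k neighbors per sample for the similarity net.
#' @return object of class `som_similarity`: `r` (sample x sample),
#'   `hclust`, `order`, `edges` (data.frame from, to, r), `flagged`
#'   (samples with constant metagene vector).
#' @export
sample_similarity <- function(model, k = 3L) {
  cb <- model$codebook
  if (ncol(cb) < 2L) stop("need >= 2 samples")
  sds <- apply(cb, 2L, stats::sd)
  flagged <- colnames(cb)[sds == 0]
  r <- suppressWarnings(stats::cor(cb))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  edges <- list()
  for (s in colnames(r)) {
    rs <- r[s, setdiff(colnames(r), s)]
    top <- names(sort(rs, decreasing = TRUE))[seq_len(min(k, length(rs)))]
    top <- top[rs[top] > 0]
    for (t in top)
      edges[[length(edges) + 1L]] <- data.frame(
        from = s, to = t, r = rs[[t]], stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), r = numeric())
  # de-duplicate undirected pairs
  key <- apply(edges[, 1:2], 1L, function(p) paste(sort(p), collapse = "|"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(r = r, hclust = hc, order = hc$order, edges = edges,
                 flagged = flagged),
            class = "som_similarity")
}

#' @export
print.som_similarity <- function(x, ...) {
  cat("Sample similarity:", ncol(x$r), "samples,", nrow(x$edges),
      "net edge(s)\n")
  if (length(x$flagged))
    cat("  flagged (constant metagene vector):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Cut the similarity dendrogram into k clusters
#'
#' @param x a `som_similarity`.
#' @param k number of clusters.
#' @return named integer cluster assignment per sample.
#' @export
similarity_clusters <- function(x, k = 2L) {
  stats::cutree(x$hclust, k = k)
}
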