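# lazily computed, cached fixtures shared across test files

.fx <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# small cohort for fast unit tests: 4 identifiable modules, 4 subtypes
small_cohort <- function(seed = 42) {
  fixture(paste0("small_cohort_", seed),
          generate_cohort(cohort_config(
            n_genes = 800, n_samples = 60, n_subtypes = 4, n_modules = 4,
            genes_per_module = 50, seed = seed)))
}

small_centered <- function(seed = 42) {
  fixture(paste0("small_centered_", seed), {
    co <- small_cohort(seed)
    center_genes(quantile_normalize(
      suppressMessages(drop_sex_chromosomes(co$expr, co$annotation))))
  })
}

small_som <- function(seed = 42) {
  fixture(paste0("small_som_", seed),
          train_som(small_centered(seed),
                    som_params(grid_k = 12, epochs = 20, seed = 1)))
}

small_labels <- function(seed = 42) {
  co <- small_cohort(seed)
  stats::setNames(co$phenotype$subtype, co$phenotype$sample_id)
}

# full study-scale analysis of one seed: default cohort conditions, both
# layers trained, spots segmented at the recovery operating point
study_analysis <- function(seed) {
  fixture(paste0("study_", seed), {
    co <- generate_cohort(cohort_config(seed = seed))
    labels <- stats::setNames(co$phenotype$subtype, co$phenotype$sample_id)
    expr_f <- suppressMessages(drop_sex_chromosomes(co$expr, co$annotation))
    expr_c <- center_genes(quantile_normalize(expr_f))
    esom <- train_som(expr_c, som_params(grid_k = 30, epochs = 25, seed = 1))
    meth_g <- suppressMessages(promoter_beta(co$meth, co$annotation))
    meth_g <- suppressMessages(drop_sex_chromosomes(meth_g, co$annotation))
    msom <- train_som(center_genes(meth_g),
                      som_params(grid_k = 30, epochs = 25, seed = 2))
    espots <- detect_spots(overexpression_summary_map(esom, labels), esom,
                           q = 0.95, connectivity = 4)
    mspots <- detect_spots(overexpression_summary_map(msom, labels, "under"),
                           msom, q = 0.95, connectivity = 4,
                           direction = "under")
    list(truth = co$truth, phenotype = co$phenotype, labels = labels,
         expr = co$expr, meth = meth_g, esom = esom, msom = msom,
         espots = espots, mspots = mspots,
         universe = length(intersect(names(esom$bmu), names(msom$bmu))))
  })
}

# minimal hand-built model for segmentation/crossmap hand examples
dummy_model <- function(grid_dims, values = NULL, n_samples = 3L,
                        bmu = NULL) {
  U <- prod(grid_dims)
  cb <- if (is.null(values)) matrix(0, U, n_samples) else values
  if (is.null(colnames(cb))) colnames(cb) <- paste0("s", seq_len(ncol(cb)))
  if (is.null(bmu))
    bmu <- stats::setNames(rep(1L, 1L), "g1")
  ug <- split(names(bmu), factor(bmu, levels = seq_len(U)))
  names(ug) <- NULL
  u <- seq_len(U)
  coords <- cbind(row = ((u - 1L) %% grid_dims[1L]) + 1L,
                  col = ((u - 1L) %/% grid_dims[1L]) + 1L)
  structure(list(codebook = cb, bmu = bmu, unit_genes = ug,
                 qe_history = numeric(), params = list(grid_dims = grid_dims),
                 grid_dims = as.integer(grid_dims), coords = coords,
                 n_genes = length(bmu)),
            class = "som_model")
}

# synthetic truth object for direct survival simulations
make_truth <- function(n_samples, activation, hazard_beta,
                       n_subtypes = ncol(activation)) {
  structure(list(
    module_members = stats::setNames(
      rep(list("none"), nrow(activation)),
      paste0("module", seq_len(nrow(activation)))),
    subtype_of_sample = stats::setNames(rep_len(seq_len(n_subtypes),
                                                n_samples),
                                        sprintf("s%03d", seq_len(n_samples))),
    coupled_modules = character(),
    hazard_beta = hazard_beta,
    activation = activation), class = "synthetic_truth")
}

sample_frame <- function(n) {
  matrix(0, 1, n, dimnames = list("g", sprintf("s%03d", seq_len(n))))
}
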