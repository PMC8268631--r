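#' Configuration for the synthetic paired cohort
#'
#' Describes a bulk cohort of `n_samples` tumours from `n_subtypes` molecular
#' subtypes, with `n_modules` planted modules of co-regulated genes. A
#' module's activity in a sample is the `activation` entry for that sample's
#' subtype (block model, in log10 expression units). A fraction of modules is
#' "coupled": their genes carry promoter methylation anti-correlated with
#' expression activity with slope `coupling_slope` (beta per log10 unit,
#' negative for the canonical repressive coupling). Survival hazard is tied
#' to module activity through per-module log-hazard coefficients.
#'
#' @param n_genes,n_samples,n_subtypes,n_modules,genes_per_module,cpgs_per_gene
#'   positive counts; `genes_per_module * n_modules` must not exceed
#'   `n_genes`.
#' @param activation module x subtype effect-size matrix (log10 units).
#'   Default: each module is activated with effect 1 in one subtype (modules
#'   cycle over subtypes), 0 elsewhere.
#' @param coupled_fraction fraction of modules (from the first) whose genes
#'   receive expression-coupled promoter methylation.
#' @param coupling_slope beta change per log10 expression unit (negative).
#' @param noise_sd_expr,noise_sd_meth gene-level Gaussian noise, in log10
#'   and beta units respectively.
#' @param baseline_beta promoter beta of unmodulated genes, in \[0, 1\].
#' @param hazard_beta per-module log-hazard per unit module activity
#'   (recycled to `n_modules`). Default: log(2) for module 1, 0 otherwise.
#' @param censor_rate target fraction of censored samples.
#' @param sex_gene_fraction fraction of background genes annotated on
#'   chrX/chrY, to exercise the sex-chromosome filter.
#' @param seed integer master seed; same seed, same cohort.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 5000L, n_samples = 120L,
                          n_subtypes = 6L, n_modules = 6L,
                          genes_per_module = 100L,
                          activation = NULL,
                          coupled_fraction = 0.5,
                          coupling_slope = -0.3,
                          noise_sd_expr = 0.4,
                          noise_sd_meth = 0.05,
                          baseline_beta = 0.5,
                          hazard_beta = NULL,
                          censor_rate = 0.3,
                          cpgs_per_gene = 5L,
                          sex_gene_fraction = 0.02,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              n_subtypes = as.integer(n_subtypes),
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              activation = activation,
              coupled_fraction = coupled_fraction,
              coupling_slope = coupling_slope,
              noise_sd_expr = noise_sd_expr,
              noise_sd_meth = noise_sd_meth,
              baseline_beta = baseline_beta,
              hazard_beta = hazard_beta,
              censor_rate = censor_rate,
              cpgs_per_gene = as.integer(cpgs_per_gene),
              sex_gene_fraction = sex_gene_fraction,
              seed = as.integer(seed))
  for (f in c("n_genes", "n_samples", "n_subtypes", "n_modules",
              "genes_per_module", "cpgs_per_gene"))
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("invalid '", f, "': must be a positive count")
  if (cfg$genes_per_module * cfg$n_modules > cfg$n_genes)
    stop("invalid 'genes_per_module': genes_per_module * n_modules ",
         "exceeds n_genes")
  if (is.null(cfg$activation)) {
    a <- matrix(0, cfg$n_modules, cfg$n_subtypes)
    for (m in seq_len(cfg$n_modules))
      a[m, ((m - 1L) %% cfg$n_subtypes) + 1L] <- 1
    cfg$activation <- a
  }
  cfg$activation <- as.matrix(cfg$activation)
  if (!identical(dim(cfg$activation),
                 c(cfg$n_modules, cfg$n_subtypes)))
    stop("invalid 'activation': must be an n_modules x n_subtypes matrix")
  if (cfg$coupled_fraction < 0 || cfg$coupled_fraction > 1)
    stop("invalid 'coupled_fraction': must lie in [0, 1]")
  if (cfg$baseline_beta < 0 || cfg$baseline_beta > 1)
    stop("invalid 'baseline_beta': must lie in [0, 1]")
  if (cfg$noise_sd_expr < 0) stop("invalid 'noise_sd_expr': must be >= 0")
  if (cfg$noise_sd_meth < 0) stop("invalid 'noise_sd_meth': must be >= 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("invalid 'censor_rate': must lie in [0, 1)")
  if (cfg$sex_gene_fraction < 0 || cfg$sex_gene_fraction > 1)
    stop("invalid 'sex_gene_fraction': must lie in [0, 1]")
  if (is.null(cfg$hazard_beta))
    cfg$hazard_beta <- c(log(2), rep(0, cfg$n_modules - 1L))
  cfg$hazard_beta <- rep_len(cfg$hazard_beta, cfg$n_modules)
  class(cfg) <- "cohort_config"
  cfg
}

# promoter window [tss-2000, tss+200] on '+', mirrored on '-'; shared with
# the aggregation stage so generator and preprocessing agree by construction
promoter_window <- function(tss, strand) {
  lo <- ifelse(strand == "+", tss - 2000L, tss - 200L)
  hi <- ifelse(strand == "+", tss + 200L, tss + 2000L)
  cbind(lo, hi)
}

#' Generate a paired expression/methylation cohort with planted truth
#'
#' Expression of gene g in sample s is the sum of activation effects of the
#' modules containing g in s's subtype, plus Gaussian noise. Genes of coupled
#' modules receive per-CpG promoter betas
#' `clamp(baseline_beta + coupling_slope * activity + noise, 0, 1)`; all
#' other genes get baseline plus noise. Each gene receives `cpgs_per_gene`
#' CpGs placed uniformly inside its promoter window. Survival and covariates
#' are generated alongside (see [generate_survival()]).
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `expr` (omics matrix, log10 scale), `meth`
#'   ([cpg_table()]), `annotation` ([gene_annotation()]), `phenotype`
#'   (data.frame with subtype, age, sex, tlr and survival columns) and
#'   `truth` (planted modules, subtype map, coupled module ids, hazard
#'   coefficients, activation matrix).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  set.seed(derive_seed(cfg$seed, 1L))
  G <- cfg$n_genes; n <- cfg$n_samples
  M <- cfg$n_modules; S <- cfg$n_subtypes
  gene_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))
  subtype <- rep_len(seq_len(S), n)

  module_of_gene <- rep(NA_integer_, G)
  module_members <- vector("list", M)
  for (m in seq_len(M)) {
    idx <- ((m - 1L) * cfg$genes_per_module + 1L):(m * cfg$genes_per_module)
    module_of_gene[idx] <- m
    module_members[[m]] <- gene_ids[idx]
  }
  names(module_members) <- paste0("module", seq_len(M))

  # annotation: autosomes cycled; a fraction of the background genes put on
  # chrX/chrY to exercise the sex-chromosome filter
  chrom <- paste0("chr", rep_len(1:22, G))
  bg <- which(is.na(module_of_gene))
  n_sex <- floor(cfg$sex_gene_fraction * G)
  if (n_sex > 0L && length(bg) > 0L) {
    sex_idx <- utils::tail(bg, min(n_sex, length(bg)))
    chrom[sex_idx] <- rep_len(c("chrX", "chrY"), length(sex_idx))
  }
  within_chr <- stats::ave(seq_len(G), chrom, FUN = seq_along)
  tss <- as.integer(within_chr * 100000L + 10000L)
  strand <- rep_len(c("+", "-"), G)
  ann <- gene_annotation(gene_ids, chrom, tss, strand)

  # expression: block signal + iid noise
  act_sample <- cfg$activation[, subtype, drop = FALSE]      # M x n
  expr <- matrix(stats::rnorm(G * n, sd = cfg$noise_sd_expr), G, n,
                 dimnames = list(gene_ids, sample_ids))
  for (m in seq_len(M)) {
    idx <- which(module_of_gene == m)
    expr[idx, ] <- expr[idx, ] +
      rep(act_sample[m, ], each = length(idx))
  }
  expr <- omics_matrix(expr, "expression_log10")

  # methylation: cpgs_per_gene CpGs per gene, uniform in the promoter window
  coupled <- seq_len(round(cfg$coupled_fraction * M))
  if (length(coupled) && max(coupled) > M) coupled <- integer(0)
  win <- promoter_window(ann$tss, ann$strand)
  ncpg <- G * cfg$cpgs_per_gene
  cpg_gene <- rep(seq_len(G), each = cfg$cpgs_per_gene)
  pos <- as.integer(floor(stats::runif(ncpg, win[cpg_gene, 1L],
                                       win[cpg_gene, 2L] + 1)))
  pos <- pmin(pos, win[cpg_gene, 2L])
  cpg_id <- sprintf("cg%07d", seq_len(ncpg))
  betas <- matrix(stats::rnorm(ncpg * n, mean = cfg$baseline_beta,
                               sd = cfg$noise_sd_meth),
                  ncpg, n, dimnames = list(cpg_id, sample_ids))
  for (m in coupled) {
    gidx <- which(module_of_gene == m)
    cidx <- which(cpg_gene %in% gidx)
    betas[cidx, ] <- betas[cidx, ] +
      rep(cfg$coupling_slope * act_sample[m, ], each = length(cidx))
  }
  betas <- clamp01(betas)
  meth <- cpg_table(cpg_id, ann$chromosome[cpg_gene], pos, betas)

  truth <- structure(list(
    module_members = module_members,
    subtype_of_sample = stats::setNames(subtype, sample_ids),
    coupled_modules = names(module_members)[coupled],
    hazard_beta = stats::setNames(cfg$hazard_beta, names(module_members)),
    activation = cfg$activation), class = "synthetic_truth")

  pheno <- data.frame(
    sample_id = sample_ids,
    subtype = paste0("S", subtype),
    age = round(pmin(90, pmax(18, stats::rnorm(n, 50, 10)))),
    sex = sample(c("F", "M"), n, replace = TRUE),
    tlr = exp(stats::rnorm(n, 0, 0.3)),
    stringsAsFactors = FALSE)

  surv <- generate_survival(truth, expr, cfg)
  pheno$surv_time <- surv$time
  pheno$surv_event <- surv$event

  list(expr = expr, meth = meth, annotation = ann,
       phenotype = pheno, truth = truth)
}

#' Generate survival outcomes from planted module activity
#'
#' Survival time is exponential with rate
#' `lambda0 * exp(sum_m hazard_beta[m] * activity_m(s))`, with `lambda0`
#' chosen so that baseline median survival is 5 time units. Censoring is
#' independent Uniform(0, T_c), with `T_c` solved numerically so the
#' expected censored fraction equals `censor_rate`.
#'
#' @param truth the `synthetic_truth` from [generate_cohort()].
#' @param expr the cohort expression matrix (sample names used).
#' @param cfg the [cohort_config()].
#' @return data.frame with `sample_id`, `time` (> 0), `event` (1 = death).
#' @export
generate_survival <- function(truth, expr, cfg) {
  sample_ids <- colnames(expr)
  subtype <- truth$subtype_of_sample[sample_ids]
  activity <- truth$activation[, subtype, drop = FALSE]   # M x n
  lp <- as.numeric(crossprod(activity, as.numeric(truth$hazard_beta)))
  lambda0 <- log(2) / 5
  rate <- lambda0 * exp(lp)
  set.seed(derive_seed(cfg$seed, 2L))
  time <- stats::rexp(length(rate), rate)
  if (cfg$censor_rate <= 0) {
    event <- rep(1L, length(time))
  } else {
    cens_frac <- function(tc) mean((1 - exp(-rate * tc)) / (rate * tc))
    tc <- stats::uniroot(function(x) cens_frac(x) - cfg$censor_rate,
                         lower = 1e-6, upper = 1e6, tol = 1e-10)$root
    cens <- stats::runif(length(time), 0, tc)
    event <- as.integer(time <= cens)
    time <- pmin(time, cens)
  }
  data.frame(sample_id = sample_ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Planted cohort truth:", length(x$module_members), "modules (",
      paste(lengths(x$module_members), collapse = ", "), "genes ),",
      length(unique(x$subtype_of_sample)), "subtypes;",
      length(x$coupled_modules), "methylation-coupled module(s)\n")
  invisible(x)
}
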