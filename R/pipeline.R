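#' Match planted modules against detected spots
#'
#' For every planted module, the best-overlapping detected spot by gene-set
#' Jaccard index — the pipeline's ground-truth recovery summary.
#'
#' @param truth a `synthetic_truth` (or a named list of gene-id vectors).
#' @param spots a `som_spots`.
#' @return data.frame module, best_spot, jaccard, n_module_genes.
#' @export
module_recovery <- function(truth, spots) {
  modules <- if (inherits(truth, "synthetic_truth")) truth$module_members
             else truth
  sets <- spot_gene_sets(spots)
  out <- lapply(names(modules), function(m) {
    mg <- modules[[m]]
    if (!length(sets)) {
      return(data.frame(module = m, best_spot = NA_character_, jaccard = 0,
                        n_module_genes = length(mg),
                        stringsAsFactors = FALSE))
    }
    j <- vapply(sets, function(sg)
      length(intersect(mg, sg)) / length(union(mg, sg)), numeric(1L))
    best <- which.max(j)
    data.frame(module = m, best_spot = names(sets)[best],
               jaccard = j[[best]], n_module_genes = length(mg),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML mirrors [run_pipeline()]'s argument structure: an optional
#' `simulate` block ([cohort_config()] fields), or an `inputs` block with
#' paths (`expr`, `cpg`, `genes`, `pheno`, optional `gmt`), plus optional
#' `som_expr` / `som_meth` ([som_params()] fields), `spots`, `network`
#' blocks, and top-level `out_dir` and `seed`.
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cartography pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> SOM training (E and M
#' layers) -> spot detection -> gene-set scoring -> phenotype maps ->
#' expression–methylation integration, writing all declared outputs under
#' `out_dir` plus a manifest (parameters, per-stage seeds, output files
#' with MD5 checksums, and — when planted truth is available — the module
#' recovery table). Rerunning with the same configuration and seed
#' reproduces byte-identical outputs.
#'
#' @param cfg a `run_config` (see [read_run_config()]) or plain list.
#' @param out_dir output directory (overrides `cfg$out_dir`).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg = list(), out_dir = cfg$out_dir) {
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  files <- character()
  add <- function(f) files <<- c(files, f)

  # --- inputs: simulate or load -------------------------------------------
  truth <- NULL
  if (!is.null(cfg$inputs)) {
    stage("load", {
      expr <- read_omics_tsv(cfg$inputs$expr, "expression_log10")
      meth_cpg <- read_cpg_tsv(cfg$inputs$cpg)
      ann <- read_gene_annotation(cfg$inputs$genes)
      pheno <- read_phenotype_csv(cfg$inputs$pheno)
    })
  } else {
    stage("simulate", {
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      ccfg <- do.call(cohort_config, sim_args)
      cohort <- generate_cohort(ccfg)
      expr <- cohort$expr; meth_cpg <- cohort$meth
      ann <- cohort$annotation; pheno <- cohort$phenotype
      truth <- cohort$truth
      add(write_omics_tsv(expr, file.path(out_dir, "expr.tsv")))
      add(write_cpg_tsv(meth_cpg, file.path(out_dir, "cpg.tsv")))
      utils::write.table(ann, file.path(out_dir, "genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(file.path(out_dir, "genes.tsv"))
      utils::write.csv(pheno, file.path(out_dir, "pheno.csv"),
                       row.names = FALSE, quote = FALSE)
      add(file.path(out_dir, "pheno.csv"))
      jsonlite::write_json(
        list(module_members = truth$module_members,
             subtype_of_sample = as.list(truth$subtype_of_sample),
             coupled_modules = truth$coupled_modules,
             hazard_beta = as.list(truth$hazard_beta)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      add(file.path(out_dir, "truth.json"))
    })
  }

  # --- preprocess ----------------------------------------------------------
  stage("preprocess", {
    expr <- suppressMessages(drop_sex_chromosomes(expr, ann))
    expr <- quantile_normalize(expr)
    meth <- suppressMessages(promoter_beta(meth_cpg, ann))
    meth <- suppressMessages(drop_sex_chromosomes(meth, ann))
    expr_c <- center_genes(expr)
    meth_c <- center_genes(meth)
  })

  # --- SOM training --------------------------------------------------------
  stage("train", {
    pe <- do.call(som_params, utils::modifyList(
      list(grid_k = 50L, seed = derive_seed(seed, 11L)),
      cfg$som_expr %||% list()))
    pm <- do.call(som_params, utils::modifyList(
      list(grid_k = 30L, seed = derive_seed(seed, 12L)),
      cfg$som_meth %||% list()))
    e_som <- train_som(expr_c, pe)
    m_som <- train_som(meth_c, pm)
    for (nm in c("e_som", "m_som")) {
      mod <- get(nm)
      d <- file.path(out_dir, nm)
      dir.create(d, showWarnings = FALSE)
      cb <- mod$codebook
      utils::write.table(
        data.frame(unit = seq_len(nrow(cb)), cb, check.names = FALSE),
        file.path(d, "codebook.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(
        data.frame(gene_id = names(mod$bmu), unit = as.integer(mod$bmu)),
        file.path(d, "bmu.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      yaml::write_yaml(mod$params[c("grid_dims", "epochs", "radius_start",
                                    "radius_end", "init", "seed")],
                       file.path(d, "params.yaml"))
      add(file.path(d, c("codebook.tsv", "bmu.tsv", "params.yaml")))
    }
  })

  # --- spots ---------------------------------------------------------------
  subtype <- stats::setNames(pheno$subtype, pheno$sample_id)
  sp_args <- cfg$spots %||% list()
  stage("spots", {
    spots <- list()
    for (nm in c("e_som", "m_som")) {
      mod <- get(nm)
      summ <- overexpression_summary_map(mod, subtype)
      sp <- do.call(detect_spots, c(list(summary = summ, model = mod),
                                    sp_args))
      spots[[nm]] <- sp
      rows <- lapply(sp$spots, function(s) {
        co <- unit_coords(mod$grid_dims)[s$units, , drop = FALSE]
        ug <- mod$unit_genes[s$units]
        data.frame(spot_id = s$spot_id,
                   unit_row = rep(co[, "row"], lengths(ug)),
                   unit_col = rep(co[, "col"], lengths(ug)),
                   gene_id = unlist(ug, use.names = FALSE),
                   stringsAsFactors = FALSE)
      })
      tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(spot_id = character(), unit_row = integer(),
                   unit_col = integer(), gene_id = character())
      f <- file.path(out_dir, paste0(sub("_som", "", nm), "_spots.tsv"))
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(f)
    }
    calls <- call_spots(spots$e_som, e_som)
    f <- file.path(out_dir, "e_calls.tsv")
    utils::write.table(
      data.frame(spot_id = rownames(calls), calls * 1L,
                 check.names = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
    imp <- spot_implication(calls)
    f <- file.path(out_dir, "e_implication_edges.tsv")
    utils::write.table(imp$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(f)
  })

  # --- gene sets -----------------------------------------------------------
  stage("genesets", {
    sets <- if (!is.null(cfg$inputs$gmt)) read_gmt(cfg$inputs$gmt)
            else if (!is.null(truth)) truth$module_members
            else spot_gene_sets(spots$e_som)
    if (length(sets)) {
      gsz <- gsz_score(sets, expr_c)
      f <- file.path(out_dir, "gsz.tsv")
      utils::write.table(
        data.frame(set = rownames(gsz), gsz, check.names = FALSE),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      add(f)
    }
  })

  # --- phenotype maps ------------------------------------------------------
  stage("phenomaps", {
    surv <- data.frame(sample_id = pheno$sample_id, time = pheno$surv_time,
                       event = pheno$surv_event)
    maps <- list(
      hr = prognostic_map(e_som, surv),
      age = covariate_map(e_som, stats::setNames(pheno$age,
                                                 pheno$sample_id)),
      tlr = covariate_map(e_som, stats::setNames(pheno$tlr,
                                                 pheno$sample_id)),
      sex = female_difference_map(e_som, stats::setNames(pheno$sex,
                                                         pheno$sample_id)))
    for (nm in names(maps)) {
      f <- file.path(out_dir, paste0("phenomap_", nm, ".tsv"))
      utils::write.table(phenotype_map_table(maps[[nm]]), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(f)
    }
  })

  # --- integration ---------------------------------------------------------
  stage("integrate", {
    cm <- covariance_map(e_som, expr, meth)
    co <- unit_coords(cm$grid_dims)
    f <- file.path(out_dir, "covmap.tsv")
    utils::write.table(
      data.frame(unit_row = co[, "row"], unit_col = co[, "col"],
                 covariance = as.numeric(cm$grid),
                 n_genes = as.integer(cm$n_genes),
                 valid = as.logical(cm$valid)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
    universe <- length(intersect(names(e_som$bmu), names(m_som$bmu)))
    net_args <- cfg$network %||% list()
    net <- do.call(build_em_network,
                   c(list(e_spots = spots$e_som, m_spots = spots$m_som,
                          universe_size = universe), net_args))
    f <- file.path(out_dir, "em_edges.tsv")
    utils::write.table(net$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(f)
    f <- file.path(out_dir, "em_network.graphml")
    write_em_graphml(net, f)
    add(f)
  })

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    seed = seed,
    parameters = list(som_expr = cfg$som_expr, som_meth = cfg$som_meth,
                      spots = sp_args, network = cfg$network,
                      simulate = cfg$simulate),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  if (!is.null(truth)) {
    rec_e <- module_recovery(truth, spots$e_som)
    manifest$module_recovery <- rec_e
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
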