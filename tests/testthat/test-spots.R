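test_that("the summary map dominates every group portrait pixel-wise", {
  mod <- small_som()
  lab <- small_labels()
  sm <- overexpression_summary_map(mod, lab)
  for (g in unique(lab))
    expect_true(all(unclass(sm) >=
                    unclass(group_mean_portrait(mod, lab, g)) - 1e-12))
  # a single group's summary is its own mean portrait
  one <- stats::setNames(rep("all", ncol(mod$codebook)),
                         colnames(mod$codebook))
  expect_equal(unclass(overexpression_summary_map(mod, one)),
               unclass(group_mean_portrait(mod, one, "all")),
               ignore_attr = TRUE)
  # under-direction summary is the pixel-wise minimum
  su <- overexpression_summary_map(mod, lab, "under")
  expect_true(all(unclass(su) <=
                  unclass(group_mean_portrait(mod, lab, "S1")) + 1e-12))
})

test_that("a constant map yields no spots and higher q never adds units", {
  mod <- dummy_model(c(6L, 6L),
                     values = matrix(0.3, 36, 2),
                     bmu = stats::setNames(rep(1:36, 2), paste0("g", 1:72)))
  flat <- structure(matrix(0.3, 6, 6), label = "flat",
                    class = c("som_portrait", "matrix"))
  expect_length(detect_spots(flat, mod)$spots, 0)
  # monotonicity of the selected-unit count in q
  set.seed(6)
  g <- structure(matrix(rnorm(36), 6, 6), label = "r",
                 class = c("som_portrait", "matrix"))
  n_units <- sapply(c(0.5, 0.7, 0.9, 0.97), function(q) {
    sp <- detect_spots(g, mod, q = q, min_size = 1)
    sum(vapply(sp$spots, function(s) s$n_units, integer(1)))
  })
  expect_true(all(diff(n_units) <= 0))
})

test_that("two isolated peaks give two single-unit spots labeled by height", {
  v <- matrix(0, 10, 10)
  v[2, 2] <- 5; v[8, 8] <- 4
  bmu <- stats::setNames(sample(100, 200, TRUE), paste0("g", 1:200))
  mod <- dummy_model(c(10L, 10L), values = matrix(0, 100, 2), bmu = bmu)
  po <- structure(v, label = "peaks", class = c("som_portrait", "matrix"))
  sp <- detect_spots(po, mod, q = 0.98, min_size = 1)
  expect_length(sp$spots, 2)
  expect_equal(sp$spots$A$peak, 5)
  expect_equal(sp$spots$B$peak, 4)
  expect_equal(sp$spots$A$n_units, 1L)
  expect_equal(sp$spots$A$units, which(as.numeric(v) == 5))
  # spot genes are the member genes of the spot units
  expect_setequal(sp$spots$A$genes, names(bmu)[bmu == sp$spots$A$units])
})

test_that("spots partition into connected components identical to a graph oracle", {
  an <- study_analysis(1)
  sp <- an$espots
  all_units <- unlist(lapply(sp$spots, function(s) s$units))
  expect_equal(anyDuplicated(all_units), 0L)
  # oracle: igraph connected components over the 8-adjacency of selected units
  k <- an$esom$grid_dims[1]
  sel <- sort(all_units)
  rc <- cbind(((sel - 1) %% k) + 1, ((sel - 1) %/% k) + 1)
  dfun <- if (sp$connectivity == 8L)
    function(i, j) pmax(abs(rc[i, 1] - rc[j, 1]), abs(rc[i, 2] - rc[j, 2]))
  else
    function(i, j) abs(rc[i, 1] - rc[j, 1]) + abs(rc[i, 2] - rc[j, 2])
  adj <- which(outer(seq_along(sel), seq_along(sel), dfun) == 1,
               arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(adj[, 1], adj[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(sel) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # same partition: each detected spot is exactly one oracle component
  # (after discarding components below min_size)
  oracle <- split(sel, comp)
  oracle <- oracle[lengths(oracle) >= sp$min_size]
  canon <- function(l) sort(vapply(l, function(u)
    paste(sort(u), collapse = ","), character(1)))
  expect_equal(canon(unname(oracle)),
               canon(unname(lapply(sp$spots, function(s) s$units))))
})

test_that("4-connectivity splits diagonal contacts that 8-connectivity joins", {
  v <- matrix(0, 4, 4)
  v[1, 1] <- 2; v[2, 2] <- 3
  mod <- dummy_model(c(4L, 4L), values = matrix(0, 16, 2),
                     bmu = stats::setNames(rep(1:16, 2), paste0("g", 1:32)))
  po <- structure(v, label = "diag", class = c("som_portrait", "matrix"))
  expect_length(detect_spots(po, mod, q = 0.8, min_size = 1,
                             connectivity = 8)$spots, 1)
  expect_length(detect_spots(po, mod, q = 0.8, min_size = 1,
                             connectivity = 4)$spots, 2)
})

test_that("spot calls use each sample's own rank threshold", {
  an <- study_analysis(1)
  calls <- call_spots(an$espots, an$esom)
  # a flat sample can never exceed its own quantile
  mod <- an$esom
  mod$codebook[, 1] <- 0.2
  calls_flat <- call_spots(an$espots, mod)
  expect_true(all(!calls_flat[, 1]))
  # invariance to adding a constant to one sample's portrait
  mod2 <- an$esom
  mod2$codebook[, 2] <- mod2$codebook[, 2] + 5
  expect_equal(call_spots(an$espots, mod2)[, 2], calls[, 2])
  # noise is moderate: each subtype's planted spot is called predominantly
  # in its member samples
  rec <- module_recovery(an$truth, an$espots)
  for (i in seq_len(nrow(rec))) {
    sp_id <- rec$best_spot[i]
    st <- an$truth$subtype_of_sample
    active <- names(st)[st == i]
    expect_gt(mean(calls[sp_id, active]), 0.9)
    expect_lt(mean(calls[sp_id, setdiff(colnames(calls), active)]), 0.1)
  }
})

test_that("spot-number histograms count calls per sample within groups", {
  calls <- rbind(A = c(TRUE, TRUE, FALSE, FALSE),
                 B = c(TRUE, FALSE, FALSE, TRUE))
  colnames(calls) <- paste0("s", 1:4)
  lab <- stats::setNames(c("x", "x", "y", "y"), colnames(calls))
  h <- spot_number_distribution(calls, lab)
  expect_equal(unname(h["x", ]), c(0L, 1L, 1L))   # counts 2 and 1
  expect_equal(unname(h["y", ]), c(1L, 1L, 0L))   # counts 0 and 1
  expect_equal(rowSums(h), c(x = 2, y = 2))
  none <- matrix(FALSE, 2, 4, dimnames = dimnames(calls))
  expect_equal(unname(spot_number_distribution(none, lab)[, "0"]), c(2L, 2L))
})

test_that("a cohort planted with two modules per subtype has modal spot count two", {
  # cyclic design: module m active in subtypes m and m+1, so every subtype
  # carries two active modules while module profiles remain distinct
  act <- matrix(0, 3, 3)
  act[cbind(1:3, 1:3)] <- 1
  act[cbind(1:3, c(2, 3, 1))] <- 1
  co <- generate_cohort(cohort_config(
    n_genes = 800, n_samples = 60, n_subtypes = 3, n_modules = 3,
    genes_per_module = 60, activation = act, noise_sd_expr = 0.2,
    seed = 13))
  ec <- center_genes(co$expr)
  mod <- train_som(ec, som_params(grid_k = 12, epochs = 20, seed = 1))
  lab <- stats::setNames(co$phenotype$subtype, co$phenotype$sample_id)
  sp <- detect_spots(overexpression_summary_map(mod, lab), mod,
                     q = 0.9, connectivity = 4)
  h <- spot_number_distribution(call_spots(sp, mod), lab)
  for (g in rownames(h))
    expect_equal(colnames(h)[which.max(h[g, ])], "2")
})

test_that("implication confidences match hand enumeration and threshold logic", {
  calls <- rbind(A = c(TRUE, TRUE, TRUE, FALSE),
                 B = c(FALSE, TRUE, TRUE, FALSE),
                 C = c(FALSE, FALSE, FALSE, FALSE))
  colnames(calls) <- paste0("s", 1:4)
  res <- spot_implication(calls)
  expect_equal(res$uncalled, "C")
  expect_equal(nrow(res$edges), 1)
  expect_equal(res$edges$conf_ab, 2 / 3)
  expect_equal(res$edges$conf_ba, 1)
  # identical call rows: both confidences 1
  dup <- rbind(A = c(TRUE, FALSE, TRUE), B = c(TRUE, FALSE, TRUE))
  colnames(dup) <- paste0("s", 1:3)
  e <- spot_implication(dup)$edges
  expect_equal(c(e$conf_ab, e$conf_ba), c(1, 1))
  # disjoint call sets: no edge
  dis <- rbind(A = c(TRUE, FALSE), B = c(FALSE, TRUE))
  colnames(dis) <- paste0("s", 1:2)
  expect_equal(nrow(spot_implication(dis)$edges), 0)
  expect_error(spot_implication(calls, samples = character()), "empty")
})

test_that("expression-methylation scatter recovers the coupling slope sign", {
  an <- study_analysis(1)
  rec <- module_recovery(an$truth, an$espots)
  coupled <- rec$best_spot[rec$module %in% an$truth$coupled_modules]
  uncoupled <- rec$best_spot[!rec$module %in% an$truth$coupled_modules]
  for (sid in coupled) {
    sc <- spot_expression_methylation_scatter(an$espots, an$expr, an$meth,
                                              an$labels, spot_id = sid)
    expect_equal(nrow(sc), 6)
    expect_lt(coef(lm(mean_beta ~ mean_expr, sc))[2], 0)
  }
  # single group, single gene: the point is that gene's two means
  g1 <- an$espots$spots[[1]]$genes[1]
  tiny <- list(genes = g1, spot_id = "T")
  one <- stats::setNames(rep("all", ncol(an$expr)), colnames(an$expr))
  sc1 <- spot_expression_methylation_scatter(tiny, an$expr, an$meth, one)
  expect_equal(sc1$mean_expr, mean(an$expr[g1, ]))
  expect_equal(sc1$mean_beta, mean(an$meth[g1, colnames(an$meth)]))
})

test_that("uncoupled spots show no systematic scatter slope", {
  # null simulation: replicate small uncoupled cohorts and test the slope t
  reps <- 40
  sig <- vapply(seq_len(reps), function(k) {
    co <- generate_cohort(cohort_config(
      n_genes = 120, n_samples = 48, n_subtypes = 4, n_modules = 1,
      genes_per_module = 30, coupled_fraction = 0, seed = 300 + k))
    mb <- suppressMessages(promoter_beta(co$meth, co$annotation))
    lab <- stats::setNames(co$phenotype$subtype, co$phenotype$sample_id)
    sp <- list(genes = co$truth$module_members$module1)
    sc <- spot_expression_methylation_scatter(sp, co$expr, mb, lab)
    fit <- summary(lm(mean_beta ~ mean_expr, sc))
    fit$coefficients[2, 4] < 0.05
  }, logical(1))
  expect_lt(mean(sig), 0.25)
})

test_that("cross-mapped gene dispersion is entropy-normalized", {
  # 3 single-unit spots + background on a 2x2 target
  bmu <- stats::setNames(1:4, paste0("g", 1:4))
  target <- dummy_model(c(2L, 2L), values = matrix(rnorm(8), 4, 2),
                        bmu = bmu)
  spots <- structure(list(
    spots = list(A = list(spot_id = "A", units = 1L, genes = "g1",
                          peak = 1, n_units = 1L),
                 B = list(spot_id = "B", units = 2L, genes = "g2",
                          peak = 1, n_units = 1L),
                 C = list(spot_id = "C", units = 3L, genes = "g3",
                          peak = 1, n_units = 1L)),
    profiles = matrix(0, 3, 2), threshold = 0, q = 0.98, min_size = 1,
    connectivity = 8, direction = "over", grid_dims = c(2L, 2L)),
    class = "som_spots")
  # all genes in one spot -> dispersion 0
  expect_equal(crossmap_genes(c("g1"), target, spots)$dispersion, 0)
  # uniform over the 4 bins (3 spots + background) -> dispersion 1
  res <- crossmap_genes(paste0("g", 1:4), target, spots)
  expect_equal(res$dispersion, 1)
  expect_equal(unname(res$bin_counts), rep(1L, 4))
  expect_equal(sum(res$density), 4)
  expect_error(crossmap_genes("nope", target, spots), "no genes shared")
})

test_that("coupled module genes melt into compact regions of the counterpart map", {
  an <- study_analysis(1)
  disp <- vapply(names(an$truth$module_members), function(m)
    crossmap_genes(an$truth$module_members[[m]], an$msom,
                   an$mspots)$dispersion, numeric(1))
  coupled <- names(disp) %in% an$truth$coupled_modules
  expect_lt(max(disp[coupled]), min(disp[!coupled]))
})
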