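# independent oracle: naive Breslow log partial likelihood by double loop
naive_breslow <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

toy_fixtures <- list(
  list(time = 1:6, event = rep(1, 6), x = rep(c(0, 1), 3)),
  list(time = c(2, 2, 3, 5, 5, 8), event = c(1, 1, 0, 1, 1, 1),
       x = c(0.5, -1, 2, 0, 1, -0.5)),
  list(time = c(1, 1, 1, 4, 6, 9, 12), event = c(1, 0, 1, 1, 0, 1, 1),
       x = c(2, 1, 0, -1, 3, 1, 0)),
  list(time = c(3, 1, 4, 1, 5, 9, 2, 6), event = c(1, 1, 1, 0, 1, 1, 1, 0),
       x = c(1, 0, 1, 1, 0, 0, 1, 0)))

test_that("Newton Cox estimates maximize the Breslow partial likelihood", {
  for (toy in toy_fixtures) {
    surv <- data.frame(sample_id = paste0("s", seq_along(toy$time)),
                       time = toy$time, event = toy$event)
    fit <- cox_fit(stats::setNames(toy$x, surv$sample_id), surv)
    expect_true(fit$valid)
    # grid-search oracle on the naive likelihood
    grid <- seq(fit$beta - 2, fit$beta + 2, by = 1e-4)
    ll <- vapply(grid, naive_breslow, numeric(1), x = toy$x,
                 time = toy$time, event = toy$event)
    expect_lt(abs(grid[which.max(ll)] - fit$beta), 1e-3)
    # refined: numeric optimum to 1e-6
    opt <- optimize(naive_breslow, c(fit$beta - 1, fit$beta + 1),
                    x = toy$x, time = toy$time, event = toy$event,
                    maximum = TRUE, tol = 1e-9)
    expect_lt(abs(opt$maximum - fit$beta), 1e-6)
    # cross-check against the survival package with Breslow ties
    cph <- survival::coxph(survival::Surv(toy$time, toy$event) ~ toy$x,
                           ties = "breslow")
    expect_equal(fit$beta, unname(coef(cph)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(cph)[1, 1])), tolerance = 1e-5)
  }
})

test_that("degenerate Cox inputs are flagged rather than fitted", {
  surv <- data.frame(sample_id = paste0("s", 1:6), time = 1:6,
                     event = rep(1, 6))
  const <- cox_fit(stats::setNames(rep(2, 6), surv$sample_id), surv)
  expect_false(const$valid)
  expect_equal(const$hr, 1)
  no_events <- data.frame(sample_id = paste0("s", 1:6), time = 1:6,
                          event = rep(0, 6))
  expect_false(cox_fit(stats::setNames(rnorm(6), no_events$sample_id),
                       no_events)$valid)
})

test_that("mean log-HR recovery over replicates brackets the planted effect", {
  tr <- make_truth(500, activation = matrix(c(1, 0), 1, 2),
                   hazard_beta = c(module1 = log(2)))
  ex <- sample_frame(500)
  x <- stats::setNames(tr$activation[1, tr$subtype_of_sample], colnames(ex))
  betas <- vapply(1:100, function(k)
    cox_fit(x, generate_survival(tr, ex, cohort_config(seed = 2000 + k)))$beta,
    numeric(1))
  expect_gt(mean(betas), 0.60)
  expect_lt(mean(betas), 0.79)
})

test_that("the null prognostic map flags about five percent of units", {
  an <- study_analysis(1)
  truth0 <- an$truth
  truth0$hazard_beta[] <- 0
  fr <- vapply(1:2, function(k) {
    s0 <- generate_survival(truth0, an$expr, cohort_config(seed = 500 + k))
    p0 <- prognostic_map(an$esom, s0)
    mean(abs(p0$z[p0$valid]) > 1.96)
  }, numeric(1))
  expect_gt(mean(fr), 0.02)
  expect_lt(mean(fr), 0.09)
})

test_that("an adverse planted module raises its units' hazard and permutation removes it", {
  an <- study_analysis(1)
  surv <- data.frame(sample_id = an$phenotype$sample_id,
                     time = an$phenotype$surv_time,
                     event = an$phenotype$surv_event)
  pm <- prognostic_map(an$esom, surv)
  adverse <- names(which(an$truth$hazard_beta > 0))
  units <- unique(an$esom$bmu[an$truth$module_members[[adverse]]])
  bg <- setdiff(which(pm$valid), units)
  expect_gt(median(pm$grid[units]), 0)
  expect_gt(median(pm$z[units]), median(pm$z[bg]))
  # permuting survival rows destroys the planted association
  set.seed(1)
  perm <- surv
  perm$sample_id <- sample(perm$sample_id)
  pmp <- prognostic_map(an$esom, perm)
  expect_lt(median(abs(pmp$grid[units])), median(abs(pm$grid[units])))
})

test_that("prognostic map needs overlap and flags constant units", {
  an <- study_analysis(1)
  surv <- data.frame(sample_id = paste0("zz", 1:5), time = 1:5,
                     event = rep(1, 5))
  expect_error(prognostic_map(an$esom, surv), ">= 10")
})

test_that("Kaplan-Meier and log-rank match a hand risk-set oracle", {
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time = c(1, 2, 2, 3, 4, 5, 6, 7),
                     event = c(1, 1, 0, 1, 1, 0, 1, 0))
  grp <- stats::setNames(rep(c("a", "b"), 4), surv$sample_id)
  res <- km_logrank(grp, surv)
  # oracle: log-rank observed/expected by naive risk-set loop
  o_a <- 0; e_a <- 0; v <- 0
  for (t in sort(unique(surv$time[surv$event == 1]))) {
    at_risk <- surv$time >= t
    d <- sum(surv$time == t & surv$event == 1)
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp[surv$sample_id] == "a")
    d_a <- sum(surv$time == t & surv$event == 1 &
               grp[surv$sample_id] == "a")
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chi2_oracle <- (o_a - e_a)^2 / v
  expect_equal(res$chi2, chi2_oracle, tolerance = 1e-6)
  expect_equal(res$p, pchisq(chi2_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # KM curves: non-increasing from 1, and the product-limit value at the
  # last event time matches the hand product
  for (g in names(res$curves)) {
    cv <- res$curves[[g]]
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_true(all(cv$surv <= 1))
    hand <- cumprod(1 - cv$n_event / cv$n_risk)
    expect_equal(cv$surv, hand, tolerance = 1e-12)
  }
})

test_that("identical duplicated groups give a null log-rank test", {
  surv <- data.frame(sample_id = paste0("s", 1:10),
                     time = c(1:5, 1:5),
                     event = rep(c(1, 1, 0, 1, 1), 2))
  grp <- stats::setNames(rep(c("a", "b"), each = 5), surv$sample_id)
  res <- km_logrank(grp, surv)
  expect_lt(res$chi2, 1e-10)
  expect_gt(res$p, 0.999)
  expect_error(km_logrank(stats::setNames(rep("a", 10), surv$sample_id),
                          surv), "two non-empty groups")
})

test_that("covariate maps hit the exact correlation limits", {
  mod <- small_som()
  u <- 25L
  x <- mod$codebook[u, ]
  cm <- covariate_map(mod, x)
  expect_equal(cm$grid[u], 1)
  cm_neg <- covariate_map(mod, -x)
  expect_equal(cm_neg$grid[u], -1)
  # constant covariate: all units invalid
  cc <- covariate_map(mod, stats::setNames(rep(1, ncol(mod$codebook)),
                                           colnames(mod$codebook)))
  expect_false(any(cc$valid))
})

test_that("independent covariates give correlations at the null scale", {
  mod <- small_som()
  n <- ncol(mod$codebook)
  set.seed(11)
  mean_abs <- mean(vapply(1:30, function(k) {
    x <- stats::setNames(rnorm(n), colnames(mod$codebook))
    cm <- covariate_map(mod, x)
    mean(abs(cm$grid[cm$valid]))
  }, numeric(1)))
  # E|r| under the null is approximately sqrt(2 / (pi * n))
  expect_lt(abs(mean_abs - sqrt(2 / (pi * n))), 0.35 * sqrt(2 / (pi * n)))
})

test_that("female difference scores behave under construction and permutation", {
  co <- small_cohort()
  mod <- small_som()
  # sex tied to subtype 1: module-1 units should score positive
  st <- co$truth$subtype_of_sample
  sex_linked <- stats::setNames(ifelse(st == 1, "F", "M"), names(st))
  fm <- female_difference_map(mod, sex_linked)
  units <- unique(mod$bmu[co$truth$module_members$module1])
  expect_true(all(fm$grid[units][fm$valid[units]] > 0))
  # sex independent of expression: scores center near zero relative to the
  # sex-linked construction
  set.seed(21)
  null_scores <- vapply(1:20, function(k) {
    sx <- stats::setNames(sample(sex_linked), names(st))
    f0 <- female_difference_map(mod, sx)
    mean(abs(f0$grid[f0$valid]))
  }, numeric(1))
  expect_lt(mean(null_scores), mean(abs(fm$grid[units])))
  # equality point: pct_female_selected == pct_female_all gives exactly 0
  # (paired F/M samples share each metagene value, so any top quartile
  # holds both members of each pair)
  even <- stats::setNames(rep(c("F", "M"), length.out = length(st)),
                          names(st))
  mod0 <- mod
  mod0$codebook[1, ] <- rep(seq_len(ncol(mod0$codebook) / 2), each = 2)
  f0 <- female_difference_map(mod0, even)
  expect_equal(f0$grid[1], 0)
  expect_error(female_difference_map(
    mod, stats::setNames(rep("F", length(st)), names(st))), "both sexes")
})

test_that("phenotype map tables expose coordinates, validity and z", {
  an <- study_analysis(1)
  surv <- data.frame(sample_id = an$phenotype$sample_id,
                     time = an$phenotype$surv_time,
                     event = an$phenotype$surv_event)
  pm <- prognostic_map(an$esom, surv)
  tab <- phenotype_map_table(pm)
  expect_equal(nrow(tab), prod(an$esom$grid_dims))
  expect_equal(tab$value[tab$unit_row == 3 & tab$unit_col == 2],
               pm$grid[3, 2])
})
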