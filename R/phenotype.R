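#' Univariate Cox proportional-hazards fit
#'
#' Maximum partial likelihood for a single continuous covariate by
#' Newton–Raphson with Breslow handling of tied event times. Convergence:
#' `|score| < 1e-8` or 50 iterations (then `valid = FALSE`). Degenerate
#' inputs (fewer than two events, constant covariate) return `valid =
#' FALSE` with HR reported as 1.
#'
#' @param x per-sample covariate, named by sample id or aligned with `surv`.
#' @param surv data.frame with columns `sample_id` (optional when `x` is
#'   unnamed), `time` (> 0) and `event` (0/1).
#' @return list with `beta`, `hr = exp(beta)`, `se`, `z`, `valid`,
#'   `n_events`, `iterations`.
#' @export
cox_fit <- function(x, surv) {
  if (!is.null(names(x)) && !is.null(surv$sample_id)) {
    shared <- intersect(names(x), surv$sample_id)
    surv <- surv[match(shared, surv$sample_id), ]
    x <- x[shared]
  }
  time <- surv$time; event <- as.integer(surv$event)
  n <- length(time)
  invalid <- list(beta = 0, hr = 1, se = NA_real_, z = NA_real_,
                  valid = FALSE, n_events = sum(event), iterations = 0L)
  if (length(x) != n || n < 2L) return(invalid)
  if (sum(event) < 2L) return(invalid)
  if (stats::sd(x) == 0) return(invalid)

  ord <- order(time, decreasing = TRUE)          # risk set = prefix
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  # last index of each tie group in descending order = full risk set at t
  grp_last <- cumsum(rle(time)$lengths)
  grp_of <- rep(seq_along(grp_last), rle(time)$lengths)
  risk_idx <- grp_last[grp_of]                   # per subject

  beta <- 0; it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    w <- exp(beta * x)
    cw <- cumsum(w); cwx <- cumsum(w * x); cwx2 <- cumsum(w * x^2)
    ri <- risk_idx[event == 1L]
    m1 <- cwx[ri] / cw[ri]
    m2 <- cwx2[ri] / cw[ri]
    score <- sum(x[event == 1L] - m1)
    info <- sum(m2 - m1^2)
    if (abs(score) < 1e-8) { converged <- TRUE; break }
    if (it >= 50L || !is.finite(score) || info <= 0) break
    beta <- beta + score / info
  }
  if (!converged) return(invalid)
  se <- 1 / sqrt(info)
  list(beta = beta, hr = exp(beta), se = se, z = beta / se, valid = TRUE,
       n_events = sum(event), iterations = it)
}

# Breslow log partial likelihood (used by the grid-search oracle in tests
# and exported for diagnostics)
#' @rdname cox_fit
#' @param beta coefficient at which to evaluate the Breslow log partial
#'   likelihood.
#' @export
cox_breslow_loglik <- function(beta, x, surv) {
  time <- surv$time; event <- as.integer(surv$event)
  ord <- order(time, decreasing = TRUE)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  grp_last <- cumsum(rle(time)$lengths)
  grp_of <- rep(seq_along(grp_last), rle(time)$lengths)
  risk_idx <- grp_last[grp_of]
  w <- exp(beta * x)
  cw <- cumsum(w)
  sum(beta * x[event == 1L] - log(cw[risk_idx[event == 1L]]))
}

new_phenotype_map <- function(grid, z, valid, statistic, dims) {
  structure(list(grid = matrix(grid, dims[1L]),
                 z = if (!is.null(z)) matrix(z, dims[1L]),
                 valid = matrix(valid, dims[1L]),
                 statistic = statistic, grid_dims = dims),
            class = "phenotype_map")
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat("Phenotype map (", x$statistic, "): ", x$grid_dims[1L], " x ",
      x$grid_dims[2L], ", ", sum(x$valid), "/", length(x$valid),
      " valid units, range [",
      format(min(x$grid[x$valid]), digits = 4), ", ",
      format(max(x$grid[x$valid]), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.phenotype_map <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  g <- x$grid; g[!x$valid] <- NA
  lim <- max(abs(range(g, na.rm = TRUE)), .Machine$double.eps)
  graphics::image(seq_len(ncol(g)), seq_len(nrow(g)), t(g),
                  zlim = c(-lim, lim), col = pal, xlab = "", ylab = "",
                  main = x$statistic, asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' Prognostic map: per-unit Cox log hazard ratio
#'
#' Fits a univariate Cox model per SOM unit, with the unit's metagene
#' values (standardized to unit variance) as continuous covariate, so the
#' stored log HR is per standard deviation of metagene value. Units where
#' the fit is degenerate are flagged invalid, not zeroed.
#'
#' @param model a `som_model`.
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @return `phenotype_map` with statistic `"log_hr"` and per-unit z values.
#' @export
prognostic_map <- function(model, surv) {
  sam <- intersect(colnames(model$codebook), surv$sample_id)
  if (length(sam) < 10L)
    stop("need >= 10 samples shared between model and survival table")
  ss <- surv[match(sam, surv$sample_id), ]
  U <- prod(model$grid_dims)
  loghr <- rep(NA_real_, U); z <- rep(NA_real_, U); ok <- logical(U)
  for (u in seq_len(U)) {
    v <- model$codebook[u, sam]
    s <- stats::sd(v)
    if (s == 0) next
    fit <- cox_fit(stats::setNames((v - mean(v)) / s, sam), ss)
    if (fit$valid) {
      loghr[u] <- fit$beta; z[u] <- fit$z; ok[u] <- TRUE
    }
  }
  new_phenotype_map(loghr, z, ok, "log_hr", model$grid_dims)
}

#' Kaplan–Meier curves and log-rank test for a sample partition
#'
#' Product-limit estimator per group and the k-sample log-rank chi-square,
#' via the survival package.
#'
#' @param groups group label per sample (named by sample id).
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @return list with `curves` (per group: data.frame time, n_risk, n_event,
#'   surv), `chi2`, `df`, `p`.
#' @export
km_logrank <- function(groups, surv) {
  sam <- intersect(names(groups), surv$sample_id)
  ss <- surv[match(sam, surv$sample_id), ]
  grp <- factor(groups[sam])
  if (nlevels(droplevels(grp)) < 2L)
    stop("need at least two non-empty groups")
  sobj <- survival::Surv(ss$time, ss$event)
  sf <- survival::survfit(sobj ~ grp)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- lapply(levels(grp), function(g) {
    i <- strata == paste0("grp=", g)
    data.frame(time = sf$time[i], n_risk = sf$n.risk[i],
               n_event = sf$n.event[i], surv = sf$surv[i])
  })
  names(curves) <- levels(grp)
  sd <- survival::survdiff(sobj ~ grp)
  df <- length(sd$n) - 1L
  list(curves = curves, chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Covariate correlation map
#'
#' Per-unit Pearson correlation between metagene values and a continuous
#' phenotype covariate (age, telomere-length ratio, ...). The stored z is
#' the t statistic of the correlation.
#'
#' @param model a `som_model`.
#' @param x named per-sample covariate.
#' @return `phenotype_map` with statistic `"pearson_r"`.
#' @export
covariate_map <- function(model, x) {
  sam <- intersect(colnames(model$codebook), names(x))
  if (length(sam) < 3L) stop("need >= 3 paired samples")
  xv <- x[sam]
  U <- prod(model$grid_dims)
  r <- rep(NA_real_, U); z <- rep(NA_real_, U); ok <- logical(U)
  if (stats::sd(xv) == 0)
    return(new_phenotype_map(r, z, ok, "pearson_r", model$grid_dims))
  n <- length(sam)
  for (u in seq_len(U)) {
    v <- model$codebook[u, sam]
    if (stats::sd(v) == 0) next
    rr <- stats::cor(v, xv)
    r[u] <- rr; ok[u] <- TRUE
    if (abs(rr) < 1) z[u] <- rr * sqrt((n - 2) / (1 - rr^2))
  }
  new_phenotype_map(r, z, ok, "pearson_r", model$grid_dims)
}

#' Female difference score map
#'
#' Per unit: take the samples whose portrait value at that unit lies in the
#' top quartile (strictly above the nearest-rank 0.75 quantile of the
#' unit's values), and compare the percentage of female patients among them
#' with the cohort-wide percentage, in percent-of-percent:
#' `100 * (pct_female_selected - pct_female_all) / pct_female_all`.
#'
#' @param model a `som_model`.
#' @param sex named per-sample labels, `"F"` / `"M"`.
#' @return `phenotype_map` with statistic `"female_diff"`.
#' @export
female_difference_map <- function(model, sex) {
  sam <- intersect(colnames(model$codebook), names(sex))
  sx <- sex[sam]
  if (length(unique(sx)) < 2L)
    stop("both sexes must be present")
  pct_all <- 100 * mean(sx == "F")
  U <- prod(model$grid_dims)
  score <- rep(NA_real_, U); ok <- logical(U)
  for (u in seq_len(U)) {
    v <- model$codebook[u, sam]
    thr <- nearest_rank_quantile(v, 0.75)
    sel <- v > thr
    if (!any(sel)) next
    pct_sel <- 100 * mean(sx[sel] == "F")
    score[u] <- 100 * (pct_sel - pct_all) / pct_all
    ok[u] <- TRUE
  }
  new_phenotype_map(score, NULL, ok, "female_diff", model$grid_dims)
}

#' Export a phenotype map as a tidy table
#'
#' @param x a `phenotype_map`.
#' @return data.frame unit_row, unit_col, value, valid, z.
#' @export
phenotype_map_table <- function(x) {
  co <- unit_coords(x$grid_dims)
  data.frame(unit_row = co[, "row"], unit_col = co[, "col"],
             value = as.numeric(x$grid), valid = as.logical(x$valid),
             z = if (is.null(x$z)) NA_real_ else as.numeric(x$z))
}
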