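#' Subject-level bootstrap of the required sample size
#'
#' Resamples subjects (not observations) with replacement within one group,
#' refits the random-slope model per replicate, recomputes the continuous
#' per-arm sample size, and summarizes the distribution with a percentile
#' 95% interval. Replicates whose fit does not converge are recorded as
#' missing, not fatal; if more than half fail the result is flagged
#' unusable. Under mechanism `"disease_specific"` a paired control resample
#' is refitted inside every replicate so the uncertainty of the control
#' slope propagates into the interval.
#'
#' @param data Wide per-visit data.frame with a `group` column.
#' @param biomarker Biomarker column to analyse.
#' @param group Treatment group label in `data$group`.
#' @param design A [trial_design()].
#' @param B Bootstrap iterations (>= 2). Default 250.
#' @param seed Integer seed; same seed, same result.
#' @param control_group Control group label (needed for
#'   `mechanism = "disease_specific"`).
#' @return A `bootstrap_result`: `point` (full-data continuous n),
#'   `n_distribution` (length B, `NA` where a replicate failed), `ci_low`,
#'   `ci_high`, `convergence_rate`, `usable`.
#' @export
bootstrap_sample_size <- function(data, biomarker, group, design, B = 250,
                                  seed = 1L, control_group = "control") {
  stopifnot(B >= 2, inherits(design, "trial_design"))
  dg <- data[data$group == group, ]
  ids <- unique(dg$subject_id)
  if (!length(ids)) stop("no subjects in group '", group, "'", call. = FALSE)
  need_control <- design$mechanism == "disease_specific"
  dc <- if (need_control) data[data$group == control_group, ] else NULL
  cids <- if (need_control) unique(dc$subject_id) else NULL
  if (need_control && !length(cids))
    stop("no subjects in control group '", control_group, "'", call. = FALSE)

  n_one <- function(dat, ctrl_dat) {
    fit <- fit_slope_model(dat, value = biomarker,
                           biomarker = biomarker, group = group)
    cfit <- if (need_control)
      fit_slope_model(ctrl_dat, value = biomarker,
                      biomarker = biomarker, group = control_group)
    sample_size_for_fit(fit, design, control_fit = cfit)$n_continuous
  }
  point <- n_one(dg, dc)

  by_id <- split(dg, dg$subject_id)
  cby_id <- if (need_control) split(dc, dc$subject_id)
  set.seed(seed)
  draws <- vapply(seq_len(B), function(b) {
    samp <- resample_subjects(dg, ids, by_id)
    csamp <- if (need_control) resample_subjects(dc, cids, cby_id)
    tryCatch(suppressWarnings(n_one(samp, csamp)),
             error = function(e) NA_real_)
  }, numeric(1))

  ok <- !is.na(draws)
  ci <- if (any(ok)) stats::quantile(draws[ok], c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(
    biomarker = biomarker, group = group, design = design, B = B, seed = seed,
    point = point, n_distribution = draws,
    ci_low = ci[1], ci_high = ci[2],
    convergence_rate = mean(ok), usable = mean(ok) >= 0.5),
    class = "bootstrap_result")
}

# subjects drawn with replacement become distinct subjects in the resample;
# pass a pre-split list (split by subject_id) to avoid rescanning the table
resample_subjects <- function(d, ids, by_id = NULL) {
  if (is.null(by_id)) by_id <- split(d, d$subject_id)
  take <- sample(ids, length(ids), replace = TRUE)
  picked <- by_id[as.character(take)]
  sizes <- vapply(picked, nrow, integer(1))
  out <- do.call(rbind, picked)
  out$subject_id <- rep(sprintf("B%05d", seq_along(take)), sizes)
  rownames(out) <- NULL
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%d replicates) of per-arm n for %s / %s\n",
              x$B, x$biomarker, x$group))
  cat(sprintf("  point %.1f, 95%% CI [%.1f, %.1f], convergence %.0f%%%s\n",
              x$point, x$ci_low, x$ci_high, 100 * x$convergence_rate,
              if (x$usable) "" else "  ** UNUSABLE **"))
  invisible(x)
}

#' Paired bootstrap comparison of two biomarkers' required sample sizes
#'
#' Each replicate draws one subject resample used for both biomarkers, so
#' the per-replicate difference `n_a - n_b` is paired. The two-sided
#' p-value is `2 * min(#{diff <= 0} + 1, #{diff >= 0} + 1) / (B + 1)`,
#' capped at 1; the add-one correction keeps p strictly positive with floor
#' `2 / (B + 1)`.
#'
#' @param data Wide per-visit data.frame with a `group` column; both
#'   biomarkers must be measured on the same subject pool.
#' @param biomarker_a,biomarker_b Biomarker columns to compare.
#' @param group Treatment group label.
#' @param design_a,design_b Trial designs (often differing only in sampling
#'   frequency). `design_b` defaults to `design_a`.
#' @param B,seed,control_group As in [bootstrap_sample_size()].
#' @return A `comparison_result`: `diff_distribution`, `p_value`,
#'   `direction` and convergence accounting.
#' @export
bootstrap_compare <- function(data, biomarker_a, biomarker_b, group,
                              design_a, design_b = design_a, B = 250,
                              seed = 1L, control_group = "control") {
  stopifnot(B >= 2, inherits(design_a, "trial_design"),
            inherits(design_b, "trial_design"))
  dg <- data[data$group == group, ]
  ids <- unique(dg$subject_id)
  need_control <- design_a$mechanism == "disease_specific" ||
    design_b$mechanism == "disease_specific"
  dc <- if (need_control) data[data$group == control_group, ] else NULL
  cids <- if (need_control) unique(dc$subject_id) else NULL

  n_for <- function(dat, ctrl_dat, biomarker, design) {
    fit <- fit_slope_model(dat, value = biomarker,
                           biomarker = biomarker, group = group)
    cfit <- if (design$mechanism == "disease_specific")
      fit_slope_model(ctrl_dat, value = biomarker,
                      biomarker = biomarker, group = control_group)
    sample_size_for_fit(fit, design, control_fit = cfit)$n_continuous
  }

  by_id <- split(dg, dg$subject_id)
  cby_id <- if (need_control) split(dc, dc$subject_id)
  set.seed(seed)
  diffs <- vapply(seq_len(B), function(b) {
    samp <- resample_subjects(dg, ids, by_id)
    csamp <- if (need_control) resample_subjects(dc, cids, cby_id)
    tryCatch(suppressWarnings(
      n_for(samp, csamp, biomarker_a, design_a) -
        n_for(samp, csamp, biomarker_b, design_b)),
      error = function(e) NA_real_)
  }, numeric(1))

  ok <- !is.na(diffs)
  d_ok <- diffs[ok]
  p <- if (length(d_ok))
    min(1, 2 * min(sum(d_ok <= 0) + 1, sum(d_ok >= 0) + 1) / (length(d_ok) + 1))
  else NA_real_
  structure(list(
    biomarker_a = biomarker_a, biomarker_b = biomarker_b, group = group,
    B = B, seed = seed, diff_distribution = diffs, p_value = p,
    direction = if (!length(d_ok) || stats::median(d_ok) == 0) "tied"
                else if (stats::median(d_ok) > 0)
                  paste(biomarker_b, "requires fewer subjects")
                else paste(biomarker_a, "requires fewer subjects"),
    convergence_rate = mean(ok), usable = mean(ok) >= 0.5),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Paired bootstrap (%d replicates): n(%s) - n(%s), %s\n",
              x$B, x$biomarker_a, x$biomarker_b, x$group))
  cat(sprintf("  median diff %.1f, p = %.4g, %s\n",
              stats::median(x$diff_distribution, na.rm = TRUE), x$p_value,
              x$direction))
  invisible(x)
}

#' Monte-Carlo validation of the closed-form power
#'
#' Simulates two-arm trials from the generative random-slope model and
#' estimates power empirically, as an independent check on the closed-form
#' sample-size formula. The control arm progresses at `slope_mean`; the
#' treated arm at `(1 - f) * slope_mean` (mechanism `"full"`) or
#' `slope_mean - f * (slope_mean - control_slope)` (`"disease_specific"`).
#'
#' The default engine (`"slope_z"`) simulates every observation, summarizes
#' each subject by the OLS slope of their own series, and applies the
#' two-sided Wald z test to the arm difference in mean slopes - numerically
#' the same test as the time-by-arm Wald test in the random-slope LME for
#' balanced complete data, at a small fraction of the cost. Engine `"lme"`
#' fits the full `nlme` interaction model per simulated trial (slow; use
#' small `nsim`).
#'
#' @param params_row One generative parameter row (needs `slope_mean`,
#'   `slope_sd`, `resid_sd`, `baseline_sd`, `corr`, `baseline_mean`).
#' @param n Subjects per arm.
#' @param schedule A `visit_schedule` (or visit times in years).
#' @param f Effect fraction in [0, 1]; `f = 0` measures type-I error.
#' @param nsim Simulated trials (>= 100 for a stable estimate; smaller values
#'   are accepted for smoke tests).
#' @param seed Integer seed.
#' @param alpha Two-sided test level. Default 0.05.
#' @param mechanism `"full"` or `"disease_specific"`.
#' @param control_slope Control-group slope, needed for
#'   `"disease_specific"`.
#' @param engine `"slope_z"` (default) or `"lme"`.
#' @return List with `power` (rejection fraction), `se` (binomial SE),
#'   `nsim`, `n`, `engine`.
#' @export
mc_power_validate <- function(params_row, n, schedule, f = 0.30, nsim = 2000,
                              seed = 1L, alpha = 0.05,
                              mechanism = c("full", "disease_specific"),
                              control_slope = NULL,
                              engine = c("slope_z", "lme")) {
  mechanism <- match.arg(mechanism)
  engine <- match.arg(engine)
  if (!inherits(schedule, "visit_schedule")) schedule <- new_visit_schedule(schedule)
  stopifnot(n >= 2, f >= 0, f <= 1, nsim >= 1)
  slope_c <- params_row$slope_mean
  slope_t <- if (mechanism == "full") (1 - f) * slope_c else {
    if (is.null(control_slope))
      stop("mechanism 'disease_specific' needs 'control_slope'", call. = FALSE)
    slope_c - f * (slope_c - control_slope)
  }
  tt <- schedule$times
  J <- length(tt)
  w <- (tt - mean(tt)) / schedule$ssq   # OLS slope weights; sum(w * t) = 1
  n <- as.integer(round(n))
  zcrit <- stats::qnorm(1 - alpha / 2)

  set.seed(seed)
  if (engine == "slope_z") {
    rej <- vapply(seq_len(nsim), function(s) {
      sim_arm <- function(mu) {
        b1 <- stats::rnorm(n, mu, params_row$slope_sd)
        eps <- matrix(stats::rnorm(n * J, 0, params_row$resid_sd), n, J)
        # per-subject OLS slope of the simulated series (intercepts cancel)
        b1 + drop(eps %*% w)
      }
      st <- sim_arm(slope_t); sc <- sim_arm(slope_c)
      z <- (mean(st) - mean(sc)) /
        sqrt(stats::var(st) / n + stats::var(sc) / n)
      abs(z) > zcrit
    }, logical(1))
  } else {
    months <- tt * 12
    rej <- vapply(seq_len(nsim), function(s) {
      sim_arm_long <- function(mu, arm, offset) {
        z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
        b0 <- params_row$baseline_sd * z1
        b1 <- mu + params_row$slope_sd *
          (params_row$corr * z1 + sqrt(1 - params_row$corr^2) * z2)
        data.frame(
          subject_id = rep(sprintf("%s%04d", arm, seq_len(n) + offset),
                           each = J),
          group = arm,
          visit_month = rep(months, n),
          value = params_row$baseline_mean + rep(b0, each = J) +
            rep(b1, each = J) * rep(tt, n) +
            stats::rnorm(n * J, 0, params_row$resid_sd))
      }
      d <- rbind(sim_arm_long(slope_c, "ctrl", 0),
                 sim_arm_long(slope_t, "trt", n))
      ct <- tryCatch(fit_group_interaction(d, "ctrl", "trt"),
                     error = function(e) NULL)
      !is.null(ct) && ct$p_value < alpha
    }, logical(1))
  }
  p_hat <- mean(rej)
  list(power = p_hat, se = sqrt(p_hat * (1 - p_hat) / nsim),
       nsim = nsim, n = n, engine = engine)
}
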