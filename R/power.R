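#' Build a trial visit schedule
#'
#' Constructs the vector of assessment times for a two-arm trial with a
#' baseline visit at time 0 and assessments every `frequency` months up to
#' `duration` months. When `duration` is not a multiple of `frequency` the
#' last visit is the largest attainable multiple; set `anchor_end = TRUE` to
#' force an additional final visit at `duration` itself.
#'
#' @param duration Trial duration in months.
#' @param frequency Months between assessments (0 < frequency <= duration).
#' @param anchor_end Force a final visit at `duration` when the grid does not
#'   reach it. Default `FALSE`.
#' @return An object of class `visit_schedule`: a list with `times` (visit
#'   times in years, including 0), `t_bar` (their mean) and `ssq`, the
#'   sum of squared deviations \eqn{\sum_j (t_j - \bar t)^2} that carries the
#'   trial-design information (duration and sampling frequency) into the
#'   sample-size formula.
#' @examples
#' build_schedule(18, 6)   # 0, 0.5, 1.0, 1.5 years
#' build_schedule(30, 3)   # 11 visits
#' @export
build_schedule <- function(duration, frequency, anchor_end = FALSE) {
  stopifnot(is.numeric(duration), length(duration) == 1L, is.finite(duration),
            is.numeric(frequency), length(frequency) == 1L, is.finite(frequency))
  if (frequency <= 0 || frequency > duration)
    stop("'frequency' must satisfy 0 < frequency <= duration", call. = FALSE)
  months <- seq(0, duration, by = frequency)
  if (anchor_end && max(months) < duration) months <- c(months, duration)
  if (length(months) < 2L)
    stop("schedule has fewer than 2 visits", call. = FALSE)
  new_visit_schedule(months / 12)
}

new_visit_schedule <- function(times_years) {
  times_years <- sort(unique(as.numeric(times_years)))
  if (length(times_years) < 2L)
    stop("a visit schedule needs at least 2 distinct times", call. = FALSE)
  t_bar <- mean(times_years)
  structure(
    list(times = times_years, t_bar = t_bar,
         ssq = sum((times_years - t_bar)^2)),
    class = "visit_schedule"
  )
}

#' @export
print.visit_schedule <- function(x, ...) {
  cat("Visit schedule:", length(x$times), "visits over",
      format(max(x$times) * 12), "months\n")
  cat("  times (years):", paste(format(x$times), collapse = ", "), "\n")
  cat("  sum (t_j - t_bar)^2 =", format(x$ssq), "years^2\n")
  invisible(x)
}

#' Sum of squared time deviations of a schedule
#'
#' @param times Numeric vector of visit times in years (>= 2 values), or a
#'   `visit_schedule`.
#' @return \eqn{\sum_j (t_j - \bar t)^2} in years squared.
#' @export
schedule_ssq <- function(times) {
  if (inherits(times, "visit_schedule")) return(times$ssq)
  stopifnot(is.numeric(times), length(times) >= 2L, all(is.finite(times)))
  sum((times - mean(times))^2)
}

#' Detectable slope difference under a fractional treatment effect
#'
#' The treatment effect is modelled as a `f` (default 30%) reduction of the
#' expected longitudinal progression, so the slope difference the trial must
#' detect is `f` times the relevant progression slope: the group-average slope
#' itself (mechanism `"full"`, progression can be reduced to zero) or the
#' group-minus-control slope (mechanism `"disease_specific"`, progression can
#' at most be reduced to the level of normal aging). The magnitude is
#' returned; the sign is irrelevant because the difference enters the
#' sample-size formula squared.
#'
#' @param slope_for_delta Progression slope (units/year) from
#'   [extract_power_inputs()].
#' @param f Effect fraction in (0, 1].
#' @return Detectable difference `delta` in units/year (>= 0).
#' @export
detectable_delta <- function(slope_for_delta, f = 0.30) {
  stopifnot(is.numeric(slope_for_delta), length(slope_for_delta) == 1L,
            is.finite(slope_for_delta),
            is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  if (slope_for_delta == 0)
    stop("slope is exactly zero: no detectable effect, required n is infinite",
         call. = FALSE)
  f * abs(slope_for_delta)
}

#' Per-arm sample size for detecting a slope difference
#'
#' Required subjects per arm for a two-arm trial analysed with a
#' random-intercept/random-slope linear mixed model:
#' \deqn{n = \frac{2\,(\sigma_b^2 + \sigma_w^2 / \sum_j (t_j-\bar t)^2)\,
#'   (z_{1-\alpha/2} + z_{1-\beta})^2}{\Delta^2}}
#' where \eqn{\sigma_w^2} is the within-subject (residual) variance,
#' \eqn{\sigma_b^2} the between-subject variance of individual slopes, and
#' \eqn{\Delta} the slope difference to detect. The bracketed variance term is
#' the sampling variance of one subject's estimated slope, so the formula is
#' the classical two-sample normal formula applied to subject-level slopes.
#'
#' @param sigma_w_sq Within-subject residual variance (units^2).
#' @param sigma_b_sq Between-subject slope variance (units^2/year^2).
#' @param schedule A `visit_schedule` (or numeric visit times in years).
#' @param delta Detectable slope difference, units/year (> 0).
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power, default 0.80.
#' @return An object of class `sample_size_result` with `n_continuous`
#'   (real-valued per-arm n), `n_per_arm` (its ceiling) and an echo of all
#'   inputs including the normal quantiles used.
#' @examples
#' sch <- build_schedule(18, 6)
#' n_per_arm(sigma_w_sq = 1.0, sigma_b_sq = 0.1, schedule = sch, delta = 0.3)
#' @export
n_per_arm <- function(sigma_w_sq, sigma_b_sq, schedule, delta,
                      alpha = 0.05, power = 0.80) {
  if (!inherits(schedule, "visit_schedule")) schedule <- new_visit_schedule(schedule)
  stopifnot(is.numeric(sigma_w_sq), sigma_w_sq >= 0,
            is.numeric(sigma_b_sq), sigma_b_sq >= 0,
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (sigma_w_sq == 0 && sigma_b_sq == 0)
    stop("both variance components are zero", call. = FALSE)
  if (delta <= 0)
    stop("'delta' must be > 0 (a zero effect cannot be powered)", call. = FALSE)
  z_alpha <- stats::qnorm(1 - alpha / 2)
  z_beta <- stats::qnorm(power)
  slope_var <- sigma_b_sq + sigma_w_sq / schedule$ssq
  n_cont <- 2 * slope_var * (z_alpha + z_beta)^2 / delta^2
  structure(
    list(n_continuous = n_cont,
         n_per_arm = max(1L, as.integer(ceiling(n_cont - 1e-12))),
         sigma_w_sq = sigma_w_sq, sigma_b_sq = sigma_b_sq,
         delta = delta, alpha = alpha, power = power,
         z_alpha = z_alpha, z_beta = z_beta,
         schedule = schedule),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("Per-arm sample size:", x$n_per_arm,
      sprintf("(continuous %.2f)\n", x$n_continuous))
  cat(sprintf("  sigma_w^2 = %.4g, sigma_b^2 = %.4g, delta = %.4g /yr\n",
              x$sigma_w_sq, x$sigma_b_sq, x$delta))
  cat(sprintf("  alpha = %g (two-sided), power = %g, %d visits, ssq = %.4g yr^2\n",
              x$alpha, x$power, length(x$schedule$times), x$schedule$ssq))
  invisible(x)
}

#' Power achieved at a given per-arm sample size
#'
#' Inverts the sample-size formula: with `n` subjects per arm the power to
#' detect a slope difference `delta` is
#' \eqn{\Phi(\Delta \sqrt{n / (2 (\sigma_b^2+\sigma_w^2/ssq))} - z_{1-\alpha/2})},
#' the dominant-tail normal approximation (the neglected opposite tail is
#' below 1e-6 in any realistic regime). Round-trips with [n_per_arm()]:
#' evaluating at `n_continuous` returns the target power to 1e-9.
#'
#' @param n Subjects per arm (>= 1, may be non-integer).
#' @inheritParams n_per_arm
#' @return Power in (0, 1).
#' @export
power_at_n <- function(n, sigma_w_sq, sigma_b_sq, schedule, delta,
                       alpha = 0.05) {
  if (!inherits(schedule, "visit_schedule")) schedule <- new_visit_schedule(schedule)
  stopifnot(is.numeric(n), all(n >= 1),
            sigma_w_sq >= 0, sigma_b_sq >= 0, delta >= 0,
            alpha > 0, alpha < 1)
  if (sigma_w_sq == 0 && sigma_b_sq == 0)
    stop("both variance components are zero", call. = FALSE)
  slope_var <- sigma_b_sq + sigma_w_sq / schedule$ssq
  stats::pnorm(delta * sqrt(n / (2 * slope_var)) - stats::qnorm(1 - alpha / 2))
}

#' Trial design description
#'
#' Bundles the design knobs of one powered comparison: duration, sampling
#' frequency, two-sided alpha, target power, effect fraction and the assumed
#' treatment mechanism.
#'
#' @param duration Trial duration, months.
#' @param frequency Months between assessments.
#' @param alpha Two-sided type-I error. Default 0.05.
#' @param power Target power. Default 0.80.
#' @param effect_fraction Fractional reduction in progression the treatment is
#'   assumed to produce. Default 0.30.
#' @param mechanism `"full"` (progression reducible to zero; delta is a
#'   fraction of the group slope) or `"disease_specific"` (progression
#'   reducible at most to normal-aging levels; delta is a fraction of the
#'   group-minus-control slope).
#' @param anchor_end Passed to [build_schedule()].
#' @return A `trial_design` list with the validated fields and the derived
#'   `schedule`.
#' @export
trial_design <- function(duration, frequency, alpha = 0.05, power = 0.80,
                         effect_fraction = 0.30,
                         mechanism = c("full", "disease_specific"),
                         anchor_end = FALSE) {
  mechanism <- match.arg(mechanism)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            effect_fraction > 0, effect_fraction <= 1)
  structure(
    list(duration = duration, frequency = frequency, alpha = alpha,
         power = power, effect_fraction = effect_fraction,
         mechanism = mechanism,
         schedule = build_schedule(duration, frequency, anchor_end)),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %g months, assessments every %g months, %s mechanism\n",
              x$duration, x$frequency, x$mechanism))
  cat(sprintf("  alpha = %g, power = %g, effect fraction = %g\n",
              x$alpha, x$power, x$effect_fraction))
  invisible(x)
}

#' Sample size for one fitted biomarker under a trial design
#'
#' Convenience wrapper: takes the treatment-group fit (and the control fit
#' when the mechanism is disease-specific), extracts the power inputs, builds
#' the detectable difference and evaluates [n_per_arm()].
#'
#' @param fit `lme_fit` for the treatment group.
#' @param design A [trial_design()].
#' @param control_fit `lme_fit` for the control group (required for
#'   mechanism `"disease_specific"`).
#' @param force Use non-converged fits anyway. Default `FALSE`.
#' @return A `sample_size_result`.
#' @export
sample_size_for_fit <- function(fit, design, control_fit = NULL, force = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  pin <- extract_power_inputs(fit, control_fit, design$mechanism, force = force)
  delta <- detectable_delta(pin$slope_for_delta, design$effect_fraction)
  if (design$mechanism == "disease_specific" && !is.null(control_fit) &&
      sign(pin$slope_for_delta) != 0 &&
      sign(fit$beta1) != 0 && sign(pin$slope_for_delta) != sign(fit$beta1))
    warning("disease-specific slope has opposite sign to the group slope ",
            "(group progresses slower than controls)", call. = FALSE)
  n_per_arm(pin$sigma_w_sq, pin$sigma_b_sq, design$schedule, delta,
            alpha = design$alpha, power = design$power)
}

#' Sweep trial duration and sampling frequency across biomarkers
#'
#' Evaluates the per-arm sample size over a grid of durations and sampling
#' frequencies for each fitted biomarker, and reports each cell's ratio to a
#' reference biomarker evaluated at the same duration but at its own fixed
#' sampling frequency (the reference is typically plasma NfL sampled monthly,
#' with MRI/cognition frequencies varied). The ratio is
#' `n_reference / n_biomarker`, so values above 1 mean the biomarker needs
#' fewer subjects than the reference.
#'
#' @param fits Named list of `lme_fit` objects (one per biomarker), the
#'   treatment-group fits.
#' @param durations Numeric vector of trial durations, months.
#' @param frequencies Numeric vector of sampling frequencies, months, applied
#'   to every non-reference biomarker.
#' @param reference Name (in `fits`) of the reference biomarker.
#' @param reference_frequency Fixed sampling frequency of the reference,
#'   months. Default 1.
#' @param control_fits Named list of control-group fits, required when
#'   `mechanism = "disease_specific"`.
#' @param effect_fraction,alpha,power,mechanism Passed to [trial_design()].
#' @return A data.frame with one row per (biomarker, duration, frequency):
#'   `n_continuous`, `n_per_arm`, the reference n at that duration, and
#'   `ratio`. Cells whose computation fails (e.g. a non-converged fit) carry
#'   `NA` and the error message; the grid is never aborted by one cell.
#' @export
sweep_designs <- function(fits, durations, frequencies, reference,
                          reference_frequency = 1,
                          control_fits = NULL,
                          effect_fraction = 0.30, alpha = 0.05, power = 0.80,
                          mechanism = c("full", "disease_specific")) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.list(fits), !is.null(names(fits)), reference %in% names(fits))
  cell_n <- function(biomarker, duration, frequency) {
    tryCatch({
      des <- trial_design(duration, frequency, alpha = alpha, power = power,
                          effect_fraction = effect_fraction,
                          mechanism = mechanism)
      cf <- if (mechanism == "disease_specific") control_fits[[biomarker]]
      res <- sample_size_for_fit(fits[[biomarker]], des, control_fit = cf)
      list(n = res$n_continuous, err = NA_character_)
    }, error = function(e) list(n = NA_real_, err = conditionMessage(e)))
  }
  ref_n <- vapply(durations, function(d)
    cell_n(reference, d, reference_frequency)$n, numeric(1))
  names(ref_n) <- as.character(durations)

  grid <- expand.grid(biomarker = names(fits), duration = durations,
                      frequency = frequencies,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- Map(function(b, d, f) {
    if (b == reference) cell_n(b, d, reference_frequency) else cell_n(b, d, f)
  }, grid$biomarker, grid$duration, grid$frequency)
  grid$n_continuous <- vapply(cells, `[[`, numeric(1), "n")
  grid$n_per_arm <- ceiling(grid$n_continuous)
  grid$n_reference <- ref_n[as.character(grid$duration)]
  grid$ratio <- grid$n_reference / grid$n_continuous
  grid$error <- vapply(cells, `[[`, character(1), "err")
  rownames(grid) <- NULL
  grid
}
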