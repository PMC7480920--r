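#' @importFrom nlme lme lmeControl pdDiag getVarCov VarCorr fixef
NULL

# Common model frame: subject, time in years, response. Accepts visit_month
# (months) or time_years; drops rows with a missing response.
prepare_model_frame <- function(data, value = "value", extra = NULL) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data),
            value %in% names(data))
  if ("time_years" %in% names(data)) {
    t_years <- data$time_years
  } else if ("visit_month" %in% names(data)) {
    t_years <- data$visit_month / 12
  } else stop("data needs a 'visit_month' or 'time_years' column", call. = FALSE)
  d <- data.frame(subject = factor(data$subject_id), t = t_years,
                  y = data[[value]])
  for (col in extra) d[[col]] <- data[[col]]
  d <- d[!is.na(d$y) & is.finite(d$t), ]
  droplevels(d)
}

new_lme_fit <- function(beta0, beta1, se_beta1, sigma_b0_sq, sigma_b1_sq,
                        cov_b0b1, sigma_w_sq, n_subjects, n_obs, converged,
                        method, biomarker = NA_character_,
                        group = NA_character_) {
  # clamp tiny negative variances and an out-of-range covariance arising from
  # floating-point extraction
  sigma_b0_sq <- max(0, sigma_b0_sq)
  sigma_b1_sq <- max(0, sigma_b1_sq)
  sigma_w_sq <- max(0, sigma_w_sq)
  bound <- sqrt(sigma_b0_sq * sigma_b1_sq)
  if (is.finite(bound)) cov_b0b1 <- max(-bound, min(bound, cov_b0b1))
  structure(
    list(beta0 = beta0, beta1 = beta1, se_beta1 = se_beta1,
         sigma_b0_sq = sigma_b0_sq, sigma_b1_sq = sigma_b1_sq,
         cov_b0b1 = cov_b0b1, sigma_w_sq = sigma_w_sq,
         n_subjects = n_subjects, n_obs = n_obs,
         converged = converged, method = method,
         biomarker = biomarker, group = group),
    class = "lme_fit"
  )
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("Random-slope LME fit [%s]%s\n", x$method,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  if (!is.na(x$biomarker)) cat("  biomarker:", x$biomarker,
                               " group:", x$group, "\n")
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g /yr (se %.3g)\n",
              x$beta0, x$beta1, x$se_beta1))
  cat(sprintf("  sigma_w^2 = %.4g, sigma_b1^2 = %.4g, sigma_b0^2 = %.4g, cov = %.4g\n",
              x$sigma_w_sq, x$sigma_b1_sq, x$sigma_b0_sq, x$cov_b0b1))
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  invisible(x)
}

# Per-subject OLS slopes/intercepts; the degenerate exact-fit path and the
# moment fallback both use these.
subject_ols <- function(d) {
  by_subj <- split(d, d$subject)
  out <- lapply(by_subj, function(s) {
    if (length(unique(s$t)) < 2L)
      return(c(b0 = NA_real_, b1 = NA_real_, rss = NA_real_, df = 0))
    f <- stats::lm.fit(cbind(1, s$t), s$y)
    c(b0 = unname(f$coefficients[1]), b1 = unname(f$coefficients[2]),
      rss = sum(f$residuals^2), df = max(0L, nrow(s) - 2L))
  })
  as.data.frame(do.call(rbind, out))
}

#' Fit the per-biomarker random-slope longitudinal model
#'
#' Fits \eqn{y_{ij} = \beta_0 + \beta_1 t_{ij} + b_{0i} + b_{1i} t_{ij} +
#' \epsilon_{ij}} by REML (via `nlme::lme`) for one biomarker in one group,
#' with an unstructured 2x2 random-effect covariance, and returns the
#' variance components the sample-size formula needs: the within-subject
#' residual variance \eqn{\sigma_w^2} and the between-subject slope variance
#' \eqn{\sigma_{b1}^2}. Time enters in years, so slopes are per year.
#'
#' Non-convergence is handled by a fallback ladder: unstructured covariance
#' (two optimizers), then a diagonal random-effect covariance, then random
#' intercept only (slope variance fixed at zero); the `method` tag records
#' which rung succeeded. Data that a mixed model cannot identify at all
#' (e.g. noise-free lines) are detected up front and returned as an exact
#' moment fit. If every rung fails, moment estimates from per-subject OLS
#' lines are returned with `converged = FALSE`; downstream operations refuse
#' such fits unless forced.
#'
#' @param data Data.frame with `subject_id`, `visit_month` (months) or
#'   `time_years`, and the response column.
#' @param value Name of the response column. Default `"value"`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param covariates Optional character vector of additional fixed-effect
#'   columns in `data` (off by default).
#' @param biomarker,group Optional labels carried into the result.
#' @return An `lme_fit` object.
#' @export
fit_slope_model <- function(data, value = "value", method = c("REML", "ML"),
                            covariates = NULL,
                            biomarker = NA_character_, group = NA_character_) {
  method <- match.arg(method)
  d <- prepare_model_frame(data, value, extra = covariates)
  n_subj <- nlevels(d$subject)
  obs_per <- table(d$subject)
  if (n_subj < 2L || sum(obs_per >= 2L) < 2L)
    stop("need >= 2 subjects with >= 2 observations each", call. = FALSE)

  ols <- subject_ols(d)
  y_scale <- max(stats::sd(d$y), 1e-8)
  # exact-fit degeneracy: every subject lies on a line and slopes are
  # (numerically) constant -- a mixed model is unidentifiable here
  ok <- stats::complete.cases(ols)
  degenerate <- all(ols$rss[ok] <= (1e-7 * y_scale)^2 * pmax(1, ols$df[ok])) &&
    stats::sd(ols$b1[ok]) < 1e-7 * max(1, abs(mean(ols$b1[ok])))
  if (degenerate) {
    b1 <- mean(ols$b1[ok]); b0 <- mean(ols$b0[ok])
    return(new_lme_fit(
      beta0 = b0, beta1 = b1, se_beta1 = 0,
      sigma_b0_sq = stats::var(ols$b0[ok]), sigma_b1_sq = 0, cov_b0b1 = 0,
      sigma_w_sq = 0, n_subjects = n_subj, n_obs = nrow(d),
      converged = TRUE, method = "degenerate_exact",
      biomarker = biomarker, group = group))
  }

  fixed <- if (is.null(covariates)) y ~ t else
    stats::reformulate(c("t", covariates), response = "y")
  attempts <- list(
    list(opt = "nlminb", tag = "unstructured"),
    list(opt = "optim", tag = "unstructured"),
    list(opt = "nlminb", tag = "diagonal"),
    list(opt = "nlminb", tag = "intercept_only")
  )
  fit <- NULL; tag <- NULL
  for (a in attempts) {
    ctrl <- lmeControl(opt = a$opt, maxIter = 200, msMaxIter = 200,
                       niterEM = 50, returnObject = FALSE)
    f <- tryCatch(switch(a$tag,
      unstructured = lme(fixed, data = d, random = ~ t | subject,
                         method = method, control = ctrl),
      diagonal = lme(fixed, data = d, random = list(subject = pdDiag(~ t)),
                     method = method, control = ctrl),
      intercept_only = lme(fixed, data = d, random = ~ 1 | subject,
                           method = method, control = ctrl)),
      error = function(e) NULL)
    if (!is.null(f)) { fit <- f; tag <- a$tag; break }
  }

  if (is.null(fit)) {
    # moment fallback from per-subject OLS; flagged non-converged
    b1s <- ols$b1[ok]
    sw <- sum(ols$rss[ok]) / max(1, sum(ols$df[ok]))
    return(new_lme_fit(
      beta0 = mean(ols$b0[ok]), beta1 = mean(b1s),
      se_beta1 = stats::sd(b1s) / sqrt(length(b1s)),
      sigma_b0_sq = stats::var(ols$b0[ok]),
      sigma_b1_sq = max(0, stats::var(b1s)), cov_b0b1 = 0,
      sigma_w_sq = sw, n_subjects = n_subj, n_obs = nrow(d),
      converged = FALSE, method = "ols_moments",
      biomarker = biomarker, group = group))
  }

  fe <- fixef(fit)
  vcv <- tryCatch(getVarCov(fit), error = function(e) NULL)
  if (tag == "intercept_only") {
    sb0 <- if (is.null(vcv)) as.numeric(VarCorr(fit)[1, "Variance"]) else vcv[1, 1]
    sb1 <- 0; cov01 <- 0
  } else {
    sb0 <- vcv["(Intercept)", "(Intercept)"]
    sb1 <- vcv["t", "t"]
    cov01 <- if (tag == "diagonal") 0 else vcv["(Intercept)", "t"]
  }
  new_lme_fit(
    beta0 = unname(fe["(Intercept)"]), beta1 = unname(fe["t"]),
    se_beta1 = sqrt(fit$varFix["t", "t"]),
    sigma_b0_sq = sb0, sigma_b1_sq = sb1, cov_b0b1 = cov01,
    sigma_w_sq = fit$sigma^2,
    n_subjects = n_subj, n_obs = nrow(d),
    converged = TRUE,
    method = paste0(tolower(method), "_", tag),
    biomarker = biomarker, group = group)
}

#' Group-by-time interaction contrast
#'
#' Fits `y ~ group * time` with random intercept and slope per subject and
#' returns the slope difference (group-by-time interaction) and the baseline
#' difference between two groups, with two-sided Wald p-values (normal
#' approximation).
#'
#' @param data Data.frame with `subject_id`, `visit_month`/`time_years`,
#'   a `group` column and the response.
#' @param group_a,group_b Group labels to contrast; the contrast is
#'   `group_b - group_a` (put the control group first).
#' @param value Response column name.
#' @param method `"REML"` or `"ML"`.
#' @return A `group_contrast` list: `delta_beta` (slope difference,
#'   units/year), `se`, `p_value`, `baseline_diff`, `baseline_se`,
#'   `baseline_p`, `converged`, `method`.
#' @export
fit_group_interaction <- function(data, group_a, group_b, value = "value",
                                  method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot("group" %in% names(data))
  data <- data[data$group %in% c(group_a, group_b), ]
  if (!nrow(data)) stop("no rows in the requested groups", call. = FALSE)
  d <- prepare_model_frame(data, value, extra = "group")
  d$grp <- factor(d$group, levels = c(group_a, group_b))
  if (any(table(d$grp) == 0)) stop("both groups must be non-empty", call. = FALSE)

  attempts <- list(list(random = ~ t | subject, tag = "unstructured"),
                   list(random = "diag", tag = "diagonal"),
                   list(random = ~ 1 | subject, tag = "intercept_only"))
  fit <- NULL; tag <- NULL
  for (a in attempts) {
    ctrl <- lmeControl(opt = "nlminb", maxIter = 200, msMaxIter = 200,
                       returnObject = FALSE)
    f <- tryCatch(
      if (identical(a$random, "diag"))
        lme(y ~ grp * t, data = d, random = list(subject = pdDiag(~ t)),
            method = method, control = ctrl)
      else
        lme(y ~ grp * t, data = d, random = a$random, method = method,
            control = ctrl),
      error = function(e) NULL)
    if (!is.null(f)) { fit <- f; tag <- a$tag; break }
  }
  if (is.null(fit)) stop("interaction model did not converge on any ladder rung",
                         call. = FALSE)
  fe <- fixef(fit); V <- fit$varFix
  int_term <- grep(":t$", names(fe), value = TRUE)
  grp_term <- setdiff(grep("^grp", names(fe), value = TRUE), int_term)
  db <- unname(fe[int_term]); se <- sqrt(V[int_term, int_term])
  bg <- unname(fe[grp_term]); bse <- sqrt(V[grp_term, grp_term])
  structure(list(
    group_a = group_a, group_b = group_b,
    delta_beta = db, se = se,
    p_value = 2 * stats::pnorm(-abs(db / se)),
    baseline_diff = bg, baseline_se = bse,
    baseline_p = 2 * stats::pnorm(-abs(bg / bse)),
    converged = TRUE, method = paste0(tolower(method), "_", tag)),
    class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Group contrast %s - %s\n", x$group_b, x$group_a))
  cat(sprintf("  slope difference: %.4g /yr (se %.3g), p = %.3g\n",
              x$delta_beta, x$se, x$p_value))
  cat(sprintf("  baseline difference: %.4g (se %.3g), p = %.3g\n",
              x$baseline_diff, x$baseline_se, x$baseline_p))
  invisible(x)
}

#' Extract the power-formula inputs from fitted models
#'
#' Pulls \eqn{\sigma_w^2}, \eqn{\sigma_b^2} (the slope random-effect
#' variance only) and the progression slope that defines the detectable
#' difference: the treatment-group slope under mechanism `"full"`, or the
#' treatment-minus-control slope under mechanism `"disease_specific"`.
#'
#' @param fit `lme_fit` for the treatment group.
#' @param control_fit `lme_fit` for the control group, required for
#'   `"disease_specific"`.
#' @param mechanism `"full"` or `"disease_specific"`.
#' @param force Accept non-converged fits. Default `FALSE`.
#' @return List with `sigma_w_sq`, `sigma_b_sq`, `slope_for_delta`.
#' @export
extract_power_inputs <- function(fit, control_fit = NULL,
                                 mechanism = c("full", "disease_specific"),
                                 force = FALSE) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(fit, "lme_fit"))
  if (!fit$converged && !force)
    stop("fit did not converge; pass force = TRUE to use it anyway",
         call. = FALSE)
  slope <- if (mechanism == "full") {
    fit$beta1
  } else {
    if (is.null(control_fit))
      stop("mechanism 'disease_specific' needs a control-group fit",
           call. = FALSE)
    stopifnot(inherits(control_fit, "lme_fit"))
    if (!control_fit$converged && !force)
      stop("control fit did not converge; pass force = TRUE to use it anyway",
           call. = FALSE)
    fit$beta1 - control_fit$beta1
  }
  list(sigma_w_sq = fit$sigma_w_sq, sigma_b_sq = fit$sigma_b1_sq,
       slope_for_delta = slope)
}

#' Serialize an LME fit to JSON
#'
#' All `lme_fit` fields plus an optional data fingerprint, as a JSON string.
#'
#' @param fit An `lme_fit`.
#' @param fingerprint Optional named list (e.g. n, seed) appended verbatim.
#' @return A JSON string.
#' @export
lme_fit_json <- function(fit, fingerprint = NULL) {
  stopifnot(inherits(fit, "lme_fit"))
  x <- unclass(fit)
  if (!is.null(fingerprint)) x$fingerprint <- fingerprint
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}
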