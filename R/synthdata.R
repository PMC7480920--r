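#' Default generative parameters for the synthetic cohort
#'
#' One row per (group, biomarker) with the parameters of the linear
#' random-intercept/random-slope model the generator draws from:
#' `baseline_mean` and `baseline_sd` (between-subject intercept mean and SD),
#' `slope_mean` and `slope_sd` (group-average slope and between-subject slope
#' SD, per year), `corr` (intercept-slope correlation) and `resid_sd`
#' (within-subject residual SD). Units are control-baseline SDs, so slopes
#' read as sd/year.
#'
#' The defaults are illustrative, not estimates from real data: they are
#' chosen once to satisfy the qualitative structure reported for this
#' biomarker panel — plasma NfL has high within-subject variability, the
#' smallest between-subject slope variability, and a smaller slope than the
#' MRI measures in the disease groups; cognition has pNfL-like within-subject
#' noise; disease-group slopes exceed control slopes for every biomarker,
#' with the pNfL preclinical-minus-control gap fixed at 0.04 sd/year and the
#' mild-minus-control gap at 0.06 sd/year. Baseline offsets follow the
#' published group means (e.g. mild-AD PACC about 3.8 SDs below controls).
#'
#' @return A data.frame with columns `group`, `biomarker`, `baseline_mean`,
#'   `baseline_sd`, `slope_mean`, `slope_sd`, `corr`, `resid_sd`.
#' @export
default_params <- function() {
  groups <- c("control", "preclinical_ad", "mild_ad")
  bm <- c("pnfl", "temporal", "hippocampus", "cdrsb", "pacc")
  p <- expand.grid(group = groups, biomarker = bm,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  val <- function(tab) {
    unlist(lapply(seq_len(nrow(p)), function(i) tab[[p$biomarker[i]]][
      match(p$group[i], groups)]))
  }
  p$baseline_mean <- val(list(
    pnfl = c(0, 0.21, 0.64),            # published baseline group contrasts
    temporal = c(0, -0.30, -1.20),
    hippocampus = c(0, -0.35, -1.30),
    cdrsb = c(0, 0.20, 3.00),
    pacc = c(0, -0.15, -3.80)))
  p$baseline_sd <- val(list(
    pnfl = c(1.0, 1.1, 1.3), temporal = c(1.0, 1.0, 1.1),
    hippocampus = c(1.0, 1.0, 1.1), cdrsb = c(0.8, 0.9, 1.5),
    pacc = c(1.0, 1.1, 2.0)))
  p$slope_mean <- val(list(
    pnfl = c(0.145, 0.185, 0.205),      # +0.04 preclinical, +0.06 mild
    temporal = c(-0.06, -0.25, -0.45),
    hippocampus = c(-0.10, -0.28, -0.55),
    cdrsb = c(0.02, 0.10, 0.60),
    pacc = c(-0.03, -0.12, -0.50)))
  p$slope_sd <- val(list(
    pnfl = c(0.04, 0.05, 0.05),         # smallest between-subject slope SD
    temporal = c(0.08, 0.12, 0.12),
    hippocampus = c(0.07, 0.10, 0.10),
    cdrsb = c(0.10, 0.25, 0.25),
    pacc = c(0.12, 0.20, 0.20)))
  p$corr <- 0.1
  p$resid_sd <- val(list(
    pnfl = c(0.55, 0.55, 0.55),         # high within-subject noise
    temporal = c(0.20, 0.20, 0.20),
    hippocampus = c(0.15, 0.15, 0.15),
    cdrsb = c(0.45, 0.50, 0.50),
    pacc = c(0.45, 0.50, 0.50)))
  p
}

validate_params <- function(params) {
  need <- c("group", "biomarker", "baseline_mean", "baseline_sd",
            "slope_mean", "slope_sd", "corr", "resid_sd")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols))
    stop("params table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(params$baseline_sd < 0) || any(params$slope_sd < 0) ||
      any(params$resid_sd < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (any(abs(params$corr) >= 1))
    stop("|intercept-slope correlation| must be < 1", call. = FALSE)
  invisible(params)
}

#' Visit schedules and missingness model for the generator
#'
#' Describes the observational visit structure the generator emulates:
#' nominal visit months per modality, a monotone retention curve over the
#' pooled visit grid (once a subject drops out no later visit of any modality
#' is observed), and independent per-modality missingness at retained visits.
#' The default schedule is the 0/6/12/24/36/48/60-month pattern with plasma
#' NfL collected from month 12 onward annually, imaging and cognition at all
#' visits, and amyloid PET every two years.
#'
#' @param schedule Named list of nominal visit months per modality; must
#'   contain `pnfl`, `mri`, `cognition` (and optionally `suvr`).
#' @param retention Probability of still being in the study at each visit of
#'   the pooled grid; non-increasing, first element 1.
#' @param modality_miss Named probabilities of a retained visit lacking a
#'   given modality.
#' @return A `missingness_model` list.
#' @export
missingness_model <- function(
    schedule = list(pnfl = c(0, 12, 24, 36, 48, 60),
                    mri = c(0, 6, 12, 24, 36, 48, 60),
                    cognition = c(0, 6, 12, 24, 36, 48, 60),
                    suvr = c(0, 24, 48)),
    retention = c(1, 0.97, 0.93, 0.85, 0.74, 0.65, 0.55),
    modality_miss = c(pnfl = 0.12, mri = 0.18, cognition = 0.04, suvr = 0.05)) {
  grid <- sort(unique(unlist(schedule)))
  if (length(retention) != length(grid))
    stop("retention must have one entry per pooled visit (",
         length(grid), ")", call. = FALSE)
  if (any(retention < 0) || any(retention > 1) || any(diff(retention) > 0))
    stop("retention must be non-increasing probabilities", call. = FALSE)
  if (any(modality_miss < 0) || any(modality_miss > 1))
    stop("modality_miss must be probabilities", call. = FALSE)
  structure(list(schedule = schedule, grid = grid, retention = retention,
                 modality_miss = modality_miss),
            class = "missingness_model")
}

#' Simulate one subject's series for one biomarker
#'
#' Draws subject effects `(b0, b1)` from a bivariate normal with SDs
#' `baseline_sd`/`slope_sd` and correlation `corr`, then
#' `y(t) = baseline_mean + b0 + (slope_mean + b1) * t_years + e_t` with
#' i.i.d. normal residuals. Uses the current RNG state; seed at the caller.
#'
#' @param params_row One row of a generative parameter table.
#' @param schedule_months Visit months (sorted, non-empty).
#' @return A data.frame with `visit_month` and `value`.
#' @export
generate_subject <- function(params_row, schedule_months) {
  stopifnot(length(schedule_months) >= 1, !is.unsorted(schedule_months))
  if (params_row$baseline_sd < 0 || params_row$slope_sd < 0 ||
      params_row$resid_sd < 0)
    stop("all SDs must be >= 0", call. = FALSE)
  if (abs(params_row$corr) >= 1)
    stop("|intercept-slope correlation| must be < 1", call. = FALSE)
  z <- stats::rnorm(2L)
  b0 <- params_row$baseline_sd * z[1]
  b1 <- params_row$slope_sd *
    (params_row$corr * z[1] + sqrt(1 - params_row$corr^2) * z[2])
  t_years <- schedule_months / 12
  y <- params_row$baseline_mean + b0 +
    (params_row$slope_mean + b1) * t_years +
    stats::rnorm(length(t_years), 0, params_row$resid_sd)
  data.frame(visit_month = schedule_months, value = y)
}

# Deterministic per-subject seed stream derived from a root seed: cohorts are
# reproducible independent of how many subjects precede a given one.
subject_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces a wide per-visit table for three diagnostic groups (amyloid-
#' negative cognitively unimpaired controls; amyloid-positive cognitively
#' unimpaired "preclinical AD"; amyloid-positive CDR 0.5-1 "mild AD"), with
#' five analysis biomarkers following group-specific linear mixed-model
#' trajectories, plus the auxiliary fields the cohort builder consumes:
#' per-visit CDR global score, longitudinal amyloid PET SUVR, and baseline
#' CSF Abeta42 and P-tau181 consistent with the group labels. Visit structure
#' and missingness follow the supplied [missingness_model()].
#'
#' @param n_control,n_preclinical,n_mild Subjects per group.
#' @param params Generative parameter table; see [default_params()].
#' @param missingness A [missingness_model()].
#' @param seed Integer root seed; per-subject streams are derived from it, so
#'   regeneration with the same arguments is identical.
#' @return A `synthetic_cohort`: list with `data` (wide per-visit
#'   data.frame), `params`, `missingness` and `seed`.
#' @export
generate_cohort <- function(n_control, n_preclinical, n_mild,
                            params = default_params(),
                            missingness = missingness_model(),
                            seed = 1L) {
  stopifnot(n_control > 0, n_preclinical > 0, n_mild > 0,
            inherits(missingness, "missingness_model"))
  validate_params(params)
  groups <- rep(c("control", "preclinical_ad", "mild_ad"),
                times = c(n_control, n_preclinical, n_mild))
  n_total <- length(groups)
  biomarkers <- unique(params$biomarker)
  grid <- missingness$grid

  one_subject <- function(i) {
    set.seed(subject_seed(seed, i))
    grp <- groups[i]
    # monotone dropout: subject remains through visits with retention >= u
    u <- stats::runif(1)
    in_study <- missingness$retention >= u
    last_kept <- if (any(in_study)) max(which(in_study)) else 1L
    kept_months <- grid[seq_len(last_kept)]

    rows <- data.frame(subject_id = sprintf("S%05d", i), group = grp,
                       visit_month = kept_months)
    # CDR global: deterministic given group (mild split ~83/17 between 0.5, 1)
    rows$cdr_global <- switch(grp,
      control = 0, preclinical_ad = 0,
      mild_ad = if (stats::runif(1) < 0.826) 0.5 else 1.0)

    modality_of <- c(pnfl = "pnfl", temporal = "mri", hippocampus = "mri",
                     cdrsb = "cognition", pacc = "cognition")
    for (bm in biomarkers) {
      prow <- params[params$group == grp & params$biomarker == bm, ]
      if (nrow(prow) != 1L)
        stop("params must have exactly one row per (group, biomarker)",
             call. = FALSE)
      mod <- modality_of[[bm]]
      sched <- intersect(missingness$schedule[[mod]], kept_months)
      col <- rep(NA_real_, length(kept_months))
      if (length(sched)) {
        ser <- generate_subject(prow, sched)
        keep <- stats::runif(length(sched)) >= missingness$modality_miss[[mod]]
        col[match(sched[keep], kept_months)] <- ser$value[keep]
      }
      rows[[bm]] <- col
    }

    # amyloid PET SUVR: well-separated group-conditioned trajectories around
    # the 0.79 positivity cutoff (realism is a non-goal)
    suvr_int <- if (grp == "control") stats::rnorm(1, 0.70, 0.025)
                else stats::rnorm(1, 0.95, 0.05)
    suvr_slope <- stats::rnorm(1, 0.003, 0.001)
    sched <- intersect(missingness$schedule$suvr, kept_months)
    suvr <- rep(NA_real_, length(kept_months))
    if (length(sched)) {
      vals <- suvr_int + suvr_slope * sched / 12 +
        stats::rnorm(length(sched), 0, 0.01)
      keep <- stats::runif(length(sched)) >= missingness$modality_miss[["suvr"]]
      suvr[match(sched[keep], kept_months)] <- vals[keep]
    }
    rows$suvr <- suvr

    # CSF at baseline only, group-conditioned around published group means
    ab42 <- switch(grp, control = stats::rnorm(1, 1453, 250),
                   preclinical_ad = stats::rnorm(1, 640, 150),
                   mild_ad = stats::rnorm(1, 620, 150))
    ptau <- switch(grp, control = stats::rnorm(1, 18.7, 6.2),
                   preclinical_ad = stats::rnorm(1, 26.1, 11.1),
                   mild_ad = stats::rnorm(1, 34.5, 15.4))
    rows$csf_ab42 <- ifelse(rows$visit_month == 0, max(ab42, 50), NA_real_)
    rows$csf_ptau <- ifelse(rows$visit_month == 0, max(ptau, 1), NA_real_)
    rows
  }

  data <- do.call(rbind, lapply(seq_len(n_total), one_subject))
  rownames(data) <- NULL
  structure(list(data = data, params = params, missingness = missingness,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic longitudinal cohort (seed", x$seed, "):",
      length(unique(x$data$subject_id)), "subjects,",
      nrow(x$data), "visit rows\n")
  print(table(x$data$group[!duplicated(x$data$subject_id)]))
  invisible(x)
}

#' Convert a wide per-visit table to long format
#'
#' @param data Wide per-visit data.frame (`subject_id`, `visit_month`, one
#'   column per measure).
#' @param measures Columns to melt; defaults to every column other than
#'   `subject_id`, `visit_month`, `group`.
#' @return Long data.frame `subject_id, visit_month, measure, value` with
#'   missing cells dropped.
#' @export
to_long <- function(data, measures = NULL) {
  id_cols <- intersect(c("subject_id", "visit_month", "group"), names(data))
  if (is.null(measures)) measures <- setdiff(names(data), id_cols)
  out <- do.call(rbind, lapply(measures, function(m) {
    d <- data[!is.na(data[[m]]), c("subject_id", "visit_month")]
    if (!nrow(d)) return(NULL)
    d$measure <- m
    d$value <- data[[m]][!is.na(data[[m]])]
    d
  }))
  rownames(out) <- NULL
  out
}

#' Convert a long table to the wide per-visit layout
#'
#' @param long Long data.frame with `subject_id, visit_month, measure, value`.
#' @return Wide per-visit data.frame, one column per measure.
#' @export
to_wide <- function(long) {
  stopifnot(all(c("subject_id", "visit_month", "measure", "value") %in%
                  names(long)))
  out <- stats::reshape(long, direction = "wide",
                        idvar = c("subject_id", "visit_month"),
                        timevar = "measure", v.names = "value")
  names(out) <- sub("^value\\.", "", names(out))
  out <- out[order(out$subject_id, out$visit_month), ]
  rownames(out) <- NULL
  out
}
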