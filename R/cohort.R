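#' Baseline amyloid PET SUVR via per-subject regression intercept
#'
#' Many subjects lack a PET scan at the common study baseline, so baseline
#' amyloid load is anchored by regressing each subject's longitudinal SUVR
#' values on time and taking the intercept (estimated SUVR at time 0). A
#' single observation is its own intercept; replicate observations at one
#' time return their mean.
#'
#' @param visit_month Months of the SUVR observations.
#' @param suvr SUVR values (> 0), same length.
#' @return OLS intercept at time 0, or `NA_real_` for an empty series (the
#'   caller then falls back to CSF).
#' @export
estimate_amyloid_intercept <- function(visit_month, suvr) {
  keep <- !is.na(suvr) & !is.na(visit_month)
  visit_month <- visit_month[keep]; suvr <- suvr[keep]
  if (!length(suvr)) return(NA_real_)
  stopifnot(all(is.finite(visit_month)), all(is.finite(suvr)))
  if (length(unique(visit_month)) == 1L) return(mean(suvr))
  unname(stats::lm.fit(cbind(1, visit_month), suvr)$coefficients[1])
}

#' Classify amyloid status from PET intercept or CSF Abeta42
#'
#' PET takes precedence: SUVR intercept strictly above `suvr_cutoff`
#' (default 0.79) is amyloid-positive. Without PET, CSF Abeta42 strictly
#' below `ab42_cutoff` (default 880 pg/mL) is positive. With neither, the
#' status is unknown and the subject is later excluded.
#'
#' @param intercept PET SUVR intercept at baseline, or `NA`.
#' @param csf_ab42 CSF Abeta42 in pg/mL, or `NA`.
#' @param suvr_cutoff,ab42_cutoff Positivity cutoffs.
#' @return List with `status` (`"positive"`, `"negative"`, `"unknown"`) and
#'   `source` (`"pet_intercept"`, `"csf"`, `NA`).
#' @export
classify_amyloid <- function(intercept, csf_ab42 = NA_real_,
                             suvr_cutoff = 0.79, ab42_cutoff = 880) {
  if (!is.na(intercept)) {
    list(status = if (intercept > suvr_cutoff) "positive" else "negative",
         source = "pet_intercept")
  } else if (!is.na(csf_ab42)) {
    list(status = if (csf_ab42 < ab42_cutoff) "positive" else "negative",
         source = "csf")
  } else {
    list(status = "unknown", source = NA_character_)
  }
}

#' Assign a subject to a diagnostic group
#'
#' Controls are amyloid-negative with CDR global 0; preclinical AD is
#' amyloid-positive with CDR 0; mild AD is amyloid-positive with CDR 0.5 or
#' 1. Anything else (CDR > 1, amyloid-negative impaired, unknown amyloid or
#' missing CDR) is excluded with a reason. P-tau positivity (CSF P-tau181
#' strictly above `ptau_cutoff`, default 27 pg/mL) is recorded for the
#' tau-positive sensitivity analysis.
#'
#' @param baseline_cdr CDR global score at baseline (0, 0.5, 1, 2, 3) or `NA`.
#' @param amyloid_status `"positive"`, `"negative"` or `"unknown"`.
#' @param csf_ptau CSF P-tau181 in pg/mL or `NA`.
#' @param ptau_cutoff Positivity cutoff, default 27.
#' @return List with `group` (`"control"`, `"preclinical_ad"`, `"mild_ad"`,
#'   `"excluded"`), `ptau_positive` (logical or `NA`), `eligible` and
#'   `exclusion_reason`.
#' @export
assign_group <- function(baseline_cdr, amyloid_status, csf_ptau = NA_real_,
                         ptau_cutoff = 27) {
  ptau_pos <- if (is.na(csf_ptau)) NA else csf_ptau > ptau_cutoff
  res <- function(group, reason = "")
    list(group = group, ptau_positive = ptau_pos,
         eligible = group != "excluded", exclusion_reason = reason)
  if (is.na(baseline_cdr)) return(res("excluded", "missing baseline CDR"))
  if (amyloid_status == "unknown")
    return(res("excluded", "amyloid status unknown"))
  if (baseline_cdr == 0) {
    if (amyloid_status == "negative") return(res("control"))
    return(res("preclinical_ad"))
  }
  if (baseline_cdr %in% c(0.5, 1)) {
    if (amyloid_status == "positive") return(res("mild_ad"))
    return(res("excluded", "amyloid-negative with CDR 0.5-1"))
  }
  res("excluded", sprintf("CDR %g beyond mild dementia", baseline_cdr))
}

#' Cognitive composite score (equally weighted sum of four z-scores)
#'
#' Each component (MMSE, delayed logical memory, Trail-Making B time,
#' delayed ADAS-Cog word recall) is z-scored against reference-group baseline
#' statistics and oriented so that higher means better cognition: Trail
#' Making B is a completion time, so its z-score is sign-flipped. The
#' composite is the sum of the four oriented z-scores; any missing component
#' makes the composite missing (no pro-rating).
#'
#' @param components Named numeric values for `mmse`, `dmemory`, `trailsb`,
#'   `dadasc`.
#' @param reference_stats Named list with a `c(mean, sd)` pair (or a list
#'   with `mean`/`sd`) per component, from the reference group's baseline.
#' @return The composite score (unitless), or `NA_real_` if any component is
#'   missing.
#' @export
compute_pacc <- function(components, reference_stats) {
  need <- c("mmse", "dmemory", "trailsb", "dadasc")
  stopifnot(all(need %in% names(components)),
            all(need %in% names(reference_stats)))
  z <- vapply(need, function(k) {
    st <- reference_stats[[k]]
    m <- if (is.list(st)) st$mean else st[[1]]
    s <- if (is.list(st)) st$sd else st[[2]]
    if (!is.finite(s) || s <= 0)
      stop("reference SD for '", k, "' must be > 0", call. = FALSE)
    (as.numeric(components[[k]]) - m) / s
  }, numeric(1))
  if (anyNA(z)) return(NA_real_)
  z[["trailsb"]] <- -z[["trailsb"]]
  sum(z)
}

#' Surface-area-weighted temporal cortical thickness composite
#'
#' Area-normalized mean cortical thickness over the bilateral entorhinal,
#' fusiform, inferior temporal and middle temporal regions:
#' \eqn{\sum_r w_r \theta_r / \sum_r w_r} with surface areas as weights.
#'
#' @param thickness Named numeric vector of regional thicknesses (mm).
#' @param area Named numeric vector of the matching surface areas (mm^2, > 0).
#' @return Weighted mean thickness in mm, or `NA_real_` if any region is
#'   missing.
#' @export
compute_temporal_composite <- function(thickness, area) {
  stopifnot(length(thickness) == length(area), length(thickness) >= 1)
  if (!is.null(names(thickness)) && !is.null(names(area)))
    area <- area[names(thickness)]
  if (anyNA(thickness) || anyNA(area)) return(NA_real_)
  stopifnot(all(area > 0))
  sum(thickness * area) / sum(area)
}

#' Z-score a biomarker against pooled baseline statistics
#'
#' Transforms one biomarker column to standard-deviation units using the
#' mean and SD of baseline observations of the reference subjects (default:
#' all subjects present), so fitted slopes read as sd/year. The statistics
#' used are attached to the result as attribute `"standardization"` for
#' provenance.
#'
#' @param data Wide per-visit data.frame with `subject_id`, `visit_month`
#'   and the biomarker column.
#' @param biomarker Column name to standardize.
#' @param reference_ids Subject ids whose baseline values define the scale;
#'   default all.
#' @param baseline_month Visit month treated as baseline. Default 0.
#' @return `data` with the biomarker column z-scored and the reference
#'   mean/SD recorded in `attr(, "standardization")[[biomarker]]`.
#' @export
standardize_biomarker <- function(data, biomarker, reference_ids = NULL,
                                  baseline_month = 0) {
  stopifnot(biomarker %in% names(data))
  ref <- data[data$visit_month == baseline_month & !is.na(data[[biomarker]]), ]
  if (!is.null(reference_ids)) ref <- ref[ref$subject_id %in% reference_ids, ]
  v <- ref[[biomarker]]
  if (length(v) < 2L)
    stop("need >= 2 baseline reference values for '", biomarker, "'",
         call. = FALSE)
  m <- mean(v); s <- stats::sd(v)
  if (s <= 0) stop("reference SD of '", biomarker, "' is zero", call. = FALSE)
  data[[biomarker]] <- (data[[biomarker]] - m) / s
  std <- attr(data, "standardization")
  if (is.null(std)) std <- list()
  std[[biomarker]] <- list(mean = m, sd = s, n_reference = length(v),
                           baseline_month = baseline_month)
  attr(data, "standardization") <- std
  data
}

# modality -> biomarker columns of the wide layout
modality_columns <- function() {
  list(pnfl = "pnfl", mri = c("temporal", "hippocampus"),
       cognition = c("cdrsb", "pacc"))
}

# per subject x modality: months at which the modality has any observation
modality_months <- function(rows, cols) {
  cols <- intersect(cols, names(rows))
  if (!length(cols)) return(numeric(0))
  has <- rowSums(!is.na(rows[, cols, drop = FALSE])) > 0
  sort(unique(rows$visit_month[has]))
}

#' Follow-up eligibility filter
#'
#' Keeps subjects with at least `min_followups` post-baseline observations in
#' each of the plasma NfL, MRI and cognition modalities, and reports a
#' per-subject exclusion reason otherwise.
#'
#' @param data Wide per-visit data.frame.
#' @param min_followups Required post-baseline observations per modality.
#'   Default 2.
#' @param modalities Named list mapping modality to biomarker columns;
#'   default [modality_columns()].
#' @return Data.frame `subject_id`, `eligible`, `reason`.
#' @export
filter_eligibility <- function(data, min_followups = 2,
                               modalities = modality_columns()) {
  ids <- unique(data$subject_id)
  if (!length(ids))
    return(data.frame(subject_id = character(0), eligible = logical(0),
                      reason = character(0)))
  res <- lapply(ids, function(id) {
    rows <- data[data$subject_id == id, ]
    short <- vapply(names(modalities), function(mod) {
      months <- modality_months(rows, modalities[[mod]])
      sum(months > 0) < min_followups
    }, logical(1))
    data.frame(subject_id = id, eligible = !any(short),
               reason = if (any(short))
                 paste0("fewer than ", min_followups, " follow-ups: ",
                        paste(names(modalities)[short], collapse = ", "))
               else "")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Restrict to visits where all modalities overlap
#'
#' For the sensitivity analysis confined to overlapping longitudinal data:
#' per subject, observations of each modality are matched to the nearest
#' nominal visit within `tolerance` months, and only nominal visits at which
#' all three modalities have a match are retained. Retained rows are
#' collapsed onto the nominal visit time. The output is always a subset of
#' the input observations and the operation is idempotent.
#'
#' @param data Wide per-visit data.frame.
#' @param tolerance Matching half-window in months. Default 1.5.
#' @param nominal_times Nominal visit months. Default the
#'   0/6/12/24/36/48/60-month schedule.
#' @param modalities Modality-to-column map; default [modality_columns()].
#' @return Filtered wide data.frame with `visit_month` snapped to nominal
#'   times.
#' @export
intersect_overlapping_visits <- function(data, tolerance = 1.5,
                                         nominal_times = c(0, 6, 12, 24, 36, 48, 60),
                                         modalities = modality_columns()) {
  stopifnot(tolerance >= 0)
  value_cols <- intersect(unlist(modalities), names(data))
  match_nominal <- function(months) {
    # nearest nominal visit within tolerance, NA otherwise
    vapply(months, function(m) {
      d <- abs(nominal_times - m)
      j <- which.min(d)
      if (d[j] <= tolerance) nominal_times[j] else NA_real_
    }, numeric(1))
  }
  out <- lapply(unique(data$subject_id), function(id) {
    rows <- data[data$subject_id == id, ]
    nominal_per_mod <- lapply(modalities, function(cols) {
      mm <- match_nominal(modality_months(rows, cols))
      unique(mm[!is.na(mm)])
    })
    keep_nominal <- Reduce(intersect, nominal_per_mod)
    if (!length(keep_nominal)) return(NULL)
    row_nominal <- match_nominal(rows$visit_month)
    rows <- rows[!is.na(row_nominal) & row_nominal %in% keep_nominal, ]
    if (!nrow(rows)) return(NULL)
    rows$visit_month <- match_nominal(rows$visit_month)
    # collapse multiple rows snapped to one nominal visit (first non-missing)
    collapsed <- lapply(split(rows, rows$visit_month), function(g) {
      first <- g[1, ]
      for (cl in names(g))
        if (anyNA(first[[cl]]) && any(!is.na(g[[cl]])))
          first[[cl]] <- g[[cl]][!is.na(g[[cl]])][1]
      first
    })
    do.call(rbind, collapsed)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data[0, ]
  rownames(out) <- NULL
  out
}

#' Build cohort assignments from a visit table
#'
#' Runs the full group-assignment procedure per subject: estimate the
#' baseline amyloid PET SUVR as the per-subject regression intercept of all
#' longitudinal SUVR values, classify amyloid status (PET first, CSF Abeta42
#' fallback), take the CDR global score at the earliest visit with one, and
#' map (CDR, amyloid) to control / preclinical AD / mild AD. Follow-up
#' eligibility (at least `min_followups` post-baseline observations per
#' modality) is applied on top; diagnostic labels are kept for excluded
#' subjects so exclusions are auditable.
#'
#' @param data Wide per-visit data.frame with `subject_id`, `visit_month`,
#'   `cdr_global`, `suvr`, `csf_ab42`, `csf_ptau` and biomarker columns.
#' @param suvr_cutoff,ab42_cutoff,ptau_cutoff Positivity cutoffs (defaults
#'   0.79, 880 pg/mL, 27 pg/mL).
#' @param min_followups Follow-up requirement per modality. Default 2.
#' @return Data.frame with one row per subject: `subject_id`, `group`,
#'   `amyloid_status`, `amyloid_source`, `ptau_positive`, `eligible`,
#'   `exclusion_reason`.
#' @export
build_cohort <- function(data, suvr_cutoff = 0.79, ab42_cutoff = 880,
                         ptau_cutoff = 27, min_followups = 2) {
  stopifnot(all(c("subject_id", "visit_month") %in% names(data)))
  elig <- filter_eligibility(data, min_followups = min_followups)
  ids <- unique(data$subject_id)
  rows <- lapply(ids, function(id) {
    d <- data[data$subject_id == id, ]
    d <- d[order(d$visit_month), ]
    interc <- if ("suvr" %in% names(d))
      estimate_amyloid_intercept(d$visit_month, d$suvr) else NA_real_
    ab42 <- first_present(d, "csf_ab42")
    ptau <- first_present(d, "csf_ptau")
    amy <- classify_amyloid(interc, ab42, suvr_cutoff, ab42_cutoff)
    cdr <- first_present(d, "cdr_global")
    asg <- assign_group(cdr, amy$status, ptau, ptau_cutoff)
    data.frame(subject_id = id, group = asg$group,
               amyloid_status = amy$status,
               amyloid_source = if (is.na(amy$source)) "" else amy$source,
               ptau_positive = asg$ptau_positive,
               eligible = asg$eligible,
               exclusion_reason = asg$exclusion_reason)
  })
  out <- do.call(rbind, rows)
  fu <- elig[match(out$subject_id, elig$subject_id), ]
  drop_fu <- out$eligible & !fu$eligible
  out$eligible <- out$eligible & fu$eligible
  out$exclusion_reason[drop_fu] <- fu$reason[drop_fu]
  rownames(out) <- NULL
  out
}

first_present <- function(d, col) {
  if (!col %in% names(d)) return(NA_real_)
  v <- d[[col]][!is.na(d[[col]])]
  if (length(v)) v[1] else NA_real_
}
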