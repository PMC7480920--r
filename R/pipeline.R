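#' Read a visit table from CSV
#'
#' Accepts the wide per-visit layout (`subject_id, visit_month, <measure
#' columns>`) or the long layout (`subject_id, visit_month, measure, value`),
#' which is pivoted to wide. Missing values are empty cells.
#'
#' @param path CSV path (UTF-8, header row required).
#' @param format `"wide"` or `"long"`.
#' @return Wide per-visit data.frame.
#' @export
read_visit_table <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "visit_month") %in% names(d)))
    stop("CSV must have 'subject_id' and 'visit_month' columns", call. = FALSE)
  if (format == "long") d <- to_wide(d)
  d
}

#' Write a visit table or cohort assignment to CSV
#'
#' @param data Data.frame to write.
#' @param path Output path.
#' @export
write_table_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
}

# 32-bit polynomial hash of the canonical config JSON, for the run manifest
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param data Wide per-visit data.frame (with `cdr_global`, `suvr`,
#'   `csf_ab42`, `csf_ptau` and biomarker columns). If `NULL`, a synthetic
#'   cohort is generated from `synth`.
#' @param synth List `n_control`, `n_preclinical`, `n_mild` for the
#'   generator (used when `data` is `NULL`). Defaults to the published group
#'   sizes 330/218/697.
#' @param params Generative parameter table for the synthetic cohort.
#' @param biomarkers Biomarker columns to analyse.
#' @param frequencies Named per-biomarker sampling frequency, months
#'   (default: plasma NfL monthly, MRI and cognition every 3 months).
#' @param durations Named per-group trial duration, months (default: 30 for
#'   preclinical AD, 18 for mild AD).
#' @param mechanism,alpha,power,effect_fraction Passed to [trial_design()].
#' @param suvr_cutoff,ab42_cutoff,ptau_cutoff Cohort cutoffs.
#' @param B Bootstrap iterations for between-biomarker comparisons (0 skips
#'   bootstrapping).
#' @param contrasts Fit the group-by-time interaction contrasts against
#'   controls. Default `TRUE`.
#' @param sweep Optional list `durations`, `frequencies`, `reference`,
#'   `reference_frequency`, `group` to run a design sweep.
#' @param seed Root seed for cohort generation and bootstrapping.
#' @param out_dir Output directory; `NULL` returns results without writing.
#' @return A validated `run_config` list.
#' @export
run_config <- function(data = NULL,
                       synth = list(n_control = 330, n_preclinical = 218,
                                    n_mild = 697),
                       params = default_params(),
                       biomarkers = c("pnfl", "temporal", "hippocampus",
                                      "cdrsb", "pacc"),
                       frequencies = c(pnfl = 1, temporal = 3,
                                       hippocampus = 3, cdrsb = 3, pacc = 3),
                       durations = c(preclinical_ad = 30, mild_ad = 18),
                       mechanism = c("full", "disease_specific"),
                       alpha = 0.05, power = 0.80, effect_fraction = 0.30,
                       suvr_cutoff = 0.79, ab42_cutoff = 880,
                       ptau_cutoff = 27,
                       B = 0, contrasts = TRUE, sweep = NULL, seed = 1L,
                       out_dir = NULL) {
  mechanism <- match.arg(mechanism)
  cfg <- list(data = data, synth = synth, params = params,
              biomarkers = biomarkers, frequencies = frequencies,
              durations = durations, mechanism = mechanism, alpha = alpha,
              power = power, effect_fraction = effect_fraction,
              suvr_cutoff = suvr_cutoff, ab42_cutoff = ab42_cutoff,
              ptau_cutoff = ptau_cutoff, B = B, contrasts = contrasts,
              sweep = sweep, seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  miss <- setdiff(cfg$biomarkers, names(cfg$frequencies))
  if (length(miss))
    stop("no sampling frequency for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$data)) {
    absent <- setdiff(cfg$biomarkers, names(cfg$data))
    if (length(absent))
      stop("input data lacks biomarker columns: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  for (g in names(cfg$durations)) {
    for (bm in cfg$biomarkers) {
      f <- cfg$frequencies[[bm]]; dur <- cfg$durations[[g]]
      if (f <= 0 || f > dur)
        stop(sprintf("frequency %g months of '%s' invalid for %g-month '%s' design",
                     f, bm, dur, g), call. = FALSE)
    }
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$power > 0, cfg$power < 1,
            cfg$effect_fraction > 0, cfg$effect_fraction <= 1, cfg$B >= 0)
  invisible(cfg)
}

#' Run the full biomarker power comparison
#'
#' End-to-end pipeline: obtain the cohort (generate synthetically or take
#' the supplied table), assign diagnostic groups and apply follow-up
#' eligibility, z-score every biomarker against the pooled baseline of
#' eligible subjects, fit the random-slope model per biomarker and group,
#' contrast each disease group against controls, convert each fit to the
#' per-arm sample size under the group's trial design, and optionally sweep
#' designs and bootstrap between-biomarker differences. Identical config and
#' seed give identical output.
#'
#' @param config A [run_config()].
#' @return A `trialpower_run` list: `cohort` (assignments), `fits`,
#'   `contrasts`, `sample_sizes` (data.frame), `sweep`, `comparisons`,
#'   `manifest`. Written as CSV/JSON under `config$out_dir` when set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_config(config)
  log_stage <- function(...) message(sprintf(...))

  if (is.null(config$data)) {
    cohort <- generate_cohort(config$synth$n_control,
                              config$synth$n_preclinical,
                              config$synth$n_mild,
                              params = config$params, seed = config$seed)
    data <- cohort$data
  } else data <- config$data
  log_stage("input: %d subjects, %d visit rows",
            length(unique(data$subject_id)), nrow(data))

  assignments <- build_cohort(data, suvr_cutoff = config$suvr_cutoff,
                              ab42_cutoff = config$ab42_cutoff,
                              ptau_cutoff = config$ptau_cutoff)
  keep <- assignments$subject_id[assignments$eligible]
  log_stage("cohort: %d eligible of %d (control %d, preclinical %d, mild %d)",
            length(keep), nrow(assignments),
            sum(assignments$group == "control" & assignments$eligible),
            sum(assignments$group == "preclinical_ad" & assignments$eligible),
            sum(assignments$group == "mild_ad" & assignments$eligible))

  d <- data[data$subject_id %in% keep, ]
  d$group <- assignments$group[match(d$subject_id, assignments$subject_id)]
  for (bm in config$biomarkers)
    d <- standardize_biomarker(d, bm)

  groups <- c("control", "preclinical_ad", "mild_ad")
  fits <- lapply(groups, function(g) {
    gl <- lapply(config$biomarkers, function(bm)
      tryCatch(fit_slope_model(d[d$group == g, ], value = bm,
                               biomarker = bm, group = g),
               error = function(e) e))
    names(gl) <- config$biomarkers
    gl
  })
  names(fits) <- groups
  n_failed <- sum(vapply(unlist(fits, recursive = FALSE),
                         function(f) !inherits(f, "lme_fit") || !f$converged,
                         logical(1)))
  log_stage("fits: %d biomarker x group models, %d failed or non-converged",
            length(groups) * length(config$biomarkers), n_failed)

  contrasts <- NULL
  if (isTRUE(config$contrasts)) {
    contrasts <- lapply(c("preclinical_ad", "mild_ad"), function(g) {
      cl <- lapply(config$biomarkers, function(bm)
        tryCatch(fit_group_interaction(d, "control", g, value = bm),
                 error = function(e) e))
      names(cl) <- config$biomarkers
      cl
    })
    names(contrasts) <- c("preclinical_ad", "mild_ad")
  }

  ss_rows <- list()
  for (g in names(config$durations)) {
    for (bm in config$biomarkers) {
      des <- trial_design(config$durations[[g]], config$frequencies[[bm]],
                          alpha = config$alpha, power = config$power,
                          effect_fraction = config$effect_fraction,
                          mechanism = config$mechanism)
      fit <- fits[[g]][[bm]]
      row <- data.frame(group = g, biomarker = bm,
                        duration = des$duration, frequency = des$frequency,
                        mechanism = config$mechanism,
                        n_continuous = NA_real_, n_per_arm = NA_integer_,
                        error = "")
      if (inherits(fit, "lme_fit")) {
        res <- tryCatch(sample_size_for_fit(
          fit, des,
          control_fit = if (config$mechanism == "disease_specific")
            fits$control[[bm]]),
          error = function(e) e)
        if (inherits(res, "sample_size_result")) {
          row$n_continuous <- res$n_continuous
          row$n_per_arm <- res$n_per_arm
        } else row$error <- conditionMessage(res)
      } else row$error <- conditionMessage(fit)
      ss_rows[[length(ss_rows) + 1L]] <- row
    }
  }
  sample_sizes <- do.call(rbind, ss_rows)
  rownames(sample_sizes) <- NULL

  sweep_grid <- NULL
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    g <- if (is.null(sw$group)) "preclinical_ad" else sw$group
    ok <- vapply(fits[[g]], function(f)
      inherits(f, "lme_fit") && f$converged, logical(1))
    sweep_grid <- sweep_designs(
      fits[[g]][ok], durations = sw$durations, frequencies = sw$frequencies,
      reference = sw$reference,
      reference_frequency = if (is.null(sw$reference_frequency)) 1
                            else sw$reference_frequency,
      control_fits = fits$control[ok],
      effect_fraction = config$effect_fraction, alpha = config$alpha,
      power = config$power, mechanism = config$mechanism)
    sweep_grid$group <- g
  }

  comparisons <- NULL
  if (config$B >= 2) {
    reference <- if ("pnfl" %in% config$biomarkers) "pnfl"
                 else config$biomarkers[1]
    comp_rows <- list()
    for (g in names(config$durations)) {
      des_ref <- trial_design(config$durations[[g]],
                              config$frequencies[[reference]],
                              alpha = config$alpha, power = config$power,
                              effect_fraction = config$effect_fraction,
                              mechanism = config$mechanism)
      for (bm in setdiff(config$biomarkers, reference)) {
        des_bm <- trial_design(config$durations[[g]],
                               config$frequencies[[bm]],
                               alpha = config$alpha, power = config$power,
                               effect_fraction = config$effect_fraction,
                               mechanism = config$mechanism)
        cmp <- tryCatch(
          bootstrap_compare(d, reference, bm, g, des_ref, des_bm,
                            B = config$B, seed = config$seed),
          error = function(e) NULL)
        if (!is.null(cmp))
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            group = g, biomarker_a = reference, biomarker_b = bm,
            median_diff = stats::median(cmp$diff_distribution, na.rm = TRUE),
            p_value = cmp$p_value,
            convergence_rate = cmp$convergence_rate)
      }
    }
    comparisons <- do.call(rbind, comp_rows)
  }

  cfg_for_hash <- config[setdiff(names(config), c("data", "out_dir"))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("trialpower")),
    config_hash = config_hash(cfg_for_hash),
    seed = config$seed,
    n_subjects_input = length(unique(data$subject_id)),
    n_eligible = length(keep),
    groups = as.list(table(assignments$group[assignments$eligible])),
    n_fit_failures = n_failed,
    mechanism = config$mechanism)

  run <- structure(list(cohort = assignments, fits = fits,
                        contrasts = contrasts, sample_sizes = sample_sizes,
                        sweep = sweep_grid, comparisons = comparisons,
                        manifest = manifest),
                   class = "trialpower_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(run$cohort, file.path(out_dir, "cohort.csv"))
  write_table_csv(run$sample_sizes, file.path(out_dir, "sample_sizes.csv"))
  if (!is.null(run$sweep))
    write_table_csv(run$sweep, file.path(out_dir, "sweep.csv"))
  if (!is.null(run$comparisons))
    write_table_csv(run$comparisons, file.path(out_dir, "comparisons.csv"))
  fits_flat <- lapply(run$fits, function(gl)
    lapply(gl, function(f)
      if (inherits(f, "lme_fit")) unclass(f)
      else list(error = conditionMessage(f))))
  jsonlite::write_json(fits_flat, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.trialpower_run <- function(x, ...) {
  cat("trialpower run (config", x$manifest$config_hash, ")\n")
  print(x$sample_sizes[, c("group", "biomarker", "duration", "frequency",
                           "n_per_arm")])
  invisible(x)
}

#' Re-run the pipeline under a named sensitivity variant
#'
#' Variants: `"overlapping_visits"` restricts every subject to visits at
#' which all three modalities were observed (within a 1.5-month matching
#' window) before fitting; `"ptau_positive"` additionally requires mild-AD
#' subjects to be CSF P-tau181 positive; `"low_frequency"` switches the
#' trial designs to plasma sampling every 3 months and MRI/cognition every 6
#' months. Returns the variant run plus a side-by-side delta table of
#' per-arm sample sizes against the base run.
#'
#' @param config A [run_config()].
#' @param which One of `"overlapping_visits"`, `"ptau_positive"`,
#'   `"low_frequency"`.
#' @param base A `trialpower_run` from [run_analysis()] on `config`;
#'   computed if `NULL`.
#' @return List with `base`, `variant` (both `trialpower_run`) and `delta`
#'   (data.frame of base vs variant n per group and biomarker).
#' @export
run_sensitivity <- function(config,
                            which = c("overlapping_visits", "ptau_positive",
                                      "low_frequency"),
                            base = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(config, "run_config"))
  if (is.null(base)) {
    base_cfg <- config
    base_cfg$out_dir <- NULL
    base <- run_analysis(base_cfg)
  }
  vcfg <- config
  vcfg$out_dir <- NULL
  if (which == "low_frequency") {
    vcfg$frequencies[] <- ifelse(names(vcfg$frequencies) == "pnfl", 3, 6)
  } else {
    # materialize the cohort so the variant filters the same data
    if (is.null(vcfg$data)) {
      vcfg$data <- generate_cohort(config$synth$n_control,
                                   config$synth$n_preclinical,
                                   config$synth$n_mild,
                                   params = config$params,
                                   seed = config$seed)$data
    }
    if (which == "overlapping_visits") {
      vcfg$data <- intersect_overlapping_visits(vcfg$data)
    } else {
      asg <- build_cohort(vcfg$data, suvr_cutoff = config$suvr_cutoff,
                          ab42_cutoff = config$ab42_cutoff,
                          ptau_cutoff = config$ptau_cutoff)
      drop <- asg$subject_id[asg$group == "mild_ad" &
                               (!asg$ptau_positive | is.na(asg$ptau_positive))]
      vcfg$data <- vcfg$data[!vcfg$data$subject_id %in% drop, ]
    }
  }
  variant <- run_analysis(vcfg)
  delta <- merge(base$sample_sizes[, c("group", "biomarker", "n_continuous")],
                 variant$sample_sizes[, c("group", "biomarker", "n_continuous")],
                 by = c("group", "biomarker"), suffixes = c("_base", "_variant"))
  delta$delta <- delta$n_continuous_variant - delta$n_continuous_base
  list(base = base, variant = variant, delta = delta, which = which)
}
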