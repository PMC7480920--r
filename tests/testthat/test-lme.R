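test_that("degenerate noise-free data yield an exact fit", {
  months <- c(0, 12, 24)
  d <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3),
                  visit_month = rep(months, 3),
                  value = rep(c(1, 2, 3), each = 3) - 0.2 * rep(months / 12, 3))
  f <- fit_slope_model(d)
  expect_true(f$converged)
  expect_equal(f$method, "degenerate_exact")
  expect_equal(f$beta1, -0.2, tolerance = 1e-10)
  expect_equal(f$sigma_w_sq, 0)
  expect_equal(f$sigma_b1_sq, 0)
})

test_that("variance components and slope are recovered from generated data", {
  pr <- data.frame(baseline_mean = 0, baseline_sd = 1, slope_mean = -0.20,
                   slope_sd = 0.10, corr = 0, resid_sd = 0.30)
  d <- gen_from_params(500, adni_months, pr, seed = 21)
  f <- fit_slope_model(d)
  expect_true(f$converged)
  expect_lt(abs(f$beta1 - (-0.20)) / 0.20, 0.05)
  expect_lt(abs(f$sigma_w_sq - 0.09) / 0.09, 0.05)
  # slope-variance estimates have ~9% sampling SD at this size; allow 3 SDs
  expect_lt(abs(f$sigma_b1_sq - 0.01) / 0.01, 0.25)
  # cross-check the whole component set against an independent mixed-model
  # implementation on the same data
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(value ~ t + (t | subject_id),
                   data = transform(d, t = visit_month / 12), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$beta1, unname(lme4::fixef(lf)["t"]), tolerance = 1e-3)
  expect_equal(f$sigma_w_sq,
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-2)
  expect_equal(f$sigma_b1_sq,
               vc$vcov[vc$grp == "subject_id" & vc$var1 == "t" &
                         is.na(vc$var2)], tolerance = 1e-2)
})

test_that("point estimates are invariant to exact data replication", {
  pr <- data.frame(baseline_mean = 0, baseline_sd = 1, slope_mean = 0.15,
                   slope_sd = 0.05, corr = 0, resid_sd = 0.4)
  d <- gen_from_params(60, c(0, 12, 24, 36), pr, seed = 31)
  d2 <- d
  d2$subject_id <- paste0(d2$subject_id, "_dup")
  f1 <- fit_slope_model(d)
  f2 <- fit_slope_model(rbind(d, d2))
  expect_equal(f2$beta0, f1$beta0, tolerance = 1e-5)
  expect_equal(f2$beta1, f1$beta1, tolerance = 1e-5)
})

test_that("location shifts and time rescaling act as expected on estimates", {
  pr <- data.frame(baseline_mean = 0, baseline_sd = 1, slope_mean = -0.25,
                   slope_sd = 0.08, corr = 0, resid_sd = 0.35)
  d <- gen_from_params(150, c(0, 12, 24, 36, 48), pr, seed = 41)
  f <- fit_slope_model(d)
  # adding a constant to all observations moves only the intercept
  d_shift <- d; d_shift$value <- d$value + 5
  fs <- fit_slope_model(d_shift)
  expect_equal(fs$sigma_w_sq, f$sigma_w_sq, tolerance = 1e-6)
  expect_equal(fs$beta1, f$beta1, tolerance = 1e-6)
  expect_equal(fs$beta0, f$beta0 + 5, tolerance = 1e-5)
  # months treated as years: slope scales by 12, slope variance by 144,
  # residual variance unchanged
  d_m <- data.frame(subject_id = d$subject_id, time_years = d$visit_month,
                    value = d$value)
  fm <- fit_slope_model(d_m)
  expect_equal(fm$beta1 * 12, f$beta1, tolerance = 1e-5)
  expect_equal(fm$sigma_b1_sq * 144, f$sigma_b1_sq, tolerance = 1e-3)
  expect_equal(fm$sigma_w_sq, f$sigma_w_sq, tolerance = 1e-5)
})

test_that("insufficient data is refused with a clear error", {
  d <- data.frame(subject_id = c("a", "a", "b"), visit_month = c(0, 12, 0),
                  value = c(1, 2, 3))
  expect_error(fit_slope_model(d), "2 subjects")
})

test_that("group interaction recovers a known slope gap and is antisymmetric", {
  months <- c(0, 12, 24, 36, 48)
  pr_a <- data.frame(baseline_mean = 0, baseline_sd = 1, slope_mean = 0.10,
                     slope_sd = 0.05, corr = 0, resid_sd = 0.3)
  pr_b <- pr_a; pr_b$slope_mean <- 0.14; pr_b$baseline_mean <- 0.2
  da <- gen_from_params(400, months, pr_a, seed = 51)
  db <- gen_from_params(400, months, pr_b, seed = 52)
  db$subject_id <- paste0("B", db$subject_id)
  da$group <- "control"; db$group <- "disease"
  d <- rbind(da, db)
  ct <- fit_group_interaction(d, "control", "disease")
  expect_lt(abs(ct$delta_beta - 0.04), 2 * ct$se)
  expect_lt(abs(ct$baseline_diff - 0.2), 2 * ct$baseline_se)
  expect_true(ct$p_value >= 0 && ct$p_value <= 1)
  # swapping group roles flips the contrast signs exactly
  ct_rev <- fit_group_interaction(d, "disease", "control")
  expect_equal(ct_rev$delta_beta, -ct$delta_beta, tolerance = 1e-6)
  expect_equal(ct_rev$p_value, ct$p_value, tolerance = 1e-6)
})

test_that("identical groups produce a null contrast", {
  months <- c(0, 12, 24, 36)
  pr <- data.frame(baseline_mean = 0, baseline_sd = 1, slope_mean = 0.1,
                   slope_sd = 0.05, corr = 0, resid_sd = 0.3)
  da <- gen_from_params(150, months, pr, seed = 61)
  db <- gen_from_params(150, months, pr, seed = 62)
  db$subject_id <- paste0("B", db$subject_id)
  da$group <- "g1"; db$group <- "g2"
  ct <- fit_group_interaction(rbind(da, db), "g1", "g2")
  expect_lt(abs(ct$delta_beta), 3 * ct$se)
})

test_that("power inputs honour the treatment mechanism", {
  mk <- function(b1, conv = TRUE)
    trialpower:::new_lme_fit(0, b1, 0.01, 1, 0.02, 0, 0.3, 100, 500, conv,
                             "reml_unstructured")
  fit <- mk(-0.20); ctrl <- mk(-0.05)
  full <- extract_power_inputs(fit, mechanism = "full")
  expect_equal(full$slope_for_delta, -0.20)
  expect_equal(full$sigma_b_sq, 0.02)
  ds <- extract_power_inputs(fit, ctrl, mechanism = "disease_specific")
  expect_equal(ds$slope_for_delta, -0.15)
  # slope variance passes through unchanged under either mechanism
  expect_equal(ds$sigma_b_sq, full$sigma_b_sq)
  expect_error(extract_power_inputs(fit, mechanism = "disease_specific"),
               "control")
  bad <- mk(-0.2, conv = FALSE)
  expect_error(extract_power_inputs(bad, mechanism = "full"), "converge")
  forced <- extract_power_inputs(bad, mechanism = "full", force = TRUE)
  expect_equal(forced$slope_for_delta, -0.2)
})

test_that("fit serialization carries all fields", {
  f <- trialpower:::new_lme_fit(0.1, -0.2, 0.01, 1, 0.01, 0.002, 0.09,
                                50, 250, TRUE, "reml_unstructured",
                                "pnfl", "mild_ad")
  js <- jsonlite::fromJSON(lme_fit_json(f, fingerprint = list(seed = 7)))
  expect_equal(js$beta1, -0.2)
  expect_equal(js$sigma_b1_sq, 0.01)
  expect_equal(js$fingerprint$seed, 7)
  expect_true(js$converged)
})
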