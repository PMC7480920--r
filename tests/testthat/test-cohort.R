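test_that("amyloid intercept is the per-subject OLS intercept", {
  expect_equal(estimate_amyloid_intercept(0, 0.85), 0.85)
  expect_equal(estimate_amyloid_intercept(c(0, 24), c(0.70, 0.90)), 0.70)
  # three points: cross-check against a generic least-squares fit
  tm <- c(0, 12, 24); sv <- c(0.80, 0.82, 0.90)
  oracle <- unname(coef(lm(sv ~ tm))[1])
  expect_equal(estimate_amyloid_intercept(tm, sv), oracle)
  expect_equal(oracle, 0.79, tolerance = 1e-10)
  # replicates at a single time return their mean
  expect_equal(estimate_amyloid_intercept(c(0, 0), c(0.8, 0.9)), 0.85)
  expect_true(is.na(estimate_amyloid_intercept(numeric(0), numeric(0))))
})

test_that("amyloid classification uses PET first, CSF fallback, strict cutoffs", {
  expect_equal(classify_amyloid(0.85, 1500),
               list(status = "positive", source = "pet_intercept"))
  # strictly greater-than at the PET boundary
  expect_equal(classify_amyloid(0.79)$status, "negative")
  expect_equal(classify_amyloid(NA, 500),
               list(status = "positive", source = "csf"))
  expect_equal(classify_amyloid(NA, 880)$status, "negative")
  expect_equal(classify_amyloid(NA, NA)$status, "unknown")
  # monotone in intercept, antitone in CSF Abeta42
  st <- sapply(c(0.5, 0.79, 0.791, 1.2),
               function(x) classify_amyloid(x)$status)
  expect_equal(st, c("negative", "negative", "positive", "positive"))
  st <- sapply(c(300, 879, 880, 1500),
               function(x) classify_amyloid(NA, x)$status)
  expect_equal(st, c("positive", "positive", "negative", "negative"))
})

test_that("group assignment partitions subjects by CDR and amyloid", {
  expect_equal(assign_group(0, "negative")$group, "control")
  g <- assign_group(0.5, "positive", csf_ptau = 30)
  expect_equal(g$group, "mild_ad")
  expect_true(g$ptau_positive)
  expect_equal(assign_group(0.5, "negative")$group, "excluded")
  expect_equal(assign_group(0, "positive")$group, "preclinical_ad")
  expect_equal(assign_group(2, "positive")$group, "excluded")
  expect_equal(assign_group(NA, "positive")$group, "excluded")
  expect_equal(assign_group(0, "unknown")$group, "excluded")
  expect_false(assign_group(1, "positive", csf_ptau = 27)$ptau_positive)

  # exhaustive partition: every (CDR, amyloid) combination maps to exactly
  # one group
  for (cdr in c(0, 0.5, 1, 2, 3, NA))
    for (amy in c("positive", "negative", "unknown")) {
      g <- assign_group(cdr, amy)$group
      expect_true(g %in% c("control", "preclinical_ad", "mild_ad", "excluded"))
    }
})

test_that("cognitive composite sums oriented z-scores and refuses partial input", {
  ref <- list(mmse = c(29, 1.2), dmemory = c(13, 3), trailsb = c(85, 40),
              dadasc = c(7, 2))
  at_mean <- c(mmse = 29, dmemory = 13, trailsb = 85, dadasc = 7)
  expect_equal(compute_pacc(at_mean, ref), 0)
  # one SD better on each component (Trail Making B better = faster)
  better <- c(mmse = 30.2, dmemory = 16, trailsb = 45, dadasc = 9)
  expect_equal(compute_pacc(better, ref), 4.0)
  slow_tmt <- c(mmse = 29, dmemory = 13, trailsb = 125, dadasc = 7)
  expect_equal(compute_pacc(slow_tmt, ref), -1.0)
  expect_true(is.na(compute_pacc(
    c(mmse = 29, dmemory = NA, trailsb = 85, dadasc = 7), ref)))
  bad_ref <- ref; bad_ref$mmse <- c(29, 0)
  expect_error(compute_pacc(at_mean, bad_ref), "SD")
})

test_that("temporal composite is the area-weighted mean thickness", {
  expect_equal(compute_temporal_composite(c(2.0, 4.0), c(1, 3)), 3.5)
  th <- rep(3.0, 8); ar <- runif(8, 100, 900)
  expect_equal(compute_temporal_composite(th, ar), 3.0)
  set.seed(7)
  th <- runif(8, 1.5, 3.5); ar <- rep(250, 8)
  expect_equal(compute_temporal_composite(th, ar), mean(th))
  # always within the range of the inputs
  for (i in 1:20) {
    th <- runif(8, 1, 4); ar <- runif(8, 10, 1000)
    v <- compute_temporal_composite(th, ar)
    expect_gte(v, min(th)); expect_lte(v, max(th))
  }
  expect_true(is.na(compute_temporal_composite(c(2, NA), c(1, 1))))
})

test_that("standardization is exact on the reference and respects linearity", {
  d <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 2),
                  visit_month = rep(c(0, 12), 4),
                  biom = c(10, 11, 12, 13, 14, 15, 16, 18))
  z <- standardize_biomarker(d, "biom")
  st <- attr(z, "standardization")$biom
  base <- z$biom[z$visit_month == 0]
  expect_equal(mean(base), 0)
  expect_equal(sd(base), 1)
  expect_equal(st$mean, 13); expect_equal(st$n_reference, 4)
  # value one reference SD above the mean maps to 1
  d2 <- d; d2$biom[1] <- st$mean + st$sd
  expect_equal(standardize_biomarker(d2, "biom")$biom[1],
               (d2$biom[1] - mean(d2$biom[d2$visit_month == 0])) /
                 sd(d2$biom[d2$visit_month == 0]))
  # re-standardizing an already standardized table is the identity
  z2 <- standardize_biomarker(z, "biom")
  expect_equal(z2$biom, z$biom, tolerance = 1e-12)
  # linear transforms of the input cancel exactly
  d3 <- d; d3$biom <- 5 * d$biom - 2
  expect_equal(standardize_biomarker(d3, "biom")$biom, z$biom,
               tolerance = 1e-12)
  d0 <- d; d0$biom <- 7
  expect_error(standardize_biomarker(d0, "biom"), "SD")
})

test_that("eligibility needs two post-baseline observations per modality", {
  mk <- function(id, months_mri, months_pnfl, months_cog) {
    months <- sort(unique(c(months_mri, months_pnfl, months_cog)))
    data.frame(subject_id = id, visit_month = months,
               temporal = ifelse(months %in% months_mri, 2.5, NA),
               hippocampus = NA_real_,
               pnfl = ifelse(months %in% months_pnfl, 20, NA),
               cdrsb = ifelse(months %in% months_cog, 1, NA),
               pacc = NA_real_)
  }
  d <- rbind(mk("ok", c(0, 12, 24), c(0, 12, 24), c(0, 6, 12)),
             mk("short", c(0, 12, 24), c(0, 12), c(0, 6, 12)))
  e <- filter_eligibility(d)
  expect_true(e$eligible[e$subject_id == "ok"])
  expect_false(e$eligible[e$subject_id == "short"])
  expect_match(e$reason[e$subject_id == "short"], "pnfl")
  empty <- filter_eligibility(d[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("overlap intersection keeps common visits, is idempotent and a subset", {
  mk_row <- function(id, m, mri = NA, pnfl = NA, cog = NA)
    data.frame(subject_id = id, visit_month = m, temporal = mri,
               hippocampus = NA_real_, pnfl = pnfl, cdrsb = cog,
               pacc = NA_real_)
  # all modalities at {0,12,24}: unchanged
  full <- do.call(rbind, lapply(c(0, 12, 24), function(m)
    mk_row("s1", m, mri = 2.5, pnfl = 20, cog = 1)))
  out <- intersect_overlapping_visits(full)
  expect_equal(sort(out$visit_month), c(0, 12, 24))
  expect_true(all(!is.na(out$temporal)))
  # MRI only through month 12: everything truncated to {0,12}
  trunc <- full
  trunc$temporal[trunc$visit_month == 24] <- NA
  out <- intersect_overlapping_visits(trunc)
  expect_equal(sort(out$visit_month), c(0, 12))
  # off-schedule cognition at 12.5 months matches the month-12 cluster
  shifted <- rbind(
    mk_row("s2", 0, mri = 2.5, pnfl = 20, cog = 1),
    mk_row("s2", 12, mri = 2.4, pnfl = 21),
    mk_row("s2", 12.5, cog = 1.2),
    mk_row("s2", 24, mri = 2.3, pnfl = 22, cog = 1.4))
  out <- intersect_overlapping_visits(shifted, tolerance = 1)
  expect_equal(sort(out$visit_month), c(0, 12, 24))
  expect_equal(out$cdrsb[out$visit_month == 12], 1.2)
  # idempotence and subset on a messier table
  set.seed(11)
  messy <- do.call(rbind, lapply(1:6, function(i) {
    months <- sort(sample(c(0, 6, 12, 24, 36), 4))
    mk_row(paste0("m", i), months,
           mri = ifelse(runif(4) < 0.7, 2.5, NA),
           pnfl = ifelse(runif(4) < 0.7, 20, NA),
           cog = ifelse(runif(4) < 0.9, 1, NA))
  }))
  once <- intersect_overlapping_visits(messy)
  twice <- intersect_overlapping_visits(once)
  expect_equal(twice, once)
  expect_lte(nrow(once), nrow(messy))
})

test_that("build_cohort assembles assignments end to end", {
  d <- rbind(
    data.frame(subject_id = "ctl", visit_month = c(0, 12, 24),
               cdr_global = 0, suvr = c(0.70, 0.71, 0.72),
               csf_ab42 = c(1500, NA, NA), csf_ptau = c(15, NA, NA)),
    data.frame(subject_id = "pre", visit_month = c(0, 12, 24),
               cdr_global = 0, suvr = c(0.95, 0.96, 0.99),
               csf_ab42 = c(600, NA, NA), csf_ptau = c(20, NA, NA)),
    data.frame(subject_id = "mld", visit_month = c(0, 12, 24),
               cdr_global = 0.5, suvr = NA_real_,
               csf_ab42 = c(500, NA, NA), csf_ptau = c(35, NA, NA)),
    data.frame(subject_id = "exc", visit_month = c(0, 12, 24),
               cdr_global = 2, suvr = c(1.1, NA, NA),
               csf_ab42 = NA_real_, csf_ptau = NA_real_))
  d$pnfl <- 20; d$temporal <- 2.5; d$hippocampus <- 7; d$cdrsb <- 1
  d$pacc <- 0
  out <- build_cohort(d)
  expect_equal(out$group[match(c("ctl", "pre", "mld", "exc"), out$subject_id)],
               c("control", "preclinical_ad", "mild_ad", "excluded"))
  expect_equal(out$amyloid_source[out$subject_id == "mld"], "csf")
  expect_true(out$ptau_positive[out$subject_id == "mld"])
  expect_true(all(out$eligible[out$subject_id %in% c("ctl", "pre", "mld")]))
  expect_false(out$eligible[out$subject_id == "exc"])
})
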