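# Direct random-slope data simulator, independent of the package generator,
# used as the data source when the generator itself is under test elsewhere.
gen_biomarker_data <- function(n, months, beta0 = 0, beta1, sd0 = 1, sd1,
                               sw, corr = 0, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  b0 <- beta0 + sd0 * z1
  b1 <- beta1 + sd1 * (corr * z1 + sqrt(1 - corr^2) * z2)
  J <- length(months)
  data.frame(
    subject_id = rep(sprintf("S%05d", seq_len(n)), each = J),
    visit_month = rep(months, n),
    value = rep(b0, each = J) + rep(b1, each = J) * rep(months / 12, n) +
      rnorm(n * J, 0, sw))
}

# Single-biomarker cohort through the package generator (truth known),
# without the other biomarkers/auxiliaries, for speed.
gen_from_params <- function(n, months, params_row, seed = 1) {
  rows <- lapply(seq_len(n), function(i) {
    set.seed((seed * 48271 + i * 16807) %% 2147483647)
    d <- generate_subject(params_row, months)
    d$subject_id <- sprintf("S%05d", i)
    d
  })
  do.call(rbind, rows)
}

adni_months <- c(0, 6, 12, 24, 36, 48, 60)
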