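# Programmatic fixtures shared across test files.

# the enumerated 4-subject competing-risks example
toy4 <- function() survival_data(c(1, 2, 3, 4), c(1, 2, 1, 0))

new_cohort_for_test <- function(rec) {
  catrisk:::new_cohort(rec, provenance = "test")
}

# a clean record table in the cohort schema
make_records <- function(n = 6, seed = 99) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = sample(25:85, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    bmi = round(runif(n, 18, 34), 1),
    tumor_site = sample(c("breast", "lung", "pancreas", "colon"), n, TRUE),
    site_risk_override = NA_character_,
    hemoglobin_g_dl = round(runif(n, 10.5, 15), 1),
    uses_rbc_growth_factors = FALSE,
    leukocytes_per_ul = round(runif(n, 4000, 10000)),
    platelets_per_ul = round(runif(n, 150e3, 340e3)),
    metastatic = sample(c(TRUE, FALSE), n, TRUE),
    vascular_lymphatic_compression = FALSE,
    prior_vte = FALSE,
    on_anticoagulation = FALSE,
    time_months = round(runif(n, 1, 20), 2),
    event = sample(0:2, n, TRUE),
    stringsAsFactors = FALSE
  )
}

write_records_csv <- function(rec, path = tempfile(fileext = ".csv")) {
  out <- rec
  for (col in names(out)) {
    x <- out[[col]]
    s <- if (is.logical(x)) ifelse(x, "true", "false") else as.character(x)
    s[is.na(x)] <- ""
    out[[col]] <- s
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

# competing-risks cohort with a group effect, for estimator cross-checks
sim_cr_data <- function(n, seed, beta = 0.5, cens = c(2, 20)) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  tv <- rexp(n, 0.15 * exp(beta * x))
  td <- rexp(n, 0.08)
  cc <- runif(n, cens[1], cens[2])
  tt <- pmin(tv, td, cc)
  ev <- ifelse(tv <= pmin(td, cc), 1L, ifelse(td <= cc, 2L, 0L))
  list(time = tt, event = ev, x = x)
}
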