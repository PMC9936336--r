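test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n = 0), "n must be")
  m <- default_marginals()
  m$metastatic <- 1.4
  expect_error(sim_config(covariate_marginals = m), "frequencies")
  expect_error(sim_config(score_level_cif6 = c("0" = 0.1, "1" = 0.2,
                                               "2" = 0.5, ">2" = 1.0)),
               "CIF targets")
  expect_error(sim_config(censoring = list(min_followup = 24,
                                           max_followup = 8,
                                           admin_fraction = 1)),
               "min_followup")
})

test_that("sampling is deterministic under a fixed seed, down to the emitted CSV", {
  c1 <- simulate_cohort(sim_config(n = 50, seed = 123))
  c2 <- simulate_cohort(sim_config(n = 50, seed = 123))
  expect_identical(cohort_records(c1), cohort_records(c2))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_cohort(c1, p1)
  write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # single record reproduces exactly too
  r1 <- cohort_records(sample_covariates(sim_config(n = 1, seed = 5)))
  r2 <- cohort_records(sample_covariates(sim_config(n = 1, seed = 5)))
  expect_identical(r1, r2)
})

test_that("covariate marginals are recovered at scale", {
  coh <- sample_covariates(sim_config(n = 10000, seed = 42))
  rec <- cohort_records(coh)
  # metastatic fraction within 3 SE of 0.68
  se <- sqrt(0.68 * 0.32 / 10000)
  expect_lt(abs(mean(rec$metastatic) - 0.68), 3 * se)
  # threshold indicators consistent with the back-filled labs
  expect_identical(rec$platelets_per_ul >= 350e3,
                   cohort_records(coh)$platelets_per_ul >= 350e3)
  comp <- khorana_components(rec, warn = FALSE)
  expect_lt(abs(mean(comp$thrombocytosis) - 0.193), 0.02)
  expect_lt(abs(mean(comp$anemia_or_esa) - 0.056), 0.01)
  expect_lt(abs(mean(comp$obesity) - 0.040), 0.01)
  # outcome fields unset at this stage
  expect_true(all(is.na(rec$time_months)))
})

test_that("a zero marginal switches a component off entirely", {
  m <- default_marginals()
  m$prior_vte <- 0
  coh <- sample_covariates(sim_config(n = 500, seed = 9,
                                      covariate_marginals = m))
  expect_false(any(cohort_records(coh)$prior_vte))
})

test_that("with no deaths and late censoring the VTE fraction matches P(VTE ever)", {
  cfg <- sim_config(n = 8000, seed = 77, death_rate = 0,
                    censoring = list(min_followup = 900,
                                     max_followup = 1000,
                                     admin_fraction = 1))
  coh <- simulate_cohort(cfg)
  rec <- cohort_records(score_cohort(coh))
  scale6 <- 1 - exp(-6 * cfg$vte_rate)
  for (s in c("0", "1", "2")) {
    sel <- rec$onkotev_stratum == s
    if (sum(sel) < 200) next
    p <- cfg$score_level_cif6[[s]] / scale6
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(rec$event[sel] == 1) - p), 3 * se)
  }
})

test_that("zero CIF targets produce no VTE events at all", {
  cfg <- sim_config(n = 400, seed = 13,
                    score_level_cif6 = c("0" = 0, "1" = 0, "2" = 0, ">2" = 0))
  coh <- simulate_cohort(cfg)
  expect_equal(sum(cohort_records(coh)$event == 1), 0L)
})

test_that("the per-stratum 6-month CIF converges to the configured targets", {
  cfg <- sim_config(n = 20000, seed = 2024)
  coh <- simulate_cohort(cfg)
  rec <- cohort_records(score_cohort(coh))
  d <- survival_data(rec$time_months, rec$event, group = rec$onkotev_stratum)
  cifs <- estimate_cif(d, 1)
  for (s in names(cifs)) {
    n_s <- sum(rec$onkotev_stratum == s)
    if (n_s < 500) next
    target <- cfg$score_level_cif6[[s]]
    est <- unname(cif_at(cifs[[s]], 6)["point"])
    mc_se <- sqrt(target * (1 - target) / n_s)
    expect_lt(abs(est - target), 3 * mc_se)
  }
})

test_that("simulated events always carry positive times and valid codes", {
  rec <- cohort_records(simulate_cohort(sim_config(n = 1000, seed = 55)))
  expect_true(all(rec$event %in% 0:2))
  expect_true(all(rec$time_months[rec$event != 0] > 0))
  expect_true(all(rec$time_months >= 0))
})
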