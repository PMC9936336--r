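test_that("the 4-subject example reproduces the hand product-limit values", {
  d <- toy4()
  e1 <- estimate_cif(d, 1)
  e2 <- estimate_cif(d, 2)
  expect_equal(e1$times, c(1, 2, 3))
  expect_equal(e1$cif, c(0.25, 0.25, 0.50))
  expect_equal(e2$cif, c(0, 0.25, 0.25))
  # step lookups
  expect_equal(unname(cif_at(e1, 2.5)["point"]), 0.25)
  expect_equal(unname(cif_at(e1, 0)["point"]), 0)
  expect_equal(unname(cif_at(e1, 100)["point"]), 0.50)
  expect_equal(unname(cif_at(e1, 0.5)), c(0, 0, 0))
})

test_that("degenerate inputs behave per contract", {
  # single subject with an event
  one <- estimate_cif(survival_data(5, 1), 1)
  expect_equal(one$cif, 1)
  expect_equal(unname(cif_at(one, 5)["point"]), 1)
  # all censored: CIF identically zero with empty times
  none <- estimate_cif(survival_data(c(1, 2, 3), c(0, 0, 0)), 1)
  expect_equal(length(none$times), 0L)
  expect_equal(unname(cif_at(none, 10)["point"]), 0)
  # empty data errors at construction
  expect_error(survival_data(numeric(0), integer(0)))
})

test_that("single-cause CIF equals 1 - Kaplan-Meier (survfit oracle)", {
  library(survival)
  set.seed(12)
  tm <- round(rexp(80, 0.2), 3)
  ev <- rbinom(80, 1, 0.6)
  est <- estimate_cif(survival_data(tm, ev), 1)
  sf <- survfit(Surv(tm, ev) ~ 1)
  km_at <- summary(sf, times = est$times)$surv
  expect_equal(est$cif, 1 - km_at, tolerance = 1e-12)
  # and with a single cause and no censoring it is the empirical CDF
  est2 <- estimate_cif(survival_data(tm, rep(1, 80)), 1)
  expect_equal(est2$cif, ecdf(tm)(est2$times))
})

test_that("estimate_cif matches the naive product-limit oracle over full small-n enumerations", {
  for (n in 2:6) {
    times <- seq_len(n)
    evs <- enumerate_events(n)
    for (r in seq_len(nrow(evs))) {
      ev <- evs[r, ]
      if (all(ev == 0)) next
      d <- survival_data(times, ev)
      for (cause in 1:2) {
        est <- estimate_cif(d, cause)
        at <- c(times, n + 0.5)
        mine <- vapply(at, function(t) unname(cif_at(est, t)["point"]),
                       numeric(1))
        expect_equal(mine, oracle_cif(times, ev, cause, at),
                     tolerance = 1e-12)
      }
    }
  }
  # tied times are processed against a common risk set
  d <- survival_data(c(1, 1, 2, 2, 3), c(1, 2, 1, 0, 1))
  est <- estimate_cif(d, 1)
  expect_equal(est$cif,
               oracle_cif(c(1, 1, 2, 2, 3), c(1, 2, 1, 0, 1), 1, est$times),
               tolerance = 1e-12)
})

test_that("CIF1 + CIF2 + KM survivor is 1 at every event time on censoring-free data", {
  set.seed(8)
  tm <- rexp(60, 0.3)
  ev <- sample(1:2, 60, TRUE)
  d <- survival_data(tm, ev)
  e1 <- estimate_cif(d, 1)
  e2 <- estimate_cif(d, 2)
  km <- catrisk:::km_curve(tm, rep(1, 60))
  at <- sort(unique(tm))
  tot <- vapply(at, function(t) {
    unname(cif_at(e1, t)["point"]) + unname(cif_at(e2, t)["point"]) +
      catrisk:::km_eval(km, t)
  }, numeric(1))
  expect_equal(tot, rep(1, length(at)), tolerance = 1e-10)
})

test_that("confidence bounds bracket the estimate inside [0,1] and match cmprsk closely", {
  library(cmprsk)
  set.seed(42)
  n <- 120
  tm <- rexp(n, 0.1)
  ev <- sample(0:2, n, TRUE, c(0.3, 0.4, 0.3))
  d <- survival_data(tm, ev)
  est <- estimate_cif(d, 1)
  expect_true(all(est$ci_low >= 0 & est$ci_high <= 1))
  expect_true(all(est$ci_low <= est$cif + 1e-12 &
                    est$cif <= est$ci_high + 1e-12))
  expect_true(all(diff(est$cif) >= 0))
  cu <- cuminc(tm, ev, cencode = 0)
  tp <- timepoints(cu, c(2, 5, 8))
  mine <- vapply(c(2, 5, 8), function(t) unname(cif_at(est, t)["point"]),
                 numeric(1))
  expect_equal(mine, unname(tp$est["1 1", ]), tolerance = 1e-12)
  myvar <- vapply(c(2, 5, 8), function(t) {
    i <- findInterval(t, est$times)
    c(0, est$variance)[i + 1]
  }, numeric(1))
  # same counting-process variance up to an equivalent small-sample form
  expect_equal(myvar, unname(tp$var["1 1", ]), tolerance = 0.05)
})

test_that("per-group estimation returns one curve per non-empty group", {
  d <- survival_data(c(1, 2, 3, 4, 1.5, 2.5), c(1, 0, 1, 2, 1, 0),
                     group = c("a", "a", "a", "a", "b", "b"))
  by_g <- estimate_cif(d, 1)
  expect_s3_class(by_g, "cif_by_group")
  expect_named(by_g, c("a", "b"))
  expect_equal(by_g$a$cif,
               oracle_cif(c(1, 2, 3, 4), c(1, 0, 1, 2), 1, by_g$a$times))
})

test_that("incidence_rate is events per 100 person-months", {
  expect_equal(round(incidence_rate(54, 4865), 1), 1.1)
  expect_equal(incidence_rate(0, 500), 0)
  expect_equal(incidence_rate(1, 100), 1)
  expect_error(incidence_rate(5, 0), "positive")
})
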