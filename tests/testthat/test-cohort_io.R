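test_that("a well-formed file parses to an identical cohort with empty filter log", {
  rec <- make_records(3)
  path <- write_records_csv(rec)
  coh <- read_cohort(path)
  expect_s3_class(coh, "cohort")
  expect_equal(nrow(cohort_records(coh)), 3L)
  expect_equal(nrow(coh$filter_log), 0L)
  expect_equal(cohort_records(coh)$patient_id, rec$patient_id)
  expect_equal(cohort_records(coh)$time_months, rec$time_months)
  expect_equal(length(coh$parse_report), 0L)
})

test_that("unparseable and out-of-range cells become missing and are counted", {
  rec <- make_records(4)
  out <- rec
  out$platelets_per_ul <- as.character(out$platelets_per_ul)
  out$platelets_per_ul[2] <- "not-a-number"
  path <- tempfile(fileext = ".csv")
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  coh <- read_cohort(path)
  expect_equal(nrow(cohort_records(coh)), 4L)
  expect_true(is.na(cohort_records(coh)$platelets_per_ul[2]))
  expect_equal(coh$parse_report[["platelets_per_ul"]], 1L)

  rec2 <- make_records(3)
  rec2$bmi[1] <- 120  # outside the (10, 80) sanity bounds
  coh2 <- read_cohort(write_records_csv(rec2))
  expect_true(is.na(cohort_records(coh2)$bmi[1]))
  expect_equal(coh2$parse_report[["bmi"]], 1L)
})

test_that("schema and validation errors are raised with names", {
  rec <- make_records(3)
  expect_error(read_cohort(write_records_csv(rec[setdiff(names(rec), "event")])),
               "event")
  dup <- rec
  dup$patient_id <- c("A", "A", "B")
  expect_error(read_cohort(write_records_csv(dup)), "duplicate.*A")
  bad <- rec
  bad$event <- c(0L, 3L, 1L)
  expect_error(read_cohort(write_records_csv(bad)), "event codes")
  neg <- rec
  neg$event <- c(1L, 0L, 0L)
  neg$time_months[1] <- 0
  expect_error(read_cohort(write_records_csv(neg)), "non-positive time")
})

test_that("write_cohort/read_cohort round-trips field values exactly", {
  rec <- make_records(8)
  rec$time_months <- rec$time_months + 1 / 3  # non-terminating decimals
  coh <- new_cohort_for_test(rec)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  for (col in names(rec)) {
    expect_equal(cohort_records(back)[[col]], rec[[col]],
                 ignore_attr = TRUE, label = col)
  }
})

test_that("eligibility filter removes anticoagulated and under-age records with separate logs", {
  rec <- make_records(5)
  rec$on_anticoagulation[2] <- TRUE
  rec$age_years[4] <- 17
  coh <- eligibility_filter(read_cohort(write_records_csv(rec)))
  kept <- cohort_records(coh)
  expect_equal(nrow(kept), 3L)
  expect_false("P002" %in% kept$patient_id)
  expect_false("P004" %in% kept$patient_id)
  expect_equal(coh$filter_log$n_removed, c(1L, 1L))
  # all-eligible cohort passes unchanged
  coh2 <- eligibility_filter(read_cohort(write_records_csv(make_records(4))))
  expect_equal(nrow(cohort_records(coh2)), 4L)
  expect_equal(sum(coh2$filter_log$n_removed), 0L)
})

test_that("complete-case filter drops undecidable scores and reproduces an exclusion flow", {
  # 473 records, 48 with a missing required input -> 425 retained
  rec <- make_records(473, seed = 11)
  rec$event <- rep(0:2, length.out = 473)
  rec$time_months <- pmax(rec$time_months, 0.5)
  drop_idx <- sample(473, 48)
  cols <- c("metastatic", "prior_vte", "vascular_lymphatic_compression",
            "time_months", "bmi", "platelets_per_ul")
  for (k in seq_along(drop_idx)) {
    rec[drop_idx[k], cols[1 + (k %% length(cols))]] <- NA
  }
  coh <- complete_case_filter(new_cohort_for_test(rec))
  expect_equal(nrow(cohort_records(coh)), 425L)
  expect_equal(coh$filter_log$n_removed, 48L)

  # no missing values -> unchanged with an n = 0 log entry
  clean <- complete_case_filter(new_cohort_for_test(make_records(10)))
  expect_equal(nrow(cohort_records(clean)), 10L)
  expect_equal(clean$filter_log$n_removed, 0L)
})

test_that("missing bmi makes the Khorana >2 flag undecidable and excludes the record", {
  rec <- make_records(2)
  rec$tumor_site <- "pancreas"  # very-high site, score >= 2 before obesity
  rec$bmi[1] <- NA
  coh <- complete_case_filter(new_cohort_for_test(rec))
  expect_equal(cohort_records(coh)$patient_id, "P002")
})

test_that("anemia component uses three-valued OR: ESA use decides it without hemoglobin", {
  rec <- make_records(2)
  rec$hemoglobin_g_dl <- NA
  rec$uses_rbc_growth_factors <- c(TRUE, FALSE)
  comp <- khorana_components(rec)
  expect_true(comp$anemia_or_esa[1])
  expect_true(is.na(comp$anemia_or_esa[2]))
})

test_that("filters are record-local: order does not change the retained set, counts reconcile", {
  rec <- make_records(60, seed = 5)
  rec$on_anticoagulation[c(3, 9)] <- TRUE
  rec$age_years[12] <- 16
  rec$metastatic[c(5, 20, 33)] <- NA
  coh <- new_cohort_for_test(rec)
  a <- complete_case_filter(eligibility_filter(coh))
  b <- eligibility_filter(complete_case_filter(coh))
  expect_equal(sort(cohort_records(a)$patient_id),
               sort(cohort_records(b)$patient_id))
  expect_equal(sum(a$filter_log$n_removed) + nrow(cohort_records(a)), 60L)
  expect_equal(sum(b$filter_log$n_removed) + nrow(cohort_records(b)), 60L)
})

test_that("summarize_cohort emits one-decimal percentages and derived flag rows", {
  # 425 records, 289 metastatic -> "metastatic yes 289 (68.0)"
  rec <- make_records(425, seed = 21)
  rec$metastatic <- rep(c(TRUE, FALSE), c(289, 136))
  tab <- summarize_cohort(new_cohort_for_test(rec))
  met <- tab[tab$block == "metastatic" & tab$level == "yes", ]
  expect_equal(met$n, 289L)
  expect_equal(met$pct, 68.0)

  # Khorana distribution with 29/8/1 at scores 3/4/5 gives a >2 count of 38
  n <- 425
  rec2 <- make_records(n, seed = 22)
  rec2$tumor_site <- "breast"
  rec2$hemoglobin_g_dl <- 12
  rec2$uses_rbc_growth_factors <- FALSE
  rec2$leukocytes_per_ul <- 8000
  rec2$platelets_per_ul <- 200e3
  rec2$bmi <- 25
  # force scores: 3 = very_high site + 1 component, 4 = +2, 5 = +3
  rec2$tumor_site[1:38] <- "pancreas"
  rec2$platelets_per_ul[1:38] <- 400e3
  rec2$leukocytes_per_ul[1:9] <- 12000
  rec2$hemoglobin_g_dl[1:1] <- 9
  tab2 <- summarize_cohort(new_cohort_for_test(rec2))
  ks <- tab2[tab2$block == "khorana_score", ]
  expect_equal(ks$n[ks$level == "3"], 29L)
  expect_equal(ks$n[ks$level == "4"], 8L)
  expect_equal(ks$n[ks$level == "5"], 1L)
  flag <- tab2[tab2$block == "khorana_flag", ]
  expect_equal(flag$n[flag$level == ">2"], 38L)
  expect_equal(flag$pct[flag$level == ">2"], 8.9)
  expect_equal(flag$n[flag$level == "<=2"], 387L)

  # single record -> percentages are 0 or 100
  tab3 <- summarize_cohort(new_cohort_for_test(make_records(1)))
  expect_true(all(tab3$pct %in% c(0, 100)))

  # empty cohort -> empty-summary marker, not a crash
  tab4 <- summarize_cohort(new_cohort_for_test(make_records(2)[0, ]))
  expect_equal(nrow(tab4), 0L)
  expect_true(isTRUE(attr(tab4, "empty")))
})
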