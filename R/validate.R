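#' Events-per-variable sample-size planning
#'
#' Minimum cohort size so that the expected number of events supplies at
#' least `events_per_variable` events for each of `n_predictors` model
#' covariates: `ceil(events_per_variable * n_predictors / expected_incidence)`.
#'
#' @param events_per_variable required events per predictor (classically 10).
#' @param n_predictors number of model covariates.
#' @param expected_incidence anticipated event proportion, in (0, 1).
#' @return Integer minimum sample size.
#' @examples
#' epv_sample_size(10, 4, 0.10) # 400
#' @export
epv_sample_size <- function(events_per_variable, n_predictors,
                            expected_incidence) {
  if (events_per_variable <= 0 || n_predictors <= 0) {
    stop("events_per_variable and n_predictors must be positive", call. = FALSE)
  }
  if (expected_incidence <= 0 || expected_incidence >= 1) {
    stop("expected_incidence must be in (0, 1)", call. = FALSE)
  }
  as.integer(ceiling(events_per_variable * n_predictors / expected_incidence))
}

#' Run the full score-validation pipeline on a cohort
#'
#' Scores the cohort, stratifies it into the four ONKOTEV levels, and
#' produces every validation surface: baseline summary table, score and
#' stratum distributions, first-event counts, the VTE incidence rate per 100
#' person-months, per-stratum cumulative incidence of VTE (with the 6-month
#' point and full step curves), Gray's test across non-empty strata, the
#' multivariable Fine-Gray model on the four score components, the
#' time-dependent AUC at the landmark horizons (marker = integer ONKOTEV
#' score), and the events-per-variable sample-size check. Deterministic
#' given the cohort and configuration; no multiplicity adjustment is applied
#' (single Gray test, per-covariate Fine-Gray p-values).
#'
#' @param cohort a filtered `cohort` with outcomes present (scored or not).
#' @param horizons landmark horizons in months for the time-dependent AUC.
#' @param landmark_months time at which per-stratum cumulative incidence is
#'   reported.
#' @param epv list with `events_per_variable` and `expected_incidence` for
#'   the sample-size check.
#' @param mapping tumor-site risk mapping.
#' @param fg_config a [fg_control()] list.
#' @return Object of class `validation_report`.
#' @export
run_validation <- function(cohort, horizons = c(3, 6, 12),
                           landmark_months = 6,
                           epv = list(events_per_variable = 10,
                                      expected_incidence = 0.10),
                           mapping = default_site_risk(),
                           fg_config = fg_control()) {
  scored <- if ("onkotev_stratum" %in% names(cohort_records(cohort))) {
    cohort
  } else {
    score_cohort(cohort, mapping)
  }
  rec <- cohort_records(scored)
  if (anyNA(rec$time_months) || anyNA(rec$event)) {
    stop("outcomes missing; apply complete_case_filter first", call. = FALSE)
  }
  n <- nrow(rec)
  notes <- character(0)
  sdat <- as_survival_data(scored)

  events <- c(vte_first = sum(rec$event == 1L),
              death_first = sum(rec$event == 2L),
              censored = sum(rec$event == 0L))
  rate <- incidence_rate(events[["vte_first"]], sum(rec$time_months))

  score_distribution <- table(factor(rec$onkotev_score, levels = 0:4))
  stratum_counts <- table(rec$onkotev_stratum)
  vte_by_stratum <- tapply(rec$event == 1L, rec$onkotev_stratum, sum,
                           default = 0L)

  nonempty <- names(stratum_counts)[stratum_counts > 0L]
  if (length(nonempty) < length(stratum_counts)) {
    notes <- c(notes, paste("empty stratum omitted from CIF:",
                            paste(setdiff(names(stratum_counts), nonempty),
                                  collapse = ", ")))
  }
  cif_by_stratum <- estimate_cif(sdat, cause = 1)
  cif_landmark <- t(vapply(cif_by_stratum, cif_at, numeric(3),
                           t = landmark_months))

  gray <- if (length(nonempty) >= 2L) {
    gray_test(sdat, cause = 1)
  } else {
    notes <- c(notes, "single non-empty stratum; Gray's test not computed")
    NULL
  }

  fg <- fine_gray_fit(sdat, cause = 1, config = fg_config)
  if (!fg$converged) notes <- c(notes, "Fine-Gray fit did not converge")

  auc <- lapply(horizons, function(h) td_auc(sdat, rec$onkotev_score, h))
  names(auc) <- paste0("m", horizons)
  auc_table <- do.call(rbind, lapply(auc, function(a) {
    data.frame(horizon_months = a$horizon, auc = a$auc, ci_low = a$ci_low,
               ci_high = a$ci_high, n_cases = a$n_cases,
               n_controls = a$n_controls)
  }))
  rownames(auc_table) <- NULL

  required_n <- epv_sample_size(epv$events_per_variable,
                                ncol(sdat$covariates),
                                epv$expected_incidence)
  power <- list(events_per_variable = epv$events_per_variable,
                n_predictors = ncol(sdat$covariates),
                expected_incidence = epv$expected_incidence,
                required_n = required_n, cohort_n = n,
                adequate = n >= required_n)

  structure(
    list(cohort_summary = summarize_cohort(scored, mapping),
         n = n,
         score_distribution = score_distribution,
         stratum_counts = stratum_counts,
         vte_by_stratum = vte_by_stratum,
         events = events,
         rate_per_100pm = rate,
         cif_by_stratum = cif_by_stratum,
         cif_landmark = cif_landmark,
         landmark_months = landmark_months,
         gray = gray,
         fine_gray = fg,
         fine_gray_table = fine_gray_table(fg),
         auc = auc,
         auc_table = auc_table,
         power = power,
         settings = list(horizons = horizons,
                         landmark_months = landmark_months,
                         significance_level = 0.05,
                         variance = "robust sandwich",
                         multiplicity_adjustment = "none",
                         filters = cohort$filter_log,
                         provenance = cohort$provenance),
         notes = notes),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("=== score validation report (n =", x$n, ") ===\n")
  cat("first events: VTE", x$events[["vte_first"]],
      "| death", x$events[["death_first"]],
      "| censored", x$events[["censored"]], "\n")
  cat(sprintf("VTE incidence rate: %.1f per 100 person-months\n",
              x$rate_per_100pm))
  cat("\nONKOTEV strata:\n")
  df <- data.frame(stratum = names(x$stratum_counts),
                   n = as.integer(x$stratum_counts),
                   vte = as.integer(x$vte_by_stratum[names(x$stratum_counts)]),
                   cif_landmark = round(x$cif_landmark[, "point"], 3))
  print(df, row.names = FALSE)
  if (!is.null(x$gray)) {
    cat("\n")
    print(x$gray)
  }
  cat("\n")
  print(x$fine_gray)
  cat("\ntime-dependent AUC (marker = ONKOTEV score):\n")
  print(transform(x$auc_table, auc = round(auc, 2), ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2)), row.names = FALSE)
  cat(sprintf("\nEPV check: %d predictors x %g events => n >= %d (%s)\n",
              x$power$n_predictors, x$power$events_per_variable,
              x$power$required_n,
              if (x$power$adequate) "adequate" else "inadequate"))
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Write a validation report to a directory
#'
#' Serializes the report as delimited tables (cohort summary, stratum table,
#' per-stratum CIF step curves, Fine-Gray table, AUC table) plus a
#' machine-readable `summary.json` echoing every setting and filter for
#' provenance.
#'
#' @param report a `validation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = ",", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(report$cohort_summary, "cohort_summary.csv")
  strat <- data.frame(
    stratum = names(report$stratum_counts),
    n = as.integer(report$stratum_counts),
    vte = as.integer(report$vte_by_stratum[names(report$stratum_counts)]),
    cif = report$cif_landmark[, "point"],
    ci_low = report$cif_landmark[, "ci_low"],
    ci_high = report$cif_landmark[, "ci_high"]
  )
  wr(strat, "stratum_table.csv")
  curves <- do.call(rbind, lapply(names(report$cif_by_stratum), function(g) {
    est <- report$cif_by_stratum[[g]]
    if (length(est$times) == 0L) return(NULL)
    data.frame(stratum = g, time = est$times, cif = est$cif,
               ci_low = est$ci_low, ci_high = est$ci_high)
  }))
  if (!is.null(curves)) wr(curves, "cif_curves.csv")
  wr(report$fine_gray_table, "fine_gray.csv")
  wr(report$auc_table, "td_auc.csv")
  summary <- list(
    n = report$n,
    events = as.list(report$events),
    rate_per_100pm = report$rate_per_100pm,
    score_distribution = as.list(report$score_distribution),
    stratum_counts = as.list(report$stratum_counts),
    gray = if (!is.null(report$gray)) {
      list(statistic = report$gray$statistic, df = report$gray$df,
           p_value = report$gray$p_value)
    } else {
      NULL
    },
    power = report$power,
    settings = report$settings[setdiff(names(report$settings), "filters")],
    filters = report$settings$filters,
    notes = report$notes
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(dir, "summary.json"))
  invisible(dir)
}
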