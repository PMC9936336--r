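#' @importFrom utils read.csv write.table head tail
NULL

# fixed cohort schema: column -> type
.cohort_schema <- c(
  patient_id = "character", age_years = "numeric", sex = "character",
  bmi = "numeric", tumor_site = "character", site_risk_override = "character",
  hemoglobin_g_dl = "numeric", uses_rbc_growth_factors = "logical",
  leukocytes_per_ul = "numeric", platelets_per_ul = "numeric",
  metastatic = "logical", vascular_lymphatic_compression = "logical",
  prior_vte = "logical", on_anticoagulation = "logical",
  time_months = "numeric", event = "integer"
)
.mandatory_cols <- c("patient_id", "time_months", "event")

parse_bool <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "yes")] <- TRUE
  out[lx %in% c("0", "false", "no")] <- FALSE
  attr(out, "n_bad") <- sum(!is.na(x) & nzchar(trimws(x)) &
                              !lx %in% c("1", "true", "yes", "0", "false", "no"))
  out
}

parse_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  attr(out, "n_bad") <- sum(!is.na(x) & nzchar(trimws(x)) & is.na(out))
  out
}

new_cohort <- function(records, provenance = "", filter_log = NULL,
                       parse_report = integer(0)) {
  if (is.null(filter_log)) {
    filter_log <- data.frame(filter = character(0), n_removed = integer(0),
                             reason = character(0), stringsAsFactors = FALSE)
  }
  structure(list(records = records, provenance = provenance,
                 filter_log = filter_log, parse_report = parse_report),
            class = "cohort")
}

#' Access the record table of a cohort
#' @param cohort a `cohort` object.
#' @return The underlying data frame of patient records.
#' @export
cohort_records <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$records
}

#' Read a patient cohort from delimited text
#'
#' Parses a UTF-8 delimited file (comma by default) with a mandatory header
#' into a validated cohort. The schema is fixed: `patient_id`, `age_years`,
#' `sex`, `bmi`, `tumor_site`, `site_risk_override`, `hemoglobin_g_dl`,
#' `uses_rbc_growth_factors`, `leukocytes_per_ul`, `platelets_per_ul`,
#' `metastatic`, `vascular_lymphatic_compression`, `prior_vte`,
#' `on_anticoagulation`, `time_months`, `event`. Booleans accept
#' `0/1/true/false/yes/no` (case-insensitive); the empty string is missing;
#' `event` codes are 0 = censored, 1 = VTE first, 2 = death first.
#'
#' Unparseable cells become missing values and are counted per column in the
#' cohort's `parse_report`; hard record invariants (negative time, event code
#' outside 0-2, an event at time 0) raise validation errors. BMI outside
#' (10, 80) and hemoglobin outside (2, 25) g/dL fail the sanity bounds and
#' are rejected to missing, counted in the parse report.
#'
#' @param path file path.
#' @param delim field delimiter (`","` default, `"\t"` supported).
#' @param aliases optional named character vector mapping file column names
#'   to schema names.
#' @param provenance free-text label stored on the cohort (defaults to the
#'   file name).
#' @return A `cohort` object.
#' @export
read_cohort <- function(path, delim = ",", aliases = NULL,
                        provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- aliases[names(raw)[hit]]
  }
  miss <- setdiff(.mandatory_cols, names(raw))
  if (length(miss) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  report <- integer(0)
  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in names(.cohort_schema)) {
    x <- if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
    x[is.na(x)] <- ""
    x[!nzchar(trimws(x))] <- NA_character_
    val <- switch(.cohort_schema[[col]],
      character = trimws(x),
      numeric = parse_num(x),
      integer = {
        v <- parse_num(x)
        iv <- as.integer(v)
        attr(iv, "n_bad") <- attr(v, "n_bad")
        iv
      },
      logical = parse_bool(x)
    )
    nb <- attr(val, "n_bad")
    if (!is.null(nb) && nb > 0L) report[col] <- nb
    attr(val, "n_bad") <- NULL
    rec[[col]] <- val
  }
  # sanity bounds: reject out-of-range labs to missing, count them
  for (spec in list(list("bmi", 10, 80), list("hemoglobin_g_dl", 2, 25))) {
    col <- spec[[1]]
    bad <- !is.na(rec[[col]]) & (rec[[col]] <= spec[[2]] | rec[[col]] >= spec[[3]])
    if (any(bad)) {
      rec[[col]][bad] <- NA_real_
      report[col] <- sum(bad) + if (col %in% names(report)) report[[col]] else 0L
    }
  }
  if (anyNA(rec$patient_id)) {
    stop("validation error: missing patient_id", call. = FALSE)
  }
  dup <- unique(rec$patient_id[duplicated(rec$patient_id)])
  if (length(dup) > 0L) {
    stop("validation error: duplicate patient_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_event <- !is.na(rec$event) & !rec$event %in% 0:2
  if (any(bad_event)) {
    stop("validation error: event codes outside {0,1,2} for: ",
         paste(rec$patient_id[bad_event], collapse = ", "), call. = FALSE)
  }
  bad_time <- !is.na(rec$time_months) & rec$time_months < 0
  if (any(bad_time)) {
    stop("validation error: negative time_months for: ",
         paste(rec$patient_id[bad_time], collapse = ", "), call. = FALSE)
  }
  bad_zero <- !is.na(rec$event) & rec$event != 0L &
    !is.na(rec$time_months) & rec$time_months <= 0
  if (any(bad_zero)) {
    stop("validation error: event at non-positive time for: ",
         paste(rec$patient_id[bad_zero], collapse = ", "), call. = FALSE)
  }
  new_cohort(rec, provenance = provenance, parse_report = report)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()] for clean data: logicals as `true`/`false`,
#' numerics in shortest round-trip notation, missing as the empty string.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  rec <- cohort_records(cohort)
  out <- rec
  for (col in names(out)) {
    x <- out[[col]]
    s <- if (is.logical(x)) ifelse(x, "true", "false") else as.character(x)
    s[is.na(x)] <- ""
    out[[col]] <- s
  }
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

add_filter_log <- function(cohort, name, n_removed, reason) {
  cohort$filter_log <- rbind(
    cohort$filter_log,
    data.frame(filter = name, n_removed = as.integer(n_removed),
               reason = reason, stringsAsFactors = FALSE)
  )
  cohort
}

#' Eligibility filter
#'
#' Removes subjects on therapeutic anticoagulation at baseline and subjects
#' younger than 18 years, logging each rule's count separately.
#'
#' @param cohort a `cohort`.
#' @param min_age minimum eligible age in years.
#' @return The filtered `cohort` with two new `filter_log` entries.
#' @export
eligibility_filter <- function(cohort, min_age = 18) {
  rec <- cohort_records(cohort)
  drop_ac <- !is.na(rec$on_anticoagulation) & rec$on_anticoagulation
  cohort$records <- rec[!drop_ac, , drop = FALSE]
  cohort <- add_filter_log(cohort, "anticoagulation", sum(drop_ac),
                           "baseline anticoagulation therapy")
  rec <- cohort$records
  drop_age <- !is.na(rec$age_years) & rec$age_years < min_age
  cohort$records <- rec[!drop_age, , drop = FALSE]
  add_filter_log(cohort, "age_under_min", sum(drop_age),
                 sprintf("age below %g years", min_age))
}

#' Complete-case filter on the score inputs and the outcome
#'
#' Removes any record for which the ONKOTEV score or the outcome cannot be
#' evaluated: a missing Khorana component (so the Khorana > 2 flag is treated
#' as missing whenever any component is undecidable), missing metastatic
#' status, vascular/lymphatic compression, prior VTE, follow-up time or event
#' code. The anemia component uses three-valued OR logic (hemoglobin < 10
#' g/dL OR use of RBC growth factors), so it is decidable when either input
#' already forces the value.
#'
#' @param cohort a `cohort`.
#' @param mapping tumor-site risk mapping, see [default_site_risk()].
#' @return The filtered `cohort` with a `complete_case` filter-log entry.
#' @export
complete_case_filter <- function(cohort, mapping = default_site_risk()) {
  rec <- cohort_records(cohort)
  if (nrow(rec) == 0L) {
    return(add_filter_log(cohort, "complete_case", 0L,
                          "missing score input or outcome"))
  }
  comp <- khorana_components(rec, mapping = mapping, warn = FALSE)
  khorana_ok <- stats::complete.cases(comp)
  keep <- khorana_ok &
    !is.na(rec$metastatic) &
    !is.na(rec$vascular_lymphatic_compression) &
    !is.na(rec$prior_vte) &
    !is.na(rec$time_months) &
    !is.na(rec$event)
  cohort$records <- rec[keep, , drop = FALSE]
  add_filter_log(cohort, "complete_case", sum(!keep),
                 "missing score input or outcome")
}

one_dec <- function(x) round(x, 1)

summary_block <- function(block, level, n, denom) {
  data.frame(block = block, level = as.character(level), n = as.integer(n),
             pct = one_dec(100 * n / denom), stringsAsFactors = FALSE)
}

#' Summarize a cohort in the style of a baseline characteristics table
#'
#' Counts and percentages (one decimal, over non-missing n) for: tumor site,
#' each Khorana component, the Khorana score distribution with the derived
#' `<=2` / `>2` split, each ONKOTEV component, and the ONKOTEV score and
#' stratum distributions.
#'
#' @param cohort a `cohort` (normally after filtering).
#' @param mapping tumor-site risk mapping.
#' @return A data frame with columns `block`, `level`, `n`, `pct`. An empty
#'   cohort returns a zero-row frame carrying attribute `empty = TRUE`.
#' @export
summarize_cohort <- function(cohort, mapping = default_site_risk()) {
  rec <- cohort_records(cohort)
  empty <- summary_block(character(0), character(0), integer(0), 1)
  if (nrow(rec) == 0L) {
    attr(empty, "empty") <- TRUE
    return(empty)
  }
  out <- list()
  tab_of <- function(x, block, levels = NULL) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(empty)
    tb <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
    summary_block(block, names(tb), as.integer(tb), length(x))
  }
  out$site <- tab_of(rec$tumor_site, "tumor_site")
  comp <- khorana_components(rec, mapping = mapping, warn = FALSE)
  out$risk <- tab_of(comp$site_risk, "tumor_risk",
                     levels = c("low", "high", "very_high"))
  yn <- function(x) ifelse(x, "yes", "no")
  out$anemia <- tab_of(yn(comp$anemia_or_esa), "hgb_lt10_or_esa", c("no", "yes"))
  out$leuko <- tab_of(yn(comp$leukocytosis), "leukocytes_gt_11000", c("no", "yes"))
  out$plt <- tab_of(yn(comp$thrombocytosis), "platelets_ge_350k", c("no", "yes"))
  out$bmi <- tab_of(yn(comp$obesity), "bmi_ge_35", c("no", "yes"))
  ks <- khorana_score(comp, na_action = "na")
  out$khorana <- tab_of(ks, "khorana_score", levels = as.character(0:6))
  out$khorana <- out$khorana[out$khorana$n > 0 |
                               out$khorana$level %in% as.character(0:3), ]
  kv <- ks[!is.na(ks)]
  out$kflag <- summary_block("khorana_flag", c("<=2", ">2"),
                             c(sum(kv <= 2), sum(kv > 2)), length(kv))
  oc <- onkotev_components(rec, khorana = ks)
  out$gt2 <- tab_of(yn(oc$khorana_gt2), "khorana_gt2", c("no", "yes"))
  out$pv <- tab_of(yn(oc$prior_vte), "prior_vte", c("no", "yes"))
  out$met <- tab_of(yn(oc$metastatic), "metastatic", c("no", "yes"))
  out$compr <- tab_of(yn(oc$compression), "vascular_lymphatic_compression",
                      c("no", "yes"))
  os <- onkotev_score(oc, na_action = "na")
  out$onkotev <- tab_of(os, "onkotev_score", levels = as.character(0:4))
  out$stratum <- tab_of(as.character(onkotev_stratum(os)), "onkotev_stratum",
                        levels = c("0", "1", "2", ">2"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$records), "records")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  if (length(x$parse_report) > 0L) {
    cat("parse report (cells set to missing):",
        paste(sprintf("%s=%d", names(x$parse_report), x$parse_report),
              collapse = ", "), "\n")
  }
  if (nrow(x$filter_log) > 0L) {
    cat("filters applied:\n")
    print(x$filter_log, row.names = FALSE)
  }
  invisible(x)
}
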