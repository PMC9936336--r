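#' Analysis-ready survival data for competing-risks estimation
#'
#' Bundles follow-up time (months), a cause-coded first-event indicator
#' (0 = censored, 1 = VTE, 2 = death as first event), an optional grouping
#' factor (e.g. the ONKOTEV stratum) and an optional numeric covariate matrix
#' into a validated container consumed by [estimate_cif()], [gray_test()],
#' [fine_gray_fit()] and [td_auc()].
#'
#' @param time numeric vector of positive follow-up times in months.
#' @param event integer vector in `{0, 1, 2}`; `0` censored, `1` event of
#'   interest (VTE), `2` competing event (death first).
#' @param group optional factor/character vector of group labels.
#' @param covariates optional numeric matrix (or data frame coercible to one)
#'   with one row per subject and named columns.
#' @return An object of class `survival_data`.
#' @examples
#' survival_data(c(1, 2, 3, 4), c(1, 2, 1, 0))
#' @export
survival_data <- function(time, event, group = NULL, covariates = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  chk_survival_vectors(time, event)
  if (any(time <= 0 & event != 0L)) {
    stop("event times must be strictly positive", call. = FALSE)
  }
  n <- length(time)
  if (!is.null(group)) {
    if (length(group) != n) stop("group length differs from time", call. = FALSE)
    if (anyNA(group)) stop("missing values in group", call. = FALSE)
    group <- factor(group)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) {
      stop("covariate matrix must have one row per subject", call. = FALSE)
    }
    if (anyNA(covariates)) stop("missing values in covariates", call. = FALSE)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    }
  }
  structure(
    list(time = time, event = event, group = group, covariates = covariates),
    class = "survival_data"
  )
}

#' Build survival data from a scored cohort
#'
#' Convenience bridge from a scored [cohort][read_cohort] (see
#' [score_cohort()]) to [survival_data()]: group is the ONKOTEV stratum and
#' the covariates are the four score components as 0/1 indicators.
#'
#' @param cohort a scored cohort (must carry `onkotev_stratum` and the
#'   component columns appended by [score_cohort()]).
#' @param marker_column column used downstream as ordinal marker (unused here,
#'   kept for provenance).
#' @return A `survival_data` object.
#' @export
as_survival_data <- function(cohort, marker_column = "onkotev_score") {
  rec <- cohort_records(cohort)
  needed <- c("time_months", "event", "onkotev_stratum", "khorana_gt2",
              "metastatic", "vascular_lymphatic_compression", "prior_vte")
  miss <- setdiff(needed, names(rec))
  if (length(miss) > 0L) {
    stop("cohort is not scored; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  covs <- cbind(
    khorana_gt2 = as.numeric(rec$khorana_gt2),
    metastatic = as.numeric(rec$metastatic),
    compression = as.numeric(rec$vascular_lymphatic_compression),
    prior_vte = as.numeric(rec$prior_vte)
  )
  survival_data(rec$time_months, rec$event,
                group = rec$onkotev_stratum, covariates = covs)
}

#' @export
print.survival_data <- function(x, ...) {
  cat("survival_data:", length(x$time), "subjects;",
      sum(x$event == 1L), "cause-1 events,",
      sum(x$event == 2L), "competing events,",
      sum(x$event == 0L), "censored\n")
  if (!is.null(x$group)) {
    cat("groups:", paste(levels(x$group), collapse = ", "), "\n")
  }
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}
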