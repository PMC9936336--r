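#' Cumulative incidence under competing risks
#'
#' Product-limit (Kalbfleisch-Prentice / Aalen-Johansen) estimator of the
#' cumulative incidence function for one cause, treating the other cause as a
#' competing event:
#' \deqn{\hat F_k(t) = \sum_{t_i \le t} \hat S(t_i-) \, d_k(t_i)/n(t_i)}
#' where \eqn{\hat S} is the all-cause Kaplan-Meier survivor. The pointwise
#' variance is the standard counting-process (delta-method) estimator and 95%
#' confidence intervals use the log(-log) complementary transform so that the
#' bounds stay inside \eqn{[0,1]}.
#'
#' Ties are handled with the usual convention: events are processed before
#' censorings at the same time, and tied events of both causes share the same
#' risk set.
#'
#' @param data a [survival_data] object.
#' @param cause which cause to estimate (1 or 2).
#' @param conf_level confidence level for pointwise intervals.
#' @return An object of class `cif_estimate` with elements `cause`, `times`
#'   (sorted distinct event times), `cif`, `variance`, `ci_low`, `ci_high`,
#'   `n`, `n_events`. If `data$group` is set, a named list of `cif_estimate`
#'   objects (class `cif_by_group`), one per non-empty group.
#' @examples
#' d <- survival_data(c(1, 2, 3, 4), c(1, 2, 1, 0))
#' estimate_cif(d, cause = 1)
#' @export
estimate_cif <- function(data, cause = 1, conf_level = 0.95) {
  stopifnot(inherits(data, "survival_data"))
  cause <- as.integer(cause)
  if (!cause %in% c(1L, 2L)) stop("cause must be 1 or 2", call. = FALSE)
  if (!is.null(data$group)) {
    lv <- levels(droplevels(data$group))
    out <- lapply(lv, function(g) {
      sel <- data$group == g
      cif_one(data$time[sel], data$event[sel], cause, conf_level)
    })
    names(out) <- lv
    class(out) <- "cif_by_group"
    return(out)
  }
  cif_one(data$time, data$event, cause, conf_level)
}

cif_one <- function(time, event, cause, conf_level) {
  n <- length(time)
  ut <- sort(unique(time[event != 0L]))
  if (length(ut) == 0L) {
    return(structure(
      list(cause = cause, times = numeric(0), cif = numeric(0),
           variance = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
           n = n, n_events = 0L, conf_level = conf_level),
      class = "cif_estimate"
    ))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d1 <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  d2 <- vapply(ut, function(t) sum(time == t & event == 2L), numeric(1))
  d_all <- d1 + d2
  surv <- cumprod(1 - d_all / n_risk)       # S(t_j), all-cause KM
  surv_prev <- c(1, surv[-length(surv)])    # S(t_j -)
  dk <- if (cause == 1L) d1 else d2
  cif <- cumsum(surv_prev * dk / n_risk)

  # Delta-method variance (Klein & Moeschberger form): Greenwood-type term in
  # the overall survivor, a binomial term in the cause-specific jumps, and
  # their covariance.
  gw <- ifelse(n_risk > d_all, d_all / (n_risk * (n_risk - d_all)), 0)
  a <- cumsum(surv_prev * dk / n_risk)                  # = cif
  variance <- numeric(length(ut))
  for (j in seq_along(ut)) {
    idx <- seq_len(j)
    t1 <- sum((cif[j] - cif[idx])^2 * gw[idx])
    t2 <- sum(surv_prev[idx]^2 * ((n_risk[idx] - dk[idx]) / n_risk[idx]) *
                dk[idx] / n_risk[idx]^2)
    t3 <- sum((cif[j] - cif[idx]) * surv_prev[idx] * dk[idx] / n_risk[idx]^2)
    variance[j] <- t1 + t2 - 2 * t3
  }
  variance <- pmax(variance, 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(variance)
  ci_low <- ci_high <- numeric(length(cif))
  pos <- cif > 0 & cif < 1
  # log(-log) transform keeps bounds in [0,1]
  sig <- se[pos] / (cif[pos] * abs(log(cif[pos])))
  ci_low[pos] <- cif[pos]^exp(z * sig)
  ci_high[pos] <- cif[pos]^exp(-z * sig)
  ci_low[!pos] <- cif[!pos]
  ci_high[!pos] <- cif[!pos]
  structure(
    list(cause = cause, times = ut, cif = cif, variance = variance,
         ci_low = ci_low, ci_high = ci_high, n = n,
         n_events = as.integer(sum(dk)), conf_level = conf_level),
    class = "cif_estimate"
  )
}

#' Evaluate a cumulative incidence curve at a time point
#'
#' Right-continuous step-function lookup of the point estimate and its
#' pointwise confidence bounds. Times before the first event map to
#' `(0, 0, 0)`; times beyond the last event time return the final step.
#'
#' @param est a `cif_estimate` from [estimate_cif()].
#' @param t non-negative time (months).
#' @return Named numeric vector `c(point, ci_low, ci_high)`.
#' @export
cif_at <- function(est, t) {
  stopifnot(inherits(est, "cif_estimate"), t >= 0)
  idx <- findInterval(t, est$times)
  c(point = c(0, est$cif)[idx + 1L],
    ci_low = c(0, est$ci_low)[idx + 1L],
    ci_high = c(0, est$ci_high)[idx + 1L])
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat("Cumulative incidence, cause", x$cause,
      sprintf("(n = %d, %d events)\n", x$n, x$n_events))
  if (length(x$times) == 0L) {
    cat("  no events observed; CIF identically 0\n")
    return(invisible(x))
  }
  df <- data.frame(time = x$times, cif = round(x$cif, 4),
                   ci_low = round(x$ci_low, 4), ci_high = round(x$ci_high, 4))
  if (nrow(df) > 10L) {
    print(utils::head(df, 5L), row.names = FALSE)
    cat("  ...", nrow(df) - 10L, "steps omitted ...\n")
    print(utils::tail(df, 5L), row.names = FALSE)
  } else {
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.cif_by_group <- function(x, ...) {
  for (g in names(x)) {
    cat("== group", g, "==\n")
    print(x[[g]])
  }
  invisible(x)
}

#' Incidence rate per 100 person-months
#'
#' @param n_events number of events observed.
#' @param person_time_months total person-time at risk, in months.
#' @return Events per 100 person-months (numeric, unrounded; reports round to
#'   one decimal).
#' @examples
#' incidence_rate(54, 4865) # ~1.1
#' @export
incidence_rate <- function(n_events, person_time_months) {
  if (person_time_months <= 0) stop("person-time must be positive", call. = FALSE)
  if (n_events < 0) stop("event count must be non-negative", call. = FALSE)
  100 * n_events / person_time_months
}
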