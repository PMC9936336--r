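# Internal product-limit machinery shared by the competing-risks estimators.
# All-cause KM and the censoring-distribution KM are small enough to keep
# self-contained; convention: at tied times events are processed before
# censorings, and IPCW lookups always use the left-continuous G(t-).

# Kaplan-Meier on (time, status); status = 1 marks the "event" whose
# distribution is estimated. Returns jump times and the survivor after each.
km_curve <- function(time, status) {
  stopifnot(length(time) == length(status))
  ord <- order(time)
  time <- time[ord]
  status <- as.integer(status[ord] != 0)
  ut <- unique(time[status == 1L])
  if (length(ut) == 0L) {
    return(list(times = numeric(0), surv = numeric(0)))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & status == 1L), numeric(1))
  list(times = ut, surv = cumprod(1 - d / n_risk))
}

# Evaluate a km_curve at t (right-continuous, S(0)=1).
km_eval <- function(km, t) {
  idx <- findInterval(t, km$times)
  c(1, km$surv)[idx + 1L]
}

# Left-continuous evaluation S(t-): product over jump times strictly < t.
km_eval_left <- function(km, t) {
  idx <- findInterval(t, km$times, left.open = TRUE)
  c(1, km$surv)[idx + 1L]
}

# Censoring-distribution KM: jumps at censoring times (event == 0), risk set
# counts everyone still under observation.
censoring_km <- function(time, event) {
  km_curve(time, event == 0)
}

chk_survival_vectors <- function(time, event) {
  if (length(time) == 0L) stop("empty survival data", call. = FALSE)
  if (length(time) != length(event)) {
    stop("time and event lengths differ", call. = FALSE)
  }
  if (anyNA(time) || anyNA(event)) {
    stop("missing values in time or event", call. = FALSE)
  }
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(event %in% c(0, 1, 2))) {
    stop("event codes must be 0 (censored), 1, or 2", call. = FALSE)
  }
  invisible(TRUE)
}
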