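td_classes <- function(data, horizon, competing) {
  time <- data$time
  event <- data$event
  ckm <- censoring_km(time, event)
  is_case <- event == 1L & time <= horizon
  is_ctrl <- time > horizon
  w_case <- 1 / km_eval_left(ckm, time)
  w_ctrl <- rep(1 / km_eval(ckm, horizon), length(time))
  if (competing == "control") {
    dead <- event == 2L & time <= horizon
    is_ctrl <- is_ctrl | dead
    w_ctrl[dead] <- 1 / km_eval_left(ckm, time)[dead]
  }
  list(case = which(is_case), ctrl = which(is_ctrl),
       w_case = w_case, w_ctrl = w_ctrl)
}

#' Time-dependent AUC for a risk marker under competing risks
#'
#' Cumulative-cases / dynamic-controls AUC at a landmark horizon with
#' inverse-probability-of-censoring weights: cases are cause-1 events in
#' `(0, horizon]` weighted by \eqn{1/\hat G(T_i-)}; controls are subjects
#' event-free beyond the horizon weighted by \eqn{1/\hat G(\tau)}. Subjects
#' whose first event is the competing cause (death) before the horizon are
#' kept as non-cases by default (the definition consistent with a CIF-based
#' cumulative/dynamic AUC); set `competing = "exclude"` to drop them. Marker
#' ties count 1/2. The confidence interval comes from the two-sample
#' Hajek-projection (influence-function) variance of the weighted
#' Mann-Whitney statistic, clipped to \eqn{[0,1]}.
#'
#' @param data a [survival_data].
#' @param marker numeric risk marker, higher = riskier (e.g. the integer
#'   ONKOTEV score).
#' @param horizon landmark time in months (> 0).
#' @param competing `"control"` (default) or `"exclude"`.
#' @param conf_level confidence level.
#' @return Object of class `td_auc`: `horizon`, `auc`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`, `undefined` (TRUE with `reason` when the AUC
#'   cannot be computed).
#' @examples
#' d <- survival_data(c(2, 3, 9, 10), c(1, 1, 0, 0))
#' td_auc(d, marker = c(3, 2, 1, 2), horizon = 6)
#' @export
td_auc <- function(data, marker, horizon, competing = c("control", "exclude"),
                   conf_level = 0.95) {
  stopifnot(inherits(data, "survival_data"), horizon > 0)
  competing <- match.arg(competing)
  if (length(marker) != length(data$time)) {
    stop("marker length must equal the number of subjects", call. = FALSE)
  }
  if (anyNA(marker)) stop("missing marker values", call. = FALSE)
  undef <- function(reason) {
    structure(list(horizon = horizon, auc = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, n_cases = 0L, n_controls = 0L,
                   undefined = TRUE, reason = reason, competing = competing),
              class = "td_auc")
  }
  if (horizon > max(data$time)) {
    return(undef("horizon beyond last observed time"))
  }
  cl <- td_classes(data, horizon, competing)
  if (length(cl$case) == 0L) return(undef("no cases by horizon"))
  if (length(cl$ctrl) == 0L) return(undef("no controls at horizon"))
  mc <- marker[cl$case]
  mk <- marker[cl$ctrl]
  wc <- cl$w_case[cl$case]
  wk <- cl$w_ctrl[cl$ctrl]
  conc <- outer(mc, mk, ">") + 0.5 * outer(mc, mk, "==")
  Wc <- sum(wc)
  Wk <- sum(wk)
  auc <- drop(wc %*% conc %*% wk) / (Wc * Wk)
  # Hajek projection terms
  p_i <- drop(conc %*% wk) / Wk     # per case
  q_j <- drop(wc %*% conc) / Wc     # per control
  v <- sum(wc^2 * (p_i - auc)^2) / Wc^2 + sum(wk^2 * (q_j - auc)^2) / Wk^2
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  structure(
    list(horizon = horizon, auc = auc,
         ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
         n_cases = length(cl$case), n_controls = length(cl$ctrl),
         undefined = FALSE, reason = NULL, competing = competing),
    class = "td_auc"
  )
}

#' Time-dependent ROC curve
#'
#' The stepwise (FPR, TPR) curve underlying [td_auc()]: thresholds sweep the
#' distinct marker values (classification positive when marker >= threshold),
#' with the same IPCW case/control weights. The trapezoidal area over the
#' returned points equals the [td_auc()] point estimate.
#'
#' @inheritParams td_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr` (including the
#'   (0,0) and (1,1) endpoints), or `NULL` (with a warning) when the AUC is
#'   undefined at the horizon.
#' @export
td_roc_curve <- function(data, marker, horizon,
                         competing = c("control", "exclude")) {
  stopifnot(inherits(data, "survival_data"), horizon > 0)
  competing <- match.arg(competing)
  res <- td_auc(data, marker, horizon, competing)
  if (res$undefined) {
    warning("ROC undefined: ", res$reason, call. = FALSE)
    return(NULL)
  }
  cl <- td_classes(data, horizon, competing)
  mc <- marker[cl$case]
  mk <- marker[cl$ctrl]
  wc <- cl$w_case[cl$case]
  wk <- cl$w_ctrl[cl$ctrl]
  thr <- sort(unique(marker), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(wc[mc >= c]) / sum(wc), numeric(1))
  fpr <- vapply(thr, function(c) sum(wk[mk >= c]) / sum(wk), numeric(1))
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (out$fpr[nrow(out)] < 1 || out$tpr[nrow(out)] < 1) {
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  out
}

#' @export
print.td_auc <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("time-dependent AUC at %g months: undefined (%s)\n",
                x$horizon, x$reason))
  } else {
    cat(sprintf(
      "time-dependent AUC at %g months: %.2f (95%% CI %.2f-%.2f); %d cases, %d controls\n",
      x$horizon, x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  }
  invisible(x)
}
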