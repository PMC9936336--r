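#' Control parameters for Fine-Gray fitting
#'
#' @param tol convergence tolerance on the max absolute score component.
#' @param max_iter maximum Newton-Raphson iterations.
#' @param coef_bound absolute coefficient bound beyond which the fit is
#'   flagged as diverged (complete separation guard).
#' @param cens_weights `"pooled"` (default) estimates the censoring
#'   distribution on the pooled sample; `"stratified"` estimates it within
#'   each level of `data$group`.
#' @param conf_level confidence level for hazard-ratio intervals.
#' @return A list of class `fg_control`.
#' @export
fg_control <- function(tol = 1e-9, max_iter = 100L, coef_bound = 15,
                       cens_weights = c("pooled", "stratified"),
                       conf_level = 0.95) {
  structure(
    list(tol = tol, max_iter = as.integer(max_iter), coef_bound = coef_bound,
         cens_weights = match.arg(cens_weights), conf_level = conf_level),
    class = "fg_control"
  )
}

cummat <- function(m) {
  # column-wise cumsum that stays a matrix for a single row
  if (nrow(m) == 1L) return(m)
  apply(m, 2L, cumsum)
}

# Weighted risk-set sums for one censoring-weight stratum.
#
# The Fine-Gray risk set at time t keeps (a) subjects still under observation
# (T_i >= t, weight 1) and (b) subjects who already failed from the competing
# cause (T_i < t), down-weighted by G(t-)/G(T_i-), G being the stratum's
# censoring-distribution Kaplan-Meier. Returns S0, S1 (E x p) and S2
# (E x p*p, row-major) evaluated at each cause-1 event time.
fg_sums_stratum <- function(time, e2, X, eta, Gminus_tk, Gminus_Ti, evt_times) {
  n <- length(time)
  p <- ncol(X)
  E <- length(evt_times)
  w <- exp(eta)
  ord <- order(time)
  t_s <- time[ord]
  w_s <- w[ord]
  X_s <- X[ord, , drop = FALSE]
  xx_cols <- function(Xm, wv) {
    out <- matrix(0, nrow(Xm), p * p)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      out[, (a - 1L) * p + b] <- Xm[, a] * Xm[, b] * wv
    }
    out
  }
  pick <- function(cm, idx) rbind(0, cm)[idx + 1L, , drop = FALSE]
  cum0 <- cumsum(w_s)
  cum1 <- cummat(X_s * w_s)
  cum2 <- cummat(xx_cols(X_s, w_s))
  n_lt <- findInterval(evt_times, t_s, left.open = TRUE)  # #{T_i < t_k}
  A0 <- cum0[n] - c(0, cum0)[n_lt + 1L]
  A1 <- matrix(cum1[n, ], E, p, byrow = TRUE) - pick(cum1, n_lt)
  A2 <- matrix(cum2[n, ], E, p * p, byrow = TRUE) - pick(cum2, n_lt)
  i2 <- which(e2)
  if (length(i2) > 0L) {
    i2 <- i2[order(time[i2])]
    t2 <- time[i2]
    wg <- w[i2] / Gminus_Ti[i2]
    b0 <- cumsum(wg)
    b1 <- cummat(X[i2, , drop = FALSE] * wg)
    b2 <- cummat(xx_cols(X[i2, , drop = FALSE], wg))
    m_lt <- findInterval(evt_times, t2, left.open = TRUE)
    B0 <- c(0, b0)[m_lt + 1L]
    B1 <- pick(b1, m_lt)
    B2 <- pick(b2, m_lt)
  } else {
    B0 <- numeric(E)
    B1 <- matrix(0, E, p)
    B2 <- matrix(0, E, p * p)
  }
  list(S0 = A0 + Gminus_tk * B0,
       S1 = A1 + Gminus_tk * B1,
       S2 = A2 + Gminus_tk * B2)
}

#' Fine-Gray subdistribution-hazard regression
#'
#' Maximizes the Fine-Gray weighted partial likelihood for the cause of
#' interest: subjects who fail from the competing cause remain in the risk
#' set with inverse-probability-of-censoring weights
#' \eqn{\hat G(t-)/\hat G(T_i-)} from the Kaplan-Meier estimate of the
#' censoring distribution (pooled by default, optionally stratified by
#' `data$group`). Newton-Raphson from a zero start, Breslow handling of tied
#' event times, and a robust (sandwich) variance built from per-subject score
#' residuals (censoring weights treated as fixed).
#'
#' @param data a [survival_data] with a covariate matrix.
#' @param cause cause of interest (1 or 2).
#' @param config a [fg_control()] list.
#' @return An object of class `fine_gray_fit`: `coefficients`, `hr`, `se`,
#'   `ci_low`, `ci_high`, `p_values`, `n`, `n_events`, `n_competing`,
#'   `converged`, `n_iterations`, `diverged` (per-coefficient separation
#'   flags), `vcov`.
#' @examples
#' set.seed(1)
#' x <- rbinom(60, 1, 0.5)
#' d <- survival_data(rexp(60) + 0.01, rbinom(60, 1, 0.8),
#'                    covariates = cbind(x = x))
#' fine_gray_fit(d)
#' @export
fine_gray_fit <- function(data, cause = 1, config = fg_control()) {
  stopifnot(inherits(data, "survival_data"))
  if (is.null(data$covariates)) stop("covariates required", call. = FALSE)
  X <- data$covariates
  p <- ncol(X)
  time <- data$time
  e1 <- data$event == as.integer(cause)
  e2 <- data$event != 0L & !e1
  if (sum(e1) == 0L) stop("no events of the target cause", call. = FALSE)
  n <- length(time)

  # censoring-weight strata: one (pooled) or the levels of data$group
  if (config$cens_weights == "stratified" && !is.null(data$group)) {
    strata <- split(seq_len(n), data$group, drop = TRUE)
  } else {
    strata <- list(all = seq_len(n))
  }
  evt_times <- sort(unique(time[e1]))
  E <- length(evt_times)
  str_info <- lapply(strata, function(idx) {
    km <- censoring_km(time[idx], data$event[idx])
    list(idx = idx,
         Gminus_tk = km_eval_left(km, evt_times),
         Gminus_Ti = km_eval_left(km, time[idx]))
  })
  Gminus_Ti <- numeric(n)
  for (s in str_info) Gminus_Ti[s$idx] <- s$Gminus_Ti

  d1 <- vapply(evt_times, function(t) sum(time == t & e1), numeric(1))
  sum_x <- t(vapply(evt_times,
                    function(t) colSums(X[time == t & e1, , drop = FALSE]),
                    numeric(p)))
  if (p == 1L) sum_x <- matrix(sum_x, ncol = 1L)

  risk_sums <- function(eta) {
    S0 <- numeric(E)
    S1 <- matrix(0, E, p)
    S2 <- matrix(0, E, p * p)
    for (s in str_info) {
      idx <- s$idx
      part <- fg_sums_stratum(time[idx], e2[idx], X[idx, , drop = FALSE],
                              eta[idx], s$Gminus_tk, s$Gminus_Ti, evt_times)
      S0 <- S0 + part$S0
      S1 <- S1 + part$S1
      S2 <- S2 + part$S2
    }
    list(S0 = S0, S1 = S1, S2 = S2)
  }

  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  info <- matrix(NA_real_, p, p)
  repeat {
    eta <- drop(X %*% beta)
    rs <- risk_sums(eta)
    xbar <- rs$S1 / rs$S0
    U <- colSums(sum_x - d1 * xbar)
    info <- matrix(0, p, p)
    for (k in seq_len(E)) {
      S2k <- matrix(rs$S2[k, ], p, p)
      info <- info + d1[k] * (S2k / rs$S0[k] - tcrossprod(xbar[k, ]))
    }
    if (max(abs(U)) < config$tol) {
      converged <- TRUE
      break
    }
    if (iter >= config$max_iter) break
    step <- tryCatch(solve(info, U), error = function(e) NULL)
    if (is.null(step)) break  # singular information (e.g. constant covariate)
    beta <- beta + step
    iter <- iter + 1L
    if (any(abs(beta) > config$coef_bound)) break
  }
  diverged <- abs(beta) > config$coef_bound

  # robust sandwich variance from per-subject score residuals:
  # eta_i = 1{cause-1 at t_k}(x_i - xbar_k)
  #         - exp(eta_i) * sum_k w_i(t_k) (x_i - xbar_k) d1_k / S0_k
  eta <- drop(X %*% beta)
  rs <- risk_sums(eta)
  xbar <- rs$S1 / rs$S0
  h0 <- cumsum(d1 / rs$S0)
  h1 <- cummat(d1 * xbar / rs$S0)
  idx_le <- findInterval(time, evt_times)  # #{t_k <= T_i}
  R0 <- c(0, h0)[idx_le + 1L]
  R1 <- rbind(0, h1)[idx_le + 1L, , drop = FALSE]
  for (s in str_info) {
    # competing-cause subjects of this stratum stay at risk after T_i with
    # weight G_g(t_k-)/G_g(T_i-)
    h0g <- cumsum(d1 * s$Gminus_tk / rs$S0)
    h1g <- cummat(d1 * s$Gminus_tk * xbar / rs$S0)
    sub <- s$idx[e2[s$idx]]
    if (length(sub) == 0L) next
    pos <- idx_le[sub]
    add0 <- (h0g[E] - c(0, h0g)[pos + 1L]) / Gminus_Ti[sub]
    add1 <- (matrix(h1g[E, ], length(sub), p, byrow = TRUE) -
               rbind(0, h1g)[pos + 1L, , drop = FALSE]) / Gminus_Ti[sub]
    R0[sub] <- R0[sub] + add0
    R1[sub, ] <- R1[sub, , drop = FALSE] + add1
  }
  eta_res <- -exp(eta) * (X * R0 - R1)
  ki <- match(time, evt_times)
  obs <- e1 & !is.na(ki)
  eta_res[obs, ] <- eta_res[obs, , drop = FALSE] +
    X[obs, , drop = FALSE] - xbar[ki[obs], , drop = FALSE]

  vcov <- tryCatch({
    iinv <- solve(info)
    iinv %*% crossprod(eta_res) %*% iinv
  }, error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- stats::qnorm(1 - (1 - config$conf_level) / 2)
  nm <- colnames(X)
  coef <- stats::setNames(beta, nm)
  structure(
    list(coefficients = coef,
         hr = exp(coef),
         se = stats::setNames(se, nm),
         ci_low = exp(coef - z * se),
         ci_high = exp(coef + z * se),
         p_values = stats::setNames(2 * stats::pnorm(-abs(beta / se)), nm),
         n = n, n_events = as.integer(sum(e1)),
         n_competing = as.integer(sum(e2)),
         converged = converged && !any(diverged),
         n_iterations = iter,
         diverged = stats::setNames(diverged, nm),
         vcov = vcov,
         conf_level = config$conf_level),
    class = "fine_gray_fit"
  )
}

#' @export
print.fine_gray_fit <- function(x, ...) {
  cat(sprintf(
    "Fine-Gray subdistribution-hazard fit (n = %d; %d events, %d competing)\n",
    x$n, x$n_events, x$n_competing))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  df <- data.frame(
    coef = round(x$coefficients, 4),
    HR = round(x$hr, 2),
    ci_low = round(x$ci_low, 2),
    ci_high = round(x$ci_high, 2),
    p = signif(x$p_values, 3)
  )
  print(df)
  invisible(x)
}

#' Serialize a Fine-Gray fit as a report table
#'
#' One row per covariate with the subdistribution hazard ratio, confidence
#' bounds and two-sided p-value, mirroring the usual published layout.
#'
#' @param fit a `fine_gray_fit`.
#' @return A data frame with columns `variable`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
fine_gray_table <- function(fit) {
  stopifnot(inherits(fit, "fine_gray_fit"))
  data.frame(
    variable = names(fit$coefficients),
    hr = unname(fit$hr),
    ci_low = unname(fit$ci_low),
    ci_high = unname(fit$ci_high),
    p = unname(fit$p_values),
    stringsAsFactors = FALSE
  )
}
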