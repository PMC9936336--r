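# Independent oracles, kept deliberately naive and separate from the package
# implementation paths.

# Direct evaluation of the product-limit cumulative incidence: for each
# requested time, loop over every distinct event time before it and
# accumulate S(t-) * d_k(t)/n(t) with S built by explicit products.
oracle_cif <- function(time, event, cause, at) {
  ut <- sort(unique(time[event != 0]))
  vapply(at, function(tt) {
    total <- 0
    for (u in ut[ut <= tt]) {
      s_minus <- 1
      for (v in ut[ut < u]) {
        n_v <- sum(time >= v)
        d_v <- sum(time == v & event != 0)
        s_minus <- s_minus * (1 - d_v / n_v)
      }
      n_u <- sum(time >= u)
      dk_u <- sum(time == u & event == cause)
      total <- total + s_minus * dk_u / n_u
    }
    total
  }, numeric(1))
}

# Brute-force pair-counting AUC on fully observed data (no censoring, no
# competing events): cases have the event by the horizon, controls survive
# beyond it; ties count one half.
oracle_pair_auc <- function(time, event, marker, horizon) {
  cases <- which(event == 1 & time <= horizon)
  ctrls <- which(time > horizon)
  if (length(cases) == 0 || length(ctrls) == 0) return(NA_real_)
  tot <- 0
  for (i in cases) for (j in ctrls) {
    tot <- tot + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  }
  tot / (length(cases) * length(ctrls))
}

# enumerate all event-code assignments for small n
enumerate_events <- function(n) {
  as.matrix(expand.grid(rep(list(0:2), n)))
}
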