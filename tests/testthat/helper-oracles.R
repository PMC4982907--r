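## Independent oracles used across the suite. These deliberately use
## direct/brute-force formulations, not the package's code paths.

## Brute-force SDF: edge-corrected Gaussian kernel sum evaluated with
## dnorm() at every grid point.
sdf_oracle <- function(trains, bw, dt, span) {
  n <- max(2L, as.integer(round((span[2] - span[1]) / dt)) + 1L)
  tt <- span[1] + (seq_len(n) - 1L) * dt
  spikes <- unlist(trains, use.names = FALSE)
  if (!length(spikes)) return(numeric(n))
  w <- 1 / (pnorm((span[2] - spikes) / bw) -
            pnorm((span[1] - spikes) / bw))
  vapply(tt, function(t0) sum(w * dnorm(t0, spikes, bw)), 0) /
    length(trains)
}

## Exhaustive latency scan: first grid time >= onset where the SDF stays
## above threshold for every point of a minDur window.
latency_oracle <- function(times, rates, onset, frac, minDur, dt,
                           baseline = 0) {
  sel <- times >= onset
  t <- times[sel]
  r <- rates[sel]
  pk <- max(r)
  if (pk <= baseline) return(NA_real_)
  thr <- baseline + frac * (pk - baseline)
  need <- max(1L, as.integer(ceiling(minDur / dt)))
  for (i in seq_len(length(r) - need + 1L)) {
    if (all(r[i:(i + need - 1L)] > thr)) return(t[i])
  }
  NA_real_
}

## Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
mw_enum_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  rk <- rank(c(a, b))
  U_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  Us <- apply(idx, 2, function(ii) sum(rk[ii]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

## Hand-computed Pearson chi-square: sum (O - E)^2 / E from the margins.
chi2_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

## A RateFunction built directly from a rate vector (bypasses computeSDF).
rate_fn <- function(rates, dt = 0.001, t0 = 0, bw = 0.025) {
  RateFunction(t0 = t0, dt = dt, rates = rates, bandwidth = bw)
}
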