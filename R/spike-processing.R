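#' Align spike times to stimulus onset
#'
#' Subtracts the epoch's onset time from every spike time; ordering is
#' preserved (a pure shift).
#'
#' @param spikeTimes Sorted spike times (s, relative to trial start).
#' @param epoch One-row data.frame or list with an `onset_s` field.
#' @return Spike times relative to stimulus onset (s).
#' @export
alignToOnset <- function(spikeTimes, epoch) {
  epoch <- as.list(epoch)
  if (is.null(epoch$onset_s) || !is.finite(epoch$onset_s))
    stop("epoch has no valid 'onset_s'")
  if (is.unsorted(spikeTimes))
    stop("spike times must be sorted ascending")
  spikeTimes - epoch$onset_s
}

#' Compute a spike density function (SDF) from one or more trials
#'
#' Gaussian-kernel rate estimate averaged across trials, evaluated on a
#' uniform grid over `span`. Each spike's kernel is edge-corrected
#' (renormalized by the kernel mass inside the span) so that the integral
#' of the SDF equals the mean spike count per trial.
#'
#' @param trains List of numeric spike-time vectors, one per trial
#'   (possibly empty vectors).
#' @param bandwidth Kernel standard deviation (s); default 0.025.
#' @param dt Grid step (s); default 0.001.
#' @param span Time span `c(t0, t1)` of the estimate (s). Defaults to
#'   `c(0, max spike time)` padded by 4 bandwidths.
#' @return A [RateFunction-class].
#' @export
computeSDF <- function(trains, bandwidth = 0.025, dt = 0.001,
                       span = NULL) {
  if (!is.list(trains)) trains <- list(trains)
  if (length(trains) == 0L) stop("need at least one trial")
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  spikes <- unlist(trains, use.names = FALSE)
  if (is.null(span)) {
    hi <- if (length(spikes)) max(spikes) else 1
    span <- c(0, hi + 4 * bandwidth)
  }
  stopifnot(length(span) == 2L, span[2] > span[1])
  n <- max(2L, as.integer(round((span[2] - span[1]) / dt)) + 1L)
  if (length(spikes)) {
    spikes <- spikes[spikes >= span[1] - 8 * bandwidth &
                     spikes <= span[2] + 8 * bandwidth]
  }
  if (length(spikes)) {
    w <- 1 / (stats::pnorm((span[2] - spikes) / bandwidth) -
              stats::pnorm((span[1] - spikes) / bandwidth))
    rates <- sdf_kernel_sum(spikes, w, span[1], dt, n, bandwidth) /
      length(trains)
  } else {
    rates <- numeric(n)
  }
  RateFunction(t0 = span[1], dt = dt, rates = rates,
               bandwidth = bandwidth, nTrials = length(trains))
}

#' Response latency from an SDF
#'
#' Earliest time at or after `onset` at which the SDF exceeds
#' `baseline + frac x (peak - baseline)` continuously for at least
#' `minDur`. The peak is taken within the search window
#' `c(onset, searchEnd)`, not the global trace maximum. With the default
#' `baseline = 0` the threshold is simply `frac` x peak; passing the
#' cell's spontaneous rate makes the threshold a fraction of the response
#' above baseline, which keeps tonically active cells from triggering on
#' their maintained firing.
#'
#' @param sdf A [RateFunction-class].
#' @param onset Stimulus onset (s); search starts here. Default 0.
#' @param frac Threshold fraction of the peak (in (0,1)); default 0.1.
#' @param minDur Minimum supra-threshold duration (s); default 0.050.
#' @param searchEnd End of the search window (s); default end of the SDF.
#' @param baseline Baseline rate subtracted before thresholding (AP/s);
#'   default 0.
#' @return Latency (s) or `NA_real_` when no qualifying crossing exists.
#' @export
detectLatency <- function(sdf, onset = 0, frac = 0.1, minDur = 0.050,
                          searchEnd = NULL, baseline = 0) {
  stopifnot(is(sdf, "RateFunction"), frac > 0, frac < 1, minDur > 0)
  tt <- rateTimes(sdf)
  if (!length(tt)) stop("empty SDF")
  if (is.null(searchEnd)) searchEnd <- tt[length(tt)]
  sel <- tt >= onset & tt <= searchEnd
  if (!any(sel)) stop("search window outside the SDF span")
  r <- sdf@rates[sel]
  t <- tt[sel]
  pk <- max(r)
  if (pk <= baseline || pk <= 0) return(NA_real_)
  above <- r > baseline + frac * (pk - baseline)
  need <- max(1L, as.integer(ceiling(minDur / sdf@dt)))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ok <- which(rl$values & rl$lengths >= need)
  if (!length(ok)) return(NA_real_)
  t[starts[ok[1]]]
}

#' Spontaneous firing rate from baseline windows
#'
#' Total baseline spike count divided by (number of trials x window
#' length).
#'
#' @param trains List of spike-time vectors, one per trial (s, relative
#'   to trial start).
#' @param baselineWindow `c(t0, t1)` preceding stimulus onset (s).
#' @return Rate in AP/s.
#' @export
spontaneousRate <- function(trains, baselineWindow) {
  if (!is.list(trains)) trains <- list(trains)
  stopifnot(length(baselineWindow) == 2L)
  len <- baselineWindow[2] - baselineWindow[1]
  if (len <= 0) stop("baseline window must have positive length")
  counts <- vapply(trains, function(s)
    sum(s >= baselineWindow[1] & s < baselineWindow[2]), 0)
  sum(counts) / (length(trains) * len)
}

#' Peak of an SDF within a window
#'
#' Maximum rate in the window on the raw (baseline-unsubtracted) SDF;
#' ties are broken by the earliest time.
#'
#' @param sdf A [RateFunction-class].
#' @param window `c(t0, t1)` within the SDF span (s).
#' @return Named list: `peak` (AP/s) and `time` (s).
#' @export
peakResponse <- function(sdf, window = NULL) {
  stopifnot(is(sdf, "RateFunction"))
  tt <- rateTimes(sdf)
  if (is.null(window)) window <- range(tt)
  stopifnot(length(window) == 2L)
  tol <- sdf@dt / 2
  if (window[1] < tt[1] - tol || window[2] > tt[length(tt)] + tol)
    stop("window outside the SDF span")
  sel <- which(tt >= window[1] - tol & tt <= window[2] + tol)
  if (!length(sel)) stop("window contains no grid points")
  r <- sdf@rates[sel]
  i <- which.max(r)  # which.max returns the first (earliest) maximum
  list(peak = r[i], time = tt[sel][i])
}
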