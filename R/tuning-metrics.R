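#' Response duration: normalized SDF area in a post-latency window
#'
#' Integral of the SDF over a window starting at the response latency,
#' divided by the peak response within that window and by the window
#' duration. Values near 1 indicate sustained firing at the peak rate for
#' the whole window; values near 0 indicate transient firing.
#'
#' @param sdf A [RateFunction-class].
#' @param latency Response latency (s); `NA` propagates to `NA`.
#' @param window Window length (s); default 0.5.
#' @param peak Peak response used as the normalizer (AP/s). Defaults to
#'   the maximum of the SDF within the window; pass the response-window
#'   peak to normalize by the cell's overall peak response instead.
#' @return Unitless value in \[0, 1\], or `NA_real_`.
#' @export
responseDuration <- function(sdf, latency, window = 0.5, peak = NULL) {
  stopifnot(is(sdf, "RateFunction"), window > 0)
  if (is.na(latency)) return(NA_real_)
  tt <- rateTimes(sdf)
  tol <- sdf@dt / 2
  if (latency < tt[1] - tol || latency + window > tt[length(tt)] + tol)
    stop("SDF does not cover [latency, latency + window]")
  sel <- which(tt >= latency - tol & tt <= latency + window + tol)
  r <- sdf@rates[sel]
  pk <- if (is.null(peak)) max(r) else max(peak, max(r))
  if (pk <= 0) return(NA_real_)
  area <- sum((r[-1] + r[-length(r)]) / 2) * sdf@dt
  min(1, area / (pk * window))
}

#' Normalized vector sum length (NVSL) and preferred direction
#'
#' Direction selectivity as the length of the response-weighted vector sum
#' over the tested directions, normalized by the scalar sum of responses:
#' `nvsl = |sum_j r_j exp(i theta_j)| / sum_j r_j`, in \[0, 1\]. The
#' preferred direction is the angle of the vector sum.
#'
#' @param directions Stimulus directions (deg), at least 2.
#' @param responses Non-negative responses (AP/s), one per direction.
#' @return List: `nvsl` (\[0,1\] or `NA` when all responses are zero) and
#'   `preferred_direction` (deg in \[0, 360), or `NA`).
#' @export
computeNVSL <- function(directions, responses) {
  stopifnot(length(directions) == length(responses),
            length(directions) >= 2)
  if (any(responses < 0)) stop("responses must be non-negative")
  s <- sum(responses)
  if (s == 0)
    return(list(nvsl = NA_real_, preferred_direction = NA_real_))
  th <- directions * pi / 180
  vx <- sum(responses * cos(th))
  vy <- sum(responses * sin(th))
  list(nvsl = sqrt(vx^2 + vy^2) / s,
       preferred_direction = (atan2(vy, vx) * 180 / pi) %% 360)
}

#' Build a tuning curve from per-epoch responses
#'
#' Averages responses sharing the same stimulus value and sorts by x.
#'
#' @param x Stimulus values, one per epoch.
#' @param responses Peak responses (AP/s), one per epoch.
#' @param variable One of `"size"`, `"speed"`, `"direction"`,
#'   `"frequency"`.
#' @param nTrials Trials behind each epoch (recycled).
#' @return A [TuningCurve-class].
#' @export
buildTuningCurve <- function(x, responses, variable, nTrials = 1L) {
  stopifnot(length(x) == length(responses))
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("need at least 2 distinct stimulus values")
  n <- rep_len(as.integer(nTrials), length(x))
  resp <- vapply(ux, function(v) mean(responses[x == v]), 0)
  ntr <- vapply(ux, function(v) sum(n[x == v]), 0L)
  TuningCurve(variable, ux, resp, ntr)
}

#' Stimulus value giving the largest measured response
#'
#' Argmax over the measured points; ties are broken toward the smaller x.
#'
#' @param curve A [TuningCurve-class].
#' @return The x of the maximum response.
#' @export
bestX <- function(curve) {
  stopifnot(is(curve, "TuningCurve"), length(curve@x) > 0)
  curve@x[which.max(curve@response)]
}

#' Tuning width: normalized area (integral / peak) of a tuning curve
#'
#' Trapezoidal integral of the responses over \[min x, max x\] divided by
#' the peak response; a flat curve gives the full x-range, narrower
#' selectivity gives smaller values.
#'
#' @param curve A [TuningCurve-class].
#' @return Width in the units of x, or `NA_real_` for an all-zero curve.
#' @export
tuningWidth <- function(curve) {
  stopifnot(is(curve, "TuningCurve"), length(curve@x) >= 2)
  pk <- max(curve@response)
  if (pk <= 0) return(NA_real_)
  r <- curve@response
  sum(diff(curve@x) * (r[-1] + r[-length(r)]) / 2) / pk
}

#' Gamma-function fit of a size or speed tuning curve
#'
#' Least-squares fit of
#' `R(x) = baseline + amplitude * g(x)/g(mode)`, with
#' `g(x) = (x/scale)^(shape-1) exp(-x/scale)` (see [gammaGain()]), using
#' Levenberg-Marquardt with several starting points. The interpolated
#' best stimulus is the argmax of the fitted curve, `(shape-1)*scale`,
#' clipped to `[min(x)/2, 2*max(x)]`; an argmax at or beyond the largest
#' tested x is flagged `"unbounded_within_range"`.
#'
#' @param curve A [TuningCurve-class] with at least 4 points.
#' @return A [GammaFit-class]; a failed fit has `converged = FALSE` and
#'   `rmse = NA` (never silent).
#' @export
fitGammaTuning <- function(curve) {
  stopifnot(is(curve, "TuningCurve"))
  x <- curve@x
  y <- curve@response
  if (length(x) < 4) stop("need at least 4 points for a gamma fit")
  if (diff(range(y)) <= 1e-9 * max(max(abs(y)), 1)) {
    ## flat curve: the degenerate amplitude-0 limit, solved analytically
    return(new("GammaFit", baseline = mean(y), amplitude = 0,
               shape = NA_real_, scale = NA_real_, bestX = NA_real_,
               rmse = stats::sd(y) * sqrt((length(y) - 1) / length(y)),
               converged = TRUE, note = "flat"))
  }
  b0 <- min(y)
  a0 <- max(y) - b0
  xpk <- x[which.max(y)]
  starts <- list()
  for (k in c(1.5, 2, 3, 5))
    starts[[length(starts) + 1]] <-
      c(b = b0, a = a0, k = k, s = max(xpk, min(x)) / (k - 1))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * ((x / s)^(k - 1) * exp(-x / s)) /
          ((k - 1)^(k - 1) * exp(-(k - 1))),
        start = as.list(st),
        lower = c(b = 0, a = 0, k = 1 + 1e-6, s = min(x) / 100),
        upper = c(b = Inf, a = Inf, k = 50, s = max(x) * 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new("GammaFit", baseline = NA_real_, amplitude = NA_real_,
               shape = NA_real_, scale = NA_real_, bestX = NA_real_,
               rmse = NA_real_, converged = FALSE, note = "no_convergence"))
  cf <- stats::coef(best$fit)
  mode <- (cf[["k"]] - 1) * cf[["s"]]
  lo <- min(x) / 2
  hi <- 2 * max(x)
  note <- ""
  bx <- mode
  if (cf[["a"]] <= 1e-9 * max(max(y), 1)) {
    note <- "flat"
    bx <- NA_real_
  } else if (mode >= max(x)) {
    note <- "unbounded_within_range"
    bx <- min(mode, hi)
  } else if (mode <= lo) {
    note <- "decreasing"
    bx <- lo
  }
  new("GammaFit", baseline = unname(cf[["b"]]),
      amplitude = unname(cf[["a"]]), shape = unname(cf[["k"]]),
      scale = unname(cf[["s"]]), bestX = unname(bx),
      rmse = sqrt(best$rss / length(x)), converged = TRUE, note = note)
}

#' Corner ("cutoff") frequency of a temporal-modulation tuning curve
#'
#' The lowest frequency above the response maximum at which the response
#' crosses half of the maximum, located by linear interpolation on a
#' log2-frequency axis between adjacent tested frequencies. `NA` when the
#' response never falls to half-maximal within the tested range.
#'
#' @param frequencies Tested frequencies (Hz), increasing; at least 2.
#' @param responses Peak firing per frequency (AP/s).
#' @return Cutoff frequency (Hz) or `NA_real_`.
#' @export
cutoffFrequency <- function(frequencies, responses) {
  stopifnot(length(frequencies) == length(responses),
            length(frequencies) >= 2, all(diff(frequencies) > 0))
  if (all(responses <= 0)) return(NA_real_)
  m <- which.max(responses)
  half <- responses[m] / 2
  if (m == length(responses)) return(NA_real_)
  for (i in seq(m, length(responses) - 1L)) {
    r1 <- responses[i]
    r2 <- responses[i + 1L]
    if (r2 <= half && r1 > half) {
      t <- (r1 - half) / (r1 - r2)
      return(2^(log2(frequencies[i]) +
                t * (log2(frequencies[i + 1L]) - log2(frequencies[i]))))
    }
  }
  NA_real_
}

#' Response polarity from baseline-subtracted onset and offset peaks
#'
#' `on_off_index = (on - off) / (on + off)` in \[-1, 1\]; the label is
#' `ON` for indices at or above `onThreshold`, `OFF` at or below
#' `offThreshold`, `ON_OFF` in between. Cells whose larger peak falls
#' below `minResponse` are treated as unresponsive (no label).
#'
#' @param onPeak Baseline-subtracted peak after stimulus onset
#'   (AP/s, non-negative).
#' @param offPeak Baseline-subtracted peak after stimulus offset
#'   (AP/s, non-negative).
#' @param onThreshold,offThreshold Index thresholds (defaults +0.5/-0.5).
#' @param minResponse Responsiveness floor (AP/s, default 0).
#' @return List: `polarity` (`"ON"`, `"OFF"`, `"ON_OFF"` or `NA`) and
#'   `on_off_index` (\[-1, 1\] or `NA`).
#' @export
polarityFromPeaks <- function(onPeak, offPeak, onThreshold = 0.5,
                              offThreshold = -0.5, minResponse = 0) {
  stopifnot(onPeak >= 0, offPeak >= 0)
  if (max(onPeak, offPeak) <= max(0, minResponse))
    return(list(polarity = NA_character_, on_off_index = NA_real_))
  idx <- (onPeak - offPeak) / (onPeak + offPeak)
  lab <- if (idx >= onThreshold) "ON"
         else if (idx <= offThreshold) "OFF"
         else "ON_OFF"
  list(polarity = lab, on_off_index = idx)
}

#' Configuration of the per-cell metrics pipeline
#'
#' All analysis knobs in one place; every metrics table records the
#' bandwidth it was computed with.
#'
#' @param bandwidth SDF kernel bandwidth (s).
#' @param dt SDF grid step (s).
#' @param latencyFrac Latency threshold as a fraction of the peak.
#' @param latencyMinDur Minimum supra-threshold duration (s).
#' @param durationWindow Response-duration window (s).
#' @param offWindow Window after stimulus offset searched for offset
#'   responses (s).
#' @param minResponse Responsiveness floor for polarity calls (AP/s above
#'   baseline).
#' @param polarityNoiseK Number of baseline-SDF standard deviations a
#'   component peak must clear (above the spontaneous rate) to count as
#'   an evoked onset/offset response (default 2).
#' @param directionMode `"count"` (mean spike count per trial during
#'   the bar transit, the default: integrating over the transit is the
#'   statistically efficient direction-response measure) or `"peak"`
#'   (peak of the trial-averaged SDF).
#' @return Named list of settings.
#' @export
metricsConfig <- function(bandwidth = 0.025, dt = 0.001,
                          latencyFrac = 0.1, latencyMinDur = 0.05,
                          durationWindow = 0.5, offWindow = 0.6,
                          minResponse = 5, polarityNoiseK = 2,
                          directionMode = c("count", "peak")) {
  list(bandwidth = bandwidth, dt = dt, latencyFrac = latencyFrac,
       latencyMinDur = latencyMinDur, durationWindow = durationWindow,
       offWindow = offWindow, minResponse = minResponse,
       polarityNoiseK = polarityNoiseK,
       directionMode = match.arg(directionMode))
}

.epoch_trains <- function(spikes, epoch_id, n_trials) {
  s <- spikes[spikes$epoch_id == epoch_id, ]
  lapply(seq_len(n_trials), function(j)
    sort(s$spike_time_s[s$trial_id == j]))
}

.metrics_one_cell <- function(spikes, epochs, n_trials, cfg) {
  bw <- cfg$bandwidth
  sdf_of <- function(ep) {
    trains <- .epoch_trains(spikes, ep$epoch_id, n_trials)
    computeSDF(trains, bandwidth = bw, dt = cfg$dt,
               span = c(0, ep$trial_duration_s))
  }
  peak_of <- function(sdf, ep) {
    off <- ep$onset_s + ep$duration_s
    win_hi <- switch(as.character(ep$protocol),
      contrast_step = , size_series = min(ep$trial_duration_s,
                                          off + cfg$offWindow),
      off)
    peakResponse(sdf, c(ep$onset_s, win_hi))$peak
  }

  size_ep <- epochs[epochs$protocol == "size_series", ]
  step_ep <- epochs[epochs$protocol %in% c("size_series", "contrast_step"), ]

  ## spontaneous rate from pre-onset baselines of all step trials
  base_trains <- unlist(lapply(step_ep$epoch_id, function(id)
    .epoch_trains(spikes, id, n_trials)), recursive = FALSE)
  spont <- spontaneousRate(base_trains, c(0, min(step_ep$onset_s)))

  ## size tuning from the stationary-spot series
  size_sdfs <- lapply(seq_len(nrow(size_ep)),
                      function(i) sdf_of(size_ep[i, ]))
  size_pk <- vapply(seq_len(nrow(size_ep)),
                    function(i) peak_of(size_sdfs[[i]], size_ep[i, ]), 0)
  size_curve <- buildTuningCurve(size_ep$diameter_um, size_pk, "size",
                                 n_trials)
  best_size <- bestX(size_curve)
  size_width <- tuningWidth(size_curve)
  size_fit <- fitGammaTuning(size_curve)
  best_size_fit <- if (size_fit@converged && !is.na(size_fit@bestX))
    size_fit@bestX else best_size

  ## polarity, latency and duration from the best-size step response
  ibest <- which(size_ep$diameter_um == best_size)[1]
  bsdf <- size_sdfs[[ibest]]
  bep <- size_ep[ibest, ]
  off_t <- bep$onset_s + bep$duration_s
  resp_end <- min(bep$trial_duration_s, off_t + cfg$offWindow)
  ## end the onset window a couple of bandwidths before the offset so that
  ## kernel smoothing cannot leak a sharp offset response backwards into
  ## it; the offset window starts at the offset itself (the forward leak
  ## of a stimulus-gated onset response is at most half its end value and
  ## decays within ~2 bandwidths)
  ## onset and offset responses both peak within ~offWindow of their
  ## transition; restricting the search windows accordingly keeps the
  ## maximum-over-window statistic from inflating the silent component in
  ## cells with high maintained rates
  on_hi <- min(bep$onset_s + cfg$offWindow, off_t - 2 * bw)
  ## a component only counts as evoked if its peak clears the baseline
  ## noise floor of the SDF, estimated from the pre-stimulus segment
  tt <- rateTimes(bsdf)
  bsel <- tt >= 3 * bw & tt <= bep$onset_s - 3 * bw
  noise_sd <- if (sum(bsel) > 10) stats::sd(bsdf@rates[bsel]) else 0
  floor_rate <- spont + cfg$polarityNoiseK * noise_sd
  on_pk <- max(0, peakResponse(bsdf, c(bep$onset_s, on_hi))$peak -
                 floor_rate)
  off_pk <- max(0, peakResponse(bsdf, c(off_t, resp_end))$peak -
                  floor_rate)
  pol <- polarityFromPeaks(on_pk, off_pk, minResponse = cfg$minResponse)
  resp_pk <- peakResponse(bsdf, c(bep$onset_s, resp_end))$peak
  ## latency is measured from the driving light transition: stimulus
  ## onset for On and On-Off cells, stimulus offset for Off cells (whose
  ## response follows the decrement in light intensity)
  lat_from <- if (!is.na(pol$polarity) && pol$polarity == "OFF")
    off_t else bep$onset_s
  lat <- detectLatency(bsdf, onset = lat_from, frac = cfg$latencyFrac,
                       minDur = cfg$latencyMinDur, searchEnd = resp_end,
                       baseline = spont)
  dur <- if (!is.na(lat) &&
             lat + cfg$durationWindow <= bep$trial_duration_s)
    responseDuration(bsdf, lat, cfg$durationWindow, peak = resp_pk)
  else NA_real_

  ## direction tuning
  dir_ep <- epochs[epochs$protocol == "direction_series", ]
  nvsl <- list(nvsl = NA_real_, preferred_direction = NA_real_)
  if (nrow(dir_ep) >= 2) {
    dir_resp <- vapply(seq_len(nrow(dir_ep)), function(i) {
      ep <- dir_ep[i, ]
      if (cfg$directionMode == "count") {
        trains <- .epoch_trains(spikes, ep$epoch_id, n_trials)
        mean(vapply(trains, function(s)
          sum(s >= ep$onset_s & s < ep$onset_s + ep$duration_s), 0))
      } else {
        peak_of(sdf_of(ep), ep)
      }
    }, 0)
    nvsl <- computeNVSL(dir_ep$direction_deg, dir_resp)
  }

  ## speed tuning
  sp_ep <- epochs[epochs$protocol == "speed_series", ]
  best_speed <- best_speed_fit <- speed_width <- NA_real_
  if (nrow(sp_ep) >= 2) {
    sp_pk <- vapply(seq_len(nrow(sp_ep)), function(i) {
      ep <- sp_ep[i, ]
      peak_of(sdf_of(ep), ep)
    }, 0)
    sp_curve <- buildTuningCurve(sp_ep$speed_um_s, sp_pk, "speed",
                                 n_trials)
    best_speed <- bestX(sp_curve)
    speed_width <- tuningWidth(sp_curve)
    sp_fit <- fitGammaTuning(sp_curve)
    best_speed_fit <- if (sp_fit@converged && !is.na(sp_fit@bestX))
      sp_fit@bestX else best_speed
  }

  ## temporal-modulation cutoff
  tf_ep <- epochs[epochs$protocol == "temporal_modulation", ]
  cutoff <- NA_real_
  if (nrow(tf_ep) >= 2) {
    tf_pk <- vapply(seq_len(nrow(tf_ep)), function(i) {
      ep <- tf_ep[i, ]
      peak_of(sdf_of(ep), ep)
    }, 0)
    o <- order(tf_ep$frequency_hz)
    cutoff <- cutoffFrequency(tf_ep$frequency_hz[o], tf_pk[o])
  }

  data.frame(
    spontaneous_rate = spont, latency_s = lat, response_duration = dur,
    nvsl = nvsl$nvsl, preferred_direction = nvsl$preferred_direction,
    best_size_um = best_size, best_size_fit_um = best_size_fit,
    size_tuning_width_um = size_width,
    best_speed_um_s = best_speed, best_speed_fit_um_s = best_speed_fit,
    speed_tuning_width_um_s = speed_width,
    cutoff_frequency_hz = cutoff,
    polarity = pol$polarity, on_off_index = pol$on_off_index,
    size_fit_note = size_fit@note, bandwidth_s = cfg$bandwidth)
}

#' Compute the full per-cell metrics table
#'
#' Runs the whole per-cell analysis for every cell of a dataset:
#' spontaneous rate, size tuning (measured and gamma-fit best size,
#' width), best-size step response (latency, response duration, polarity),
#' direction tuning (NVSL, preferred direction), speed tuning, and the
#' temporal-modulation cutoff frequency.
#'
#' @param dataset An [RgcDataset-class], or a spike `data.frame` together
#'   with `epochs`.
#' @param epochs Epoch table (ignored when `dataset` is an `RgcDataset`).
#' @param trialsPerEpoch Number of trials recorded per stimulus condition
#'   (needed because trials without spikes leave no rows in the spike
#'   table); default 5.
#' @param config Settings from [metricsConfig()].
#' @return `data.frame`, one row per cell, carrying `cell_id` (and
#'   `group` when available) plus every metric.
#' @export
computeCellMetrics <- function(dataset, epochs = NULL, trialsPerEpoch = 5,
                               config = metricsConfig()) {
  if (is(dataset, "RgcDataset")) {
    spikes <- spikeTable(dataset)
    epochs <- epochTable(dataset)
    cells <- cellTable(dataset)
  } else {
    spikes <- dataset
    if (is.null(epochs)) stop("'epochs' required with a spike table")
    cells <- data.frame(cell_id = unique(spikes$cell_id))
  }
  spl <- split(spikes, factor(spikes$cell_id, levels = cells$cell_id))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    m <- .metrics_one_cell(spl[[i]], epochs, trialsPerEpoch, config)
    m <- cbind(cell_id = cells$cell_id[i], m)
    if ("group" %in% names(cells)) m$group <- cells$group[i]
    out[[i]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
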