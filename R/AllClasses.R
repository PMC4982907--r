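#' @useDynLib rgclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' RateFunction: a kernel-smoothed firing-rate estimate on a uniform grid
#'
#' Container for a spike density function (SDF): the trial-averaged,
#' Gaussian-kernel-smoothed firing rate of one cell during one stimulus
#' epoch, evaluated on a uniform time grid.
#'
#' @slot t0 Start of the time grid (s, relative to trial start).
#' @slot dt Grid spacing (s).
#' @slot rates Firing rate at each grid point (AP/s), non-negative.
#' @slot bandwidth Gaussian kernel standard deviation (s).
#' @slot nTrials Number of trials averaged.
#'
#' @export
setClass("RateFunction",
  representation(t0 = "numeric", dt = "numeric", rates = "numeric",
                 bandwidth = "numeric", nTrials = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@dt) != 1L || object@dt <= 0)
      msg <- c(msg, "'dt' must be a single positive number")
    if (length(object@t0) != 1L || !is.finite(object@t0))
      msg <- c(msg, "'t0' must be a single finite number")
    if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
      msg <- c(msg, "'bandwidth' must be a single positive number")
    if (any(!is.finite(object@rates)) || any(object@rates < 0))
      msg <- c(msg, "'rates' must be finite and non-negative")
    if (length(object@nTrials) != 1L || object@nTrials < 1L)
      msg <- c(msg, "'nTrials' must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' Construct a RateFunction
#'
#' @param t0 Grid start (s).
#' @param dt Grid spacing (s).
#' @param rates Rates at grid points (AP/s).
#' @param bandwidth Kernel bandwidth (s).
#' @param nTrials Number of trials the estimate averages over.
#' @return A [RateFunction-class] object.
#' @export
RateFunction <- function(t0, dt, rates, bandwidth, nTrials = 1L) {
  new("RateFunction", t0 = as.numeric(t0), dt = as.numeric(dt),
      rates = as.numeric(rates), bandwidth = as.numeric(bandwidth),
      nTrials = as.integer(nTrials))
}

#' @describeIn RateFunction-class Time grid of the estimate (s).
#' @param x A `RateFunction`.
#' @export
rateTimes <- function(x) {
  stopifnot(is(x, "RateFunction"))
  x@t0 + (seq_along(x@rates) - 1L) * x@dt
}

#' @describeIn RateFunction-class Rate values (AP/s).
#' @export
rateValues <- function(x) {
  stopifnot(is(x, "RateFunction"))
  x@rates
}

setMethod("show", "RateFunction", function(object) {
  span <- object@t0 + c(0, (length(object@rates) - 1L) * object@dt)
  cat(sprintf(
    "RateFunction: %d points over [%.3f, %.3f] s (dt = %.4g s)\n",
    length(object@rates), span[1], span[2], object@dt))
  cat(sprintf("  bandwidth %.4g s, %d trial(s), peak %.2f AP/s\n",
              object@bandwidth, object@nTrials,
              if (length(object@rates)) max(object@rates) else NA_real_))
})

#' TuningCurve: trial-averaged response versus a stimulus variable
#'
#' @slot variable Which stimulus variable the curve spans:
#'   `"size"` (um), `"speed"` (um/s), `"direction"` (deg) or
#'   `"frequency"` (Hz).
#' @slot x Stimulus values, strictly increasing (directions unique in
#'   \[0, 360)).
#' @slot response Trial-averaged peak response at each x (AP/s), >= 0.
#' @slot nTrials Trials contributing to each point.
#'
#' @export
setClass("TuningCurve",
  representation(variable = "character", x = "numeric",
                 response = "numeric", nTrials = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@variable %in% c("size", "speed", "direction", "frequency"))
      msg <- c(msg, "unknown tuning variable")
    if (length(object@x) != length(object@response) ||
        length(object@x) != length(object@nTrials))
      msg <- c(msg, "'x', 'response' and 'nTrials' lengths differ")
    if (any(diff(object@x) <= 0))
      msg <- c(msg, "'x' must be strictly increasing")
    if (object@variable == "direction" &&
        (any(object@x < 0) || any(object@x >= 360)))
      msg <- c(msg, "directions must lie in [0, 360)")
    if (any(object@response < 0) || any(!is.finite(object@response)))
      msg <- c(msg, "responses must be finite and non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct a TuningCurve
#'
#' @param variable One of `"size"`, `"speed"`, `"direction"`, `"frequency"`.
#' @param x Stimulus values (strictly increasing).
#' @param response Responses (AP/s).
#' @param nTrials Trials per point (recycled if length 1).
#' @return A [TuningCurve-class] object.
#' @export
TuningCurve <- function(variable, x, response, nTrials = 1L) {
  o <- order(x)
  new("TuningCurve", variable = variable, x = as.numeric(x)[o],
      response = as.numeric(response)[o],
      nTrials = rep_len(as.integer(nTrials), length(x))[o])
}

#' @describeIn TuningCurve-class Stimulus values.
#' @param object A `TuningCurve`.
#' @export
curveX <- function(object) object@x

#' @describeIn TuningCurve-class Response values (AP/s).
#' @export
curveResponse <- function(object) object@response

setMethod("show", "TuningCurve", function(object) {
  cat(sprintf("TuningCurve (%s): %d points\n",
              object@variable, length(object@x)))
  print(data.frame(x = object@x, response = object@response,
                   n_trials = object@nTrials), row.names = FALSE)
})

#' GammaFit: least-squares gamma-function fit of a tuning curve
#'
#' The fitted form is
#' `R(x) = baseline + amplitude * g(x) / g(mode)`, with
#' `g(x) = (x/scale)^(shape-1) * exp(-x/scale)` and
#' `mode = (shape-1)*scale`, so `amplitude` is the fitted peak above
#' baseline.
#'
#' @slot baseline Fitted baseline (AP/s).
#' @slot amplitude Fitted peak above baseline (AP/s).
#' @slot shape Gamma shape (> 1 for a peaked curve).
#' @slot scale Gamma scale (units of x).
#' @slot bestX Argmax of the fitted curve over the evaluation range.
#' @slot rmse Root-mean-square residual (NA when the fit failed).
#' @slot converged Whether the optimizer converged.
#' @slot note `""`, `"unbounded_within_range"` (argmax at or beyond the
#'   upper evaluation limit) or `"decreasing"` (argmax at the lower limit).
#'
#' @export
setClass("GammaFit",
  representation(baseline = "numeric", amplitude = "numeric",
                 shape = "numeric", scale = "numeric", bestX = "numeric",
                 rmse = "numeric", converged = "logical", note = "character"))

setMethod("show", "GammaFit", function(object) {
  cat("GammaFit:",
      if (object@converged) "converged" else "NOT converged", "\n")
  cat(sprintf(
    "  baseline %.3g, amplitude %.3g, shape %.3g, scale %.4g, best x %.4g\n",
    object@baseline, object@amplitude, object@shape, object@scale,
    object@bestX))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Gaussian2DFit: moments-based 2D Gaussian fit to a point cloud
#'
#' @slot center Mean position (x, y, um).
#' @slot sdMajor Square root of the larger covariance eigenvalue (um).
#' @slot sdMinor Square root of the smaller covariance eigenvalue (um).
#' @slot orientation Angle of the major axis, degrees CCW from +x,
#'   in \[0, 180).
#' @slot cov 2x2 sample covariance matrix.
#' @slot nPoints Number of points fitted.
#'
#' @export
setClass("Gaussian2DFit",
  representation(center = "numeric", sdMajor = "numeric",
                 sdMinor = "numeric", orientation = "numeric",
                 cov = "matrix", nPoints = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 2L || any(!is.finite(object@center)))
      msg <- c(msg, "'center' must be two finite coordinates")
    if (!isTRUE(object@sdMajor >= object@sdMinor) || object@sdMinor < 0)
      msg <- c(msg, "need sdMajor >= sdMinor >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Gaussian2DFit", function(object) {
  cat(sprintf(
    "Gaussian2DFit: center (%.1f, %.1f) um, sd %.1f x %.1f um, %d points\n",
    object@center[1], object@center[2], object@sdMajor, object@sdMinor,
    object@nPoints))
})

#' @describeIn Gaussian2DFit-class Fitted center (x, y um).
#' @param object A `Gaussian2DFit`.
#' @export
fitCenter <- function(object) object@center

#' @describeIn Gaussian2DFit-class Fitted standard deviations
#'   `c(major, minor)` (um).
#' @export
fitSD <- function(object) c(major = object@sdMajor, minor = object@sdMinor)

#' LabeledCellMap: a retinal point cloud with per-fluorophore labels
#'
#' Positions are in um relative to the optic nerve head (by convention the
#' origin); each label channel is a logical column `label_<channel>`.
#'
#' @slot retinaId Identifier of the retina.
#' @slot opticNerveHead Position of the optic nerve head (x, y um).
#' @slot cells `data.frame` with columns `x_um`, `y_um` and one or more
#'   logical `label_*` columns.
#'
#' @export
setClass("LabeledCellMap",
  representation(retinaId = "character", opticNerveHead = "numeric",
                 cells = "data.frame"),
  validity = function(object) {
    msg <- character()
    cl <- object@cells
    if (!all(c("x_um", "y_um") %in% names(cl)))
      msg <- c(msg, "cells need 'x_um' and 'y_um' columns")
    else if (nrow(cl) && any(!is.finite(cl$x_um) | !is.finite(cl$y_um)))
      msg <- c(msg, "coordinates must be finite")
    labs <- grep("^label_", names(cl), value = TRUE)
    if (!length(labs))
      msg <- c(msg, "cells need at least one 'label_*' column")
    else if (!all(vapply(cl[labs], is.logical, TRUE)))
      msg <- c(msg, "'label_*' columns must be logical")
    if (length(object@opticNerveHead) != 2L)
      msg <- c(msg, "'opticNerveHead' must be (x, y)")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabeledCellMap
#'
#' @param cells `data.frame` with `x_um`, `y_um` and logical `label_*`
#'   columns.
#' @param retinaId Retina identifier.
#' @param opticNerveHead Optic nerve head position (x, y um); default the
#'   origin.
#' @return A [LabeledCellMap-class] object.
#' @export
LabeledCellMap <- function(cells, retinaId = "retina1",
                           opticNerveHead = c(0, 0)) {
  new("LabeledCellMap", retinaId = as.character(retinaId),
      opticNerveHead = as.numeric(opticNerveHead),
      cells = as.data.frame(cells))
}

#' @describeIn LabeledCellMap-class Label channel names (without the
#'   `label_` prefix).
#' @param object A `LabeledCellMap`.
#' @export
mapChannels <- function(object) {
  sub("^label_", "", grep("^label_", names(object@cells), value = TRUE))
}

#' @describeIn LabeledCellMap-class Positions of the cells carrying one
#'   label, as an n x 2 matrix.
#' @param channel Channel name.
#' @export
channelPoints <- function(object, channel) {
  col <- paste0("label_", channel)
  if (!col %in% names(object@cells))
    stop("unknown channel: ", channel)
  keep <- object@cells[[col]]
  cbind(x = object@cells$x_um[keep], y = object@cells$y_um[keep])
}

setMethod("show", "LabeledCellMap", function(object) {
  cat(sprintf("LabeledCellMap '%s': %d cells\n", object@retinaId,
              nrow(object@cells)))
  for (ch in mapChannels(object))
    cat(sprintf("  %s: %d labeled\n", ch,
                sum(object@cells[[paste0("label_", ch)]])))
})

#' RgcDataset: a simulated or loaded multi-cell recording dataset
#'
#' Bundles the three tables the pipeline works on: per-trial spike times,
#' stimulus epochs, and per-cell metadata (for simulated data this includes
#' the ground-truth class and tuning parameters).
#'
#' @slot spikes `data.frame`: `cell_id`, `trial_id`, `epoch_id`,
#'   `spike_time_s`.
#' @slot epochs `data.frame`: `epoch_id`, `protocol`, `onset_s`,
#'   `duration_s`, `trial_duration_s`, `diameter_um`, `contrast`,
#'   `direction_deg`, `speed_um_s`, `frequency_hz`.
#' @slot cells `data.frame` with one row per cell (`cell_id`, `group`, and,
#'   when simulated, `true_class` plus generator parameters).
#' @slot seed Master seed used for generation (NA when loaded from files).
#'
#' @export
setClass("RgcDataset",
  representation(spikes = "data.frame", epochs = "data.frame",
                 cells = "data.frame", seed = "integer"),
  validity = function(object) {
    msg <- character()
    need_sp <- c("cell_id", "trial_id", "epoch_id", "spike_time_s")
    if (!all(need_sp %in% names(object@spikes)))
      msg <- c(msg, paste("spikes table needs columns:",
                          paste(need_sp, collapse = ", ")))
    need_ep <- c("epoch_id", "protocol", "onset_s", "duration_s",
                 "trial_duration_s")
    if (!all(need_ep %in% names(object@epochs)))
      msg <- c(msg, paste("epoch table needs columns:",
                          paste(need_ep, collapse = ", ")))
    if (!"cell_id" %in% names(object@cells))
      msg <- c(msg, "cells table needs a 'cell_id' column")
    if (length(msg)) msg else TRUE
  })

#' @describeIn RgcDataset-class Spike table accessor.
#' @param object An `RgcDataset`.
#' @export
spikeTable <- function(object) object@spikes

#' @describeIn RgcDataset-class Epoch table accessor.
#' @export
epochTable <- function(object) object@epochs

#' @describeIn RgcDataset-class Per-cell metadata (ground truth when
#'   simulated).
#' @export
cellTable <- function(object) object@cells

setMethod("show", "RgcDataset", function(object) {
  cat(sprintf("RgcDataset: %d cells, %d epochs, %d spikes\n",
              nrow(object@cells), nrow(object@epochs),
              nrow(object@spikes)))
  if ("true_class" %in% names(object@cells)) {
    tab <- table(object@cells$group, object@cells$true_class)
    print(tab)
  }
})
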