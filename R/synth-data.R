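#' Parameters of a generative RGC response model
#'
#' Bundles the tuning parameters of one functional cell type for the
#' synthetic-data generator. The generator uses a separable drive: a
#' polarity kernel (exponential decay with time constant `kinetics_tau`,
#' triggered at stimulus onset and/or offset), multiplied by a von Mises
#' direction gain, a gamma-shaped size gain, a gamma-shaped speed gain, and
#' a first-order low-pass temporal-frequency gain.
#'
#' @param polarity `"ON"`, `"OFF"` or `"ON_OFF"`.
#' @param spontaneous_rate Maintained firing in darkness (AP/s, >= 0).
#' @param peak_gain Peak stimulus-driven rate above baseline (AP/s).
#' @param kinetics_tau Decay time constant of the step response (s); large
#'   values give sustained responses, small values transient ones.
#' @param ds_kappa von Mises concentration of the direction gain (>= 0;
#'   0 means direction-flat).
#' @param preferred_direction Preferred motion direction (deg in \[0, 360)).
#' @param size_shape,size_scale Gamma size-tuning shape (> 1) and scale (um).
#' @param speed_shape,speed_scale Gamma speed-tuning shape (> 1) and scale
#'   (um/s).
#' @param tf_cutoff Low-pass corner of the temporal-modulation gain (Hz).
#' @return A named list of validated parameters (class `"CellTypeParams"`).
#' @export
cellTypeParams <- function(polarity, spontaneous_rate, peak_gain,
                           kinetics_tau, ds_kappa = 0,
                           preferred_direction = 0,
                           size_shape = 2, size_scale = 400,
                           speed_shape = 2, speed_scale = 600,
                           tf_cutoff = 4) {
  polarity <- match.arg(polarity, c("ON", "OFF", "ON_OFF"))
  stopifnot(spontaneous_rate >= 0, peak_gain >= 0, kinetics_tau > 0,
            ds_kappa >= 0,
            preferred_direction >= 0, preferred_direction < 360,
            size_shape > 1, size_scale > 0, speed_shape > 1,
            speed_scale > 0, tf_cutoff > 0)
  structure(list(polarity = polarity,
                 spontaneous_rate = spontaneous_rate,
                 peak_gain = peak_gain, kinetics_tau = kinetics_tau,
                 ds_kappa = ds_kappa,
                 preferred_direction = preferred_direction,
                 size_shape = size_shape, size_scale = size_scale,
                 speed_shape = speed_shape, speed_scale = speed_scale,
                 tf_cutoff = tf_cutoff),
            class = "CellTypeParams")
}

#' von Mises direction gain, normalized to 1 at the preferred direction
#'
#' `exp(kappa * (cos(theta - pref) - 1))`; `kappa = 0` gives a flat gain.
#'
#' @param direction_deg Stimulus direction(s), degrees.
#' @param preferred_deg Preferred direction, degrees.
#' @param kappa Concentration (>= 0).
#' @return Gain in (0, 1].
#' @export
vonMisesGain <- function(direction_deg, preferred_deg, kappa) {
  exp(kappa * (cos((direction_deg - preferred_deg) * pi / 180) - 1))
}

#' Gamma-shaped tuning gain, normalized to 1 at the mode
#'
#' `g(x) = (x/scale)^(shape-1) * exp(-x/scale)` divided by its value at the
#' mode `(shape-1)*scale`. Requires `shape > 1` so the mode is interior.
#'
#' @param x Stimulus value(s) (> 0).
#' @param shape Gamma shape (> 1).
#' @param scale Gamma scale (same units as x).
#' @return Gain in (0, 1].
#' @export
gammaGain <- function(x, shape, scale) {
  stopifnot(shape > 1, scale > 0)
  k <- shape - 1
  peak <- k^k * exp(-k)
  (x / scale)^k * exp(-x / scale) / peak
}

#' First-order low-pass temporal-frequency gain
#'
#' `1 / sqrt(1 + (f/fc)^2)`.
#'
#' @param frequency_hz Modulation frequency (Hz).
#' @param cutoff_hz Corner frequency (Hz).
#' @return Gain in (0, 1].
#' @export
lowpassGain <- function(frequency_hz, cutoff_hz) {
  1 / sqrt(1 + (frequency_hz / cutoff_hz)^2)
}

## Envelope time constant of a moving-bar response: a bar drives the cell
## for as long as it crosses the receptive-field region (~240 um at the
## bar's speed), never less than the cell's own step kinetics.
.transit_tau <- function(params, speed_um_s) {
  if (is.null(speed_um_s) || is.na(speed_um_s))
    return(params$kinetics_tau)
  max(params$kinetics_tau, 240 / speed_um_s)
}

.step_drive <- function(t, onset, offset, polarity, tau) {
  on <- ifelse(t >= onset & t < offset, exp(-(t - onset) / tau), 0)
  off <- ifelse(t >= offset, exp(-(t - offset) / tau), 0)
  switch(polarity, ON = on, OFF = off, ON_OFF = on + off)
}

#' Expected firing rate of a model cell during one stimulus epoch
#'
#' Evaluates the generative rate model on a user-supplied uniform time grid
#' (seconds, relative to trial start). The rate is the spontaneous rate
#' plus a stimulus drive that depends on the epoch's protocol:
#' stationary-spot steps engage the polarity kernel gated by the stimulus
#' window; moving-bar protocols engage a transit-response envelope scaled
#' by the von Mises direction gain (direction series) or the gamma speed
#' gain (speed series; the bar is taken to move in the cell's preferred
#' direction, as in the recording protocol); sinusoidal luminance
#' modulation produces a rectified sinusoid scaled by the low-pass gain
#' (treated as full-field, so no size gain applies).
#'
#' @param params A [cellTypeParams()] object.
#' @param epoch A one-row data.frame (or list) with fields `protocol`,
#'   `onset_s`, `duration_s` and the protocol-specific fields
#'   `diameter_um`, `contrast`, `direction_deg`, `speed_um_s`,
#'   `frequency_hz`.
#' @param grid Uniform, increasing time grid (s) covering the epoch.
#' @return A [RateFunction-class] holding the noise-free rate (bandwidth is
#'   set to the grid spacing as a placeholder; no smoothing is involved).
#' @export
rateTemplate <- function(params, epoch, grid) {
  stopifnot(inherits(params, "CellTypeParams"), length(grid) >= 2)
  dts <- diff(grid)
  if (any(abs(dts - dts[1]) > 1e-9 * dts[1]) || dts[1] <= 0)
    stop("'grid' must be uniform and increasing")
  epoch <- as.list(epoch)
  onset <- epoch$onset_s
  offset <- onset + epoch$duration_s
  if (min(grid) > onset || max(grid) < offset)
    stop("'grid' must cover the stimulus epoch")
  contrast <- if (is.null(epoch$contrast) || is.na(epoch$contrast)) 1
              else epoch$contrast
  A <- params$peak_gain * contrast
  sz_gain <- function() {
    d <- epoch$diameter_um
    if (is.null(d) || is.na(d)) 1
    else gammaGain(d, params$size_shape, params$size_scale)
  }
  drive <- switch(as.character(epoch$protocol),
    contrast_step = ,
    size_series = A * sz_gain() *
      .step_drive(grid, onset, offset, params$polarity,
                  params$kinetics_tau),
    direction_series = A * sz_gain() *
      vonMisesGain(epoch$direction_deg, params$preferred_direction,
                   params$ds_kappa) *
      ifelse(grid >= onset & grid < offset,
             exp(-(grid - onset) /
                   .transit_tau(params, epoch$speed_um_s)), 0),
    speed_series = A * sz_gain() *
      gammaGain(epoch$speed_um_s, params$speed_shape,
                params$speed_scale) *
      ifelse(grid >= onset & grid < offset,
             exp(-(grid - onset) /
                   .transit_tau(params, epoch$speed_um_s)), 0),
    temporal_modulation = {
      f <- epoch$frequency_hz
      s <- sin(2 * pi * f * (grid - onset))
      mod <- switch(params$polarity, ON = pmax(0, s),
                    OFF = pmax(0, -s), ON_OFF = abs(s))
      A * lowpassGain(f, params$tf_cutoff) *
        ifelse(grid >= onset & grid < offset, mod, 0)
    },
    stop("unknown protocol: ", epoch$protocol))
  RateFunction(t0 = grid[1], dt = dts[1],
               rates = params$spontaneous_rate + drive,
               bandwidth = dts[1], nTrials = 1L)
}

.sample_trials <- function(rates, times, dt, n_trials) {
  ## Bernoulli thinning on the discrete grid: at most one spike per bin,
  ## P(spike in bin) = 1 - exp(-rate * dt).
  p <- -expm1(-rates * dt)
  ng <- length(p)
  u <- matrix(stats::runif(ng * n_trials), nrow = ng)
  lapply(seq_len(n_trials), function(j) times[u[, j] < p])
}

#' Sample a spike train from a rate function (inhomogeneous Poisson)
#'
#' Discrete-grid thinning: each grid bin of width `dt` emits at most one
#' spike with probability `1 - exp(-rate * dt)`, so spike times are unique
#' at grid resolution and sorted. Same seed, same output.
#'
#' @param rate A [RateFunction-class] (non-negative by construction).
#' @param seed Optional integer seed set before sampling.
#' @return Numeric vector of spike times (s), strictly inside the grid
#'   span, sorted ascending.
#' @export
sampleSpikes <- function(rate, seed = NULL) {
  stopifnot(is(rate, "RateFunction"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  .sample_trials(rate@rates, rateTimes(rate), rate@dt, 1L)[[1]]
}

#' The standard stimulus battery of the recording protocol
#'
#' One epoch per stimulus condition: contrast steps (including a blank),
#' five spot sizes from 50 to 800 um, eight motion directions at
#' 800 um/s, seven speeds from 50 to 3,200 um/s, and sinusoidal luminance
#' modulation at 1, 2 and 4 Hz.
#'
#' @return `data.frame` with columns `epoch_id`, `protocol`, `onset_s`,
#'   `duration_s`, `trial_duration_s`, `diameter_um`, `contrast`,
#'   `direction_deg`, `speed_um_s`, `frequency_hz`.
#' @export
standardProtocol <- function() {
  row <- function(protocol, onset, dur, trial, diam = NA, contrast = NA,
                  direction = NA, speed = NA, freq = NA)
    data.frame(protocol = protocol, onset_s = onset, duration_s = dur,
               trial_duration_s = trial, diameter_um = diam,
               contrast = contrast, direction_deg = direction,
               speed_um_s = speed, frequency_hz = freq)
  ep <- rbind(
    do.call(rbind, lapply(c(0, 0.5, 0.9), function(ct)
      row("contrast_step", 0.5, 1.0, 2.5, diam = 200, contrast = ct))),
    do.call(rbind, lapply(c(50, 100, 200, 400, 800), function(d)
      row("size_series", 0.5, 1.0, 2.5, diam = d, contrast = 0.9))),
    do.call(rbind, lapply(seq(0, 315, by = 45), function(th)
      row("direction_series", 0.25, 1.5, 2.0, diam = 200, contrast = 0.9,
          direction = th, speed = 800))),
    do.call(rbind, lapply(c(50, 100, 200, 400, 800, 1600, 3200),
      function(v)
        row("speed_series", 0.25, 1.0, 1.75, diam = 200, contrast = 0.9,
            speed = v))),
    do.call(rbind, lapply(c(1, 2, 4), function(f)
      row("temporal_modulation", 0.5, 3.0, 4.0, contrast = 0.9,
          freq = f))))
  ep <- cbind(epoch_id = sprintf("ep%02d", seq_len(nrow(ep))), ep)
  rownames(ep) <- NULL
  ep
}

#' Default generative parameters for the six functional groups
#'
#' Sustained types use a 600-ms kernel, transient types a 50-ms kernel;
#' the small-transient ON type has narrow gamma size tuning (mode 80 um)
#' and a low temporal cutoff; the ON-OFF direction-selective type has
#' `ds_kappa = 2`. Peak gain is 60 AP/s throughout.
#'
#' @return Named list of [cellTypeParams()] objects.
#' @export
defaultCellTypeParams <- function() {
  list(
    ON_OFF_DS = cellTypeParams("ON_OFF", spontaneous_rate = 3,
      peak_gain = 120, kinetics_tau = 0.15, ds_kappa = 4,
      size_shape = 2, size_scale = 300, speed_shape = 2,
      speed_scale = 600, tf_cutoff = 4),
    OFF_SUSTAINED = cellTypeParams("OFF", spontaneous_rate = 8,
      peak_gain = 120, kinetics_tau = 0.6, size_shape = 2,
      size_scale = 400, speed_shape = 2, speed_scale = 400,
      tf_cutoff = 4),
    OFF_TRANSIENT = cellTypeParams("OFF", spontaneous_rate = 6,
      peak_gain = 120, kinetics_tau = 0.05, size_shape = 2,
      size_scale = 400, speed_shape = 2, speed_scale = 400,
      tf_cutoff = 3),
    ON_SUSTAINED = cellTypeParams("ON", spontaneous_rate = 5,
      peak_gain = 120, kinetics_tau = 0.6, size_shape = 2,
      size_scale = 400, speed_shape = 2, speed_scale = 400,
      tf_cutoff = 4),
    ON_TRANSIENT = cellTypeParams("ON", spontaneous_rate = 4,
      peak_gain = 120, kinetics_tau = 0.05, size_shape = 2,
      size_scale = 400, speed_shape = 2, speed_scale = 400,
      tf_cutoff = 4),
    ON_SMALL_TRANSIENT = cellTypeParams("ON", spontaneous_rate = 1,
      peak_gain = 120, kinetics_tau = 0.05, size_shape = 3,
      size_scale = 40, speed_shape = 2, speed_scale = 200,
      tf_cutoff = 1.5))
}

#' Default population composition of the two projection groups
#'
#' Class counts mirror the characterized populations: 10/89
#' dLGN-projecting and 20/103 SC-projecting ON-OFF DS cells, 11 vs 8
#' sustained OFF, 8 vs 15 transient OFF, 45 vs 36 ON cells in total with
#' 1 of 9 small-transient ON cells in the dLGN-projecting group. The
#' sustained/transient split of the remaining ON cells (not itemized in
#' the source counts) is set so sustained ON cells dominate the
#' dLGN-projecting group and transient ON cells the SC-projecting group.
#' Group-specific parameter overrides give transient OFF cells a high
#' maintained rate and high temporal cutoff in the dLGN-projecting group
#' (10.7 AP/s) and a low rate and low cutoff in the SC-projecting group
#' (1.8 AP/s).
#'
#' @return List with elements `composition` (`data.frame`: `group`,
#'   `class`, `n`), `classParams` (see [defaultCellTypeParams()]) and
#'   `overrides` (per-group, per-class parameter replacements).
#' @export
defaultPopulationConfig <- function() {
  comp <- rbind(
    data.frame(group = "dLGN",
               class = c("ON_OFF_DS", "OFF_SUSTAINED", "OFF_TRANSIENT",
                         "ON_SUSTAINED", "ON_TRANSIENT",
                         "ON_SMALL_TRANSIENT"),
               n = c(10, 11, 8, 30, 14, 1)),
    data.frame(group = "SC",
               class = c("ON_OFF_DS", "OFF_SUSTAINED", "OFF_TRANSIENT",
                         "ON_SUSTAINED", "ON_TRANSIENT",
                         "ON_SMALL_TRANSIENT"),
               n = c(20, 8, 15, 12, 16, 8)))
  list(composition = comp,
       classParams = defaultCellTypeParams(),
       overrides = list(
         dLGN = list(OFF_TRANSIENT = list(spontaneous_rate = 10.7,
                                          tf_cutoff = 6)),
         SC = list(OFF_TRANSIENT = list(spontaneous_rate = 1.8,
                                        tf_cutoff = 1.5))))
}

.apply_overrides <- function(params, ov) {
  if (is.null(ov)) return(params)
  for (nm in names(ov)) params[[nm]] <- ov[[nm]]
  do.call(cellTypeParams, params[setdiff(names(params), "class")])
}

#' Simulate a full multi-cell recording experiment with known ground truth
#'
#' Every cell receives the full stimulus battery of [standardProtocol()];
#' spikes are drawn by discrete-grid thinning from the cell's rate
#' templates. All randomness comes from one generator stream seeded once
#' with the master seed, so the dataset is exactly reproducible.
#'
#' @param config Population configuration as returned by
#'   [defaultPopulationConfig()]. `composition` may give per-class counts
#'   (`n`) or fractions (`fraction`, which must sum to 1 within each group
#'   and require `groupSizes`).
#' @param seed Master seed (integer).
#' @param protocol Epoch table; defaults to [standardProtocol()].
#' @param trialsPerEpoch Trials per stimulus condition (default 5).
#' @param dt Simulation grid step (s; default 1 ms).
#' @param groupSizes Named integer vector of group sizes, required when
#'   `composition` uses fractions.
#' @return An [RgcDataset-class] with spikes, epochs and ground truth.
#' @export
simulateExperiment <- function(config = defaultPopulationConfig(),
                               seed = 1, protocol = standardProtocol(),
                               trialsPerEpoch = 5, dt = 0.001,
                               groupSizes = NULL) {
  comp <- config$composition
  if ("fraction" %in% names(comp)) {
    for (g in unique(comp$group)) {
      fr <- comp$fraction[comp$group == g]
      if (abs(sum(fr) - 1) > 1e-8)
        stop("class fractions must sum to 1 within group '", g, "'")
    }
    if (is.null(groupSizes))
      stop("'groupSizes' required when composition gives fractions")
    comp$n <- round(comp$fraction * groupSizes[comp$group])
  }
  stopifnot(all(comp$n >= 0), all(comp$class %in% names(config$classParams)))
  comp <- comp[comp$n > 0, , drop = FALSE]

  cells <- comp[rep(seq_len(nrow(comp)), comp$n), c("group", "class")]
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("c%04d", seq_len(n_cells))
  rownames(cells) <- NULL

  spikes_acc <- vector("list", n_cells)
  truth_acc <- vector("list", n_cells)
  set.seed(as.integer(seed))
  for (i in seq_len(n_cells)) {
    cls <- cells$class[i]
    grp <- cells$group[i]
    params <- config$classParams[[cls]]
    params <- .apply_overrides(unclass(params),
                               config$overrides[[grp]][[cls]])
    params$preferred_direction <- stats::runif(1, 0, 360)
    params <- do.call(cellTypeParams, unclass(params))

    ep_spk <- vector("list", nrow(protocol))
    for (e in seq_len(nrow(protocol))) {
      ep <- protocol[e, ]
      ng <- round(ep$trial_duration_s / dt)
      grid <- (seq_len(ng) - 0.5) * dt
      tmpl <- rateTemplate(params, ep, grid)
      tr <- .sample_trials(tmpl@rates, grid, dt, trialsPerEpoch)
      ns <- lengths(tr)
      if (sum(ns) == 0) next
      ep_spk[[e]] <- data.frame(
        cell_id = cells$cell_id[i],
        trial_id = rep(seq_len(trialsPerEpoch), ns),
        epoch_id = ep$epoch_id,
        spike_time_s = unlist(tr, use.names = FALSE))
    }
    spikes_acc[[i]] <- do.call(rbind, ep_spk[!vapply(ep_spk, is.null, TRUE)])
    truth_acc[[i]] <- data.frame(
      cell_id = cells$cell_id[i], group = grp, true_class = cls,
      polarity = params$polarity,
      spontaneous_rate = params$spontaneous_rate,
      peak_gain = params$peak_gain, kinetics_tau = params$kinetics_tau,
      ds_kappa = params$ds_kappa,
      preferred_direction = params$preferred_direction,
      size_shape = params$size_shape, size_scale = params$size_scale,
      speed_shape = params$speed_shape, speed_scale = params$speed_scale,
      tf_cutoff = params$tf_cutoff)
  }
  spikes <- do.call(rbind, spikes_acc[!vapply(spikes_acc, is.null, TRUE)])
  if (is.null(spikes))
    spikes <- data.frame(cell_id = character(), trial_id = integer(),
                         epoch_id = character(), spike_time_s = numeric())
  rownames(spikes) <- NULL
  new("RgcDataset", spikes = spikes, epochs = protocol,
      cells = do.call(rbind, truth_acc), seed = as.integer(seed))
}

#' Default retina-map parameters for a two-virus labeling experiment
#'
#' Two clusters of retrogradely labeled cells on opposite sides of the
#' optic nerve head (origin), each about 875 um from it so the
#' inter-centroid distance is about 1,750 um, with 150-um isotropic
#' spread -- the geometry of a nasal/temporal dual-injection map.
#'
#' @param angleSeparation Angle (deg) between the two centroid vectors.
#' @param colabelProb Probability that a reference-channel cell also
#'   carries the test label.
#' @return Parameter list for [simulateRetinaMap()].
#' @export
defaultRetinaMapParams <- function(angleSeparation = 164,
                                   colabelProb = 0.8) {
  r <- 875
  a1 <- 10
  a2 <- a1 + angleSeparation
  list(channels = list(
         GFP = list(n = 500,
                    center = r * c(cos(a1 * pi / 180),
                                   sin(a1 * pi / 180)),
                    sd = 150),
         mCherry = list(n = 500,
                        center = r * c(cos(a2 * pi / 180),
                                       sin(a2 * pi / 180)),
                        sd = 150)),
       colabel = list(ref = "GFP", test = "DiD", prob = colabelProb),
       retinaRadius = 2600)
}

#' Simulate a retrogradely labeled retinal cell map
#'
#' Each channel's cells are drawn from an isotropic 2D Gaussian around the
#' channel's cluster center, resampled to stay within the retina radius;
#' reference-channel cells additionally carry the test label with
#' probability `colabel$prob`.
#'
#' @param params List with `channels` (per channel: `n`, `center`, `sd`),
#'   optional `colabel` (`ref`, `test`, `prob`) and `retinaRadius` (um).
#' @param seed Integer seed.
#' @return A [LabeledCellMap-class].
#' @export
simulateRetinaMap <- function(params = defaultRetinaMapParams(),
                              seed = 1) {
  set.seed(as.integer(seed))
  stopifnot(is.list(params$channels), length(params$channels) >= 1)
  if (!is.null(params$colabel))
    stopifnot(params$colabel$prob >= 0, params$colabel$prob <= 1)
  radius <- if (is.null(params$retinaRadius)) Inf else params$retinaRadius
  chans <- names(params$channels)
  all_labels <- unique(c(chans, params$colabel$test))

  draw_cluster <- function(n, center, sd) {
    stopifnot(sd > 0)
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n) {
      m <- cbind(stats::rnorm(n, center[1], sd),
                 stats::rnorm(n, center[2], sd))
      m <- m[sqrt(rowSums(m^2)) <= radius, , drop = FALSE]
      out <- rbind(out, m)
    }
    out[seq_len(n), , drop = FALSE]
  }

  rows <- lapply(chans, function(ch) {
    p <- params$channels[[ch]]
    if (p$n == 0)
      return(NULL)
    xy <- draw_cluster(p$n, p$center, p$sd)
    df <- data.frame(x_um = xy[, 1], y_um = xy[, 2])
    for (lb in all_labels) df[[paste0("label_", lb)]] <- lb == ch
    df
  })
  cells <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(cells)) {
    cells <- data.frame(x_um = numeric(), y_um = numeric())
    for (lb in all_labels) cells[[paste0("label_", lb)]] <- logical()
  }
  cl <- params$colabel
  if (!is.null(cl) && nrow(cells)) {
    ref <- cells[[paste0("label_", cl$ref)]]
    hit <- stats::runif(nrow(cells)) < cl$prob
    col <- paste0("label_", cl$test)
    cells[[col]] <- cells[[col]] | (ref & hit)
  }
  rownames(cells) <- NULL
  LabeledCellMap(cells, retinaId = sprintf("sim_seed%d", as.integer(seed)))
}
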