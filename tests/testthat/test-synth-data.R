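grid_for <- function(trial_s, dt = 0.001) (seq_len(round(trial_s / dt)) - 0.5) * dt

step_epoch <- function(contrast = 0.9, diameter = 200) {
  data.frame(epoch_id = "e1", protocol = "contrast_step", onset_s = 0.5,
             duration_s = 1, trial_duration_s = 2.5,
             diameter_um = diameter, contrast = contrast,
             direction_deg = NA, speed_um_s = NA, frequency_hz = NA)
}

dir_epoch <- function(direction) {
  data.frame(epoch_id = "d1", protocol = "direction_series",
             onset_s = 0.25, duration_s = 1.5, trial_duration_s = 2,
             diameter_um = 200, contrast = 1,
             direction_deg = direction, speed_um_s = 800,
             frequency_hz = NA)
}

test_that("rate templates revert to the spontaneous rate without drive", {
  p <- cellTypeParams("ON", spontaneous_rate = 7, peak_gain = 100,
                      kinetics_tau = 0.1)
  g <- grid_for(2.5)
  blank <- rateTemplate(p, step_epoch(contrast = 0), g)
  expect_equal(rateValues(blank), rep(7, length(g)))
  ## and before onset with a driven stimulus
  driven <- rateTemplate(p, step_epoch(contrast = 1), g)
  expect_equal(rateValues(driven)[g < 0.5], rep(7, sum(g < 0.5)))
  expect_true(all(rateValues(driven) >= 0))
})

test_that("polarity kernels peak after onset, offset, or both", {
  g <- grid_for(2.5)
  peak_t <- function(pol) {
    p <- cellTypeParams(pol, 0, 100, 0.1)
    r <- rateValues(rateTemplate(p, step_epoch(contrast = 1), g))
    g[r > 0.99 * max(r)]
  }
  expect_true(min(peak_t("ON")) >= 0.5 && max(peak_t("ON")) < 0.6)
  expect_true(min(peak_t("OFF")) >= 1.5)
  both <- range(peak_t("ON_OFF"))
  expect_equal(both, c(0.5, 1.5), tolerance = 0.01)
})

test_that("direction gain is flat at kappa 0 and von Mises otherwise", {
  g <- grid_for(2)
  p0 <- cellTypeParams("ON_OFF", 5, 80, 0.15, ds_kappa = 0,
                       preferred_direction = 90)
  expect_equal(rateValues(rateTemplate(p0, dir_epoch(0), g)),
               rateValues(rateTemplate(p0, dir_epoch(180), g)))
  ## kappa = 2: drive ratio preferred vs anti-preferred is e^4
  p2 <- cellTypeParams("ON_OFF", 0, 80, 0.15, ds_kappa = 2,
                       preferred_direction = 90)
  pk <- function(th) max(rateValues(rateTemplate(p2, dir_epoch(th), g)))
  expect_equal(pk(90) / pk(270), exp(4), tolerance = 1e-12)
})

test_that("unknown protocols and non-uniform grids are rejected", {
  p <- cellTypeParams("ON", 5, 60, 0.1)
  bad <- step_epoch()
  bad$protocol <- "flicker_dance"
  expect_error(rateTemplate(p, bad, grid_for(2.5)), "unknown protocol")
  expect_error(rateTemplate(p, step_epoch(), c(0, 0.1, 0.3, 2.5)),
               "uniform")
  expect_error(rateTemplate(p, step_epoch(), c(0.4, 0.6)), "cover")
})

test_that("spike sampling is seed-deterministic, sorted, in-span", {
  p <- cellTypeParams("ON", 20, 100, 0.3)
  rt <- rateTemplate(p, step_epoch(contrast = 1), grid_for(2.5))
  s1 <- sampleSpikes(rt, seed = 42)
  s2 <- sampleSpikes(rt, seed = 42)
  expect_identical(s1, s2)
  expect_false(is.unsorted(s1, strictly = TRUE))
  expect_true(all(s1 > 0 & s1 < 2.5))
  ## zero rate -> empty train
  z <- rate_fn(rep(0, 100))
  expect_length(sampleSpikes(z, seed = 1), 0)
  ## negative rates cannot even be represented
  expect_error(rate_fn(c(1, -1, 1)), "non-negative")
})

test_that("sampled counts match the Poisson mean (Monte Carlo)", {
  r <- 10
  rt <- rate_fn(rep(r, 1000), dt = 0.001)  # constant 10 AP/s for 1 s
  counts <- vapply(1:1000, function(s) length(sampleSpikes(rt, seed = s)), 0)
  expect_lt(abs(mean(counts) - r), 3 * sqrt(r / 1000))
})

test_that("simulateExperiment honors composition, determinism, protocol", {
  cfg <- defaultPopulationConfig()
  cfg$composition <- data.frame(group = "SC", class = "ON_TRANSIENT",
                                n = 10)
  ds <- simulateExperiment(cfg, seed = 3, trialsPerEpoch = 2)
  expect_equal(nrow(cellTable(ds)), 10)
  expect_true(all(cellTable(ds)$true_class == "ON_TRANSIENT"))
  expect_setequal(unique(epochTable(ds)$protocol),
                  c("contrast_step", "size_series", "direction_series",
                    "speed_series", "temporal_modulation"))
  expect_equal(sum(epochTable(ds)$protocol == "size_series"), 5)
  expect_equal(sum(epochTable(ds)$protocol == "direction_series"), 8)
  ds2 <- simulateExperiment(cfg, seed = 3, trialsPerEpoch = 2)
  expect_identical(spikeTable(ds), spikeTable(ds2))
  expect_identical(cellTable(ds), cellTable(ds2))
})

test_that("fractional compositions must sum to 1 per group", {
  cfg <- defaultPopulationConfig()
  cfg$composition <- data.frame(group = "SC",
                                class = c("ON_SUSTAINED", "ON_TRANSIENT"),
                                fraction = c(0.6, 0.3))
  expect_error(simulateExperiment(cfg, seed = 1, groupSizes = c(SC = 10)),
               "sum to 1")
  cfg$composition$fraction <- c(0.6, 0.4)
  ds <- simulateExperiment(cfg, seed = 1, trialsPerEpoch = 1,
                           groupSizes = c(SC = 5))
  expect_equal(nrow(cellTable(ds)), 5)
})

test_that("simulated retina maps have requested counts and geometry", {
  prm <- defaultRetinaMapParams()
  prm$channels$GFP$n <- 500
  prm$channels$GFP$sd <- 150
  map <- simulateRetinaMap(prm, seed = 11)
  pts <- channelPoints(map, "GFP")
  expect_equal(nrow(pts), 500)
  ## CLT bound on the sample mean, per axis
  ctr <- prm$channels$GFP$center
  bound <- 4 * 150 / sqrt(500)
  expect_lt(abs(mean(pts[, 1]) - ctr[1]), bound)
  expect_lt(abs(mean(pts[, 2]) - ctr[2]), bound)
  expect_true(all(sqrt(rowSums(cbind(map@cells$x_um, map@cells$y_um)^2))
                  <= prm$retinaRadius))
})

test_that("co-labeling probabilities of 0, 1 and empty channels work", {
  prm <- defaultRetinaMapParams(colabelProb = 1)
  map1 <- simulateRetinaMap(prm, seed = 5)
  cl <- map1@cells
  expect_true(all(cl$label_DiD[cl$label_GFP]))
  prm$colabel$prob <- 0
  map0 <- simulateRetinaMap(prm, seed = 5)
  expect_false(any(map0@cells$label_DiD))
  prm$channels$mCherry$n <- 0
  mape <- simulateRetinaMap(prm, seed = 5)
  expect_equal(nrow(channelPoints(mape, "mCherry")), 0)
})

test_that("measured NVSL is monotone in the generator's ds_kappa", {
  g <- grid_for(2)
  dirs <- seq(0, 315, by = 45)
  nvsl_for <- function(kappa) {
    p <- cellTypeParams("ON_OFF", 4, 100, 0.15, ds_kappa = kappa,
                        preferred_direction = 45)
    resp <- vapply(dirs, function(th)
      max(rateValues(rateTemplate(p, dir_epoch(th), g))), 0)
    computeNVSL(dirs, resp)$nvsl
  }
  vals <- vapply(c(0, 0.5, 1, 2, 4, 8), nvsl_for, 0)
  expect_true(all(diff(vals) >= -1e-12))
  expect_lt(vals[1], 0.05)
  expect_gt(vals[6], 0.7)
})
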