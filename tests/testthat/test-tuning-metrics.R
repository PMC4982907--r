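test_that("response duration reproduces the analytic cases", {
  dt <- 0.0005
  tt <- seq(0, 0.6, by = dt)
  P <- 40
  ## constant at peak across the window -> 1
  expect_equal(responseDuration(rate_fn(rep(P, length(tt)), dt = dt),
                                latency = 0.05), 1)
  ## at peak for 50 ms then zero -> 0.1
  r <- ifelse(tt < 0.05, P, 0)
  expect_equal(responseDuration(rate_fn(r, dt = dt), latency = 0),
               0.1, tolerance = 0.01)
  ## linear decay from peak to zero across the window -> 0.5
  r2 <- pmax(0, P * (1 - tt / 0.5))
  expect_equal(responseDuration(rate_fn(r2, dt = dt), latency = 0),
               0.5, tolerance = 2e-3)
  ## NA latency propagates; uncovered window errors
  expect_true(is.na(responseDuration(rate_fn(rep(P, 100)), NA_real_)))
  expect_error(responseDuration(rate_fn(rep(P, 100), dt = dt),
                                latency = 0.2), "cover")
})

test_that("NVSL reproduces the analytic direction-tuning cases", {
  dirs <- seq(0, 315, by = 45)
  ## symmetric responses cancel
  expect_equal(computeNVSL(dirs, rep(5, 8))$nvsl, 0, tolerance = 1e-12)
  ## single direction -> perfectly selective
  r1 <- ifelse(dirs == 90, 12, 0)
  res1 <- computeNVSL(dirs, r1)
  expect_equal(res1$nvsl, 1)
  expect_equal(res1$preferred_direction, 90)
  ## cosine tuning 1 + cos(theta): nvsl = 4/8, preferred 0
  rc <- 1 + cos(dirs * pi / 180)
  resc <- computeNVSL(dirs, rc)
  expect_equal(resc$nvsl, 0.5, tolerance = 1e-12)
  expect_equal(resc$preferred_direction %% 360, 0, tolerance = 1e-9)
  ## all-zero responses -> undefined
  expect_true(is.na(computeNVSL(dirs, rep(0, 8))$nvsl))
  expect_error(computeNVSL(dirs, rep(-1, 8)), "non-negative")
})

test_that("NVSL is invariant to positive scaling of all responses", {
  set.seed(12)
  dirs <- seq(0, 315, by = 45)
  for (rep in 1:10) {
    r <- runif(8, 0, 50)
    k <- runif(1, 0.01, 100)
    a <- computeNVSL(dirs, r)
    b <- computeNVSL(dirs, k * r)
    expect_equal(a$nvsl, b$nvsl)
    expect_equal(a$preferred_direction, b$preferred_direction)
  }
})

test_that("tuning curves average duplicates and find the best stimulus", {
  cv <- buildTuningCurve(c(100, 200, 100), c(8, 20, 12), "size")
  expect_equal(curveX(cv), c(100, 200))
  expect_equal(curveResponse(cv), c(10, 20))
  expect_error(buildTuningCurve(c(100, 100), c(1, 2), "size"),
               "distinct")
  expect_equal(bestX(TuningCurve("size", c(100, 200, 400), c(5, 9, 3))),
               200)
  ## flat curve: tie broken toward the smaller x
  expect_equal(bestX(TuningCurve("size", c(50, 100, 200), rep(4, 3))), 50)
  set.seed(3)
  x <- sort(sample(50:800, 6))
  r <- runif(6)
  expect_equal(bestX(TuningCurve("size", x, r)), x[which.max(r)])
})

test_that("tuning width is the normalized area and bounded by the range", {
  ## flat curve over 50-800 um -> full range
  flat <- TuningCurve("size", c(50, 100, 200, 400, 800), rep(30, 5))
  expect_equal(tuningWidth(flat), 750)
  ## triangle peaking mid-range, zero at the ends -> half the range
  tri <- TuningCurve("size", c(0, 400, 800), c(0, 60, 0))
  expect_equal(tuningWidth(tri), 400)
  ## random curves match an independent trapezoid and never exceed range
  set.seed(21)
  for (rep in 1:10) {
    x <- sort(runif(5, 50, 800))
    r <- runif(5, 0, 80)
    cv <- TuningCurve("size", x, r)
    trapz <- sum(diff(x) * (r[-1] + r[-5]) / 2)
    expect_equal(tuningWidth(cv), trapz / max(r), tolerance = 1e-9)
    expect_lte(tuningWidth(cv), diff(range(x)) + 1e-12)
  }
  expect_true(is.na(tuningWidth(TuningCurve("size", c(1, 2), c(0, 0)))))
})

test_that("gamma fits recover noise-free parameters", {
  x <- c(50, 100, 150, 200, 300, 450, 600, 800)
  y <- 5 + 55 * gammaGain(x, shape = 3, scale = 100)
  fit <- fitGammaTuning(TuningCurve("size", x, y))
  expect_true(fit@converged)
  expect_equal(fit@baseline, 5, tolerance = 1e-3)
  expect_equal(fit@amplitude, 55, tolerance = 1e-3)
  ## analytic argmax = (shape-1)*scale = 200, recovered within 1%
  expect_equal(fit@bestX, 200, tolerance = 0.01)
  expect_lt(fit@rmse, 1e-4)
})

test_that("degenerate tuning shapes are flagged, never silent", {
  x <- c(50, 100, 200, 400, 800)
  flat <- fitGammaTuning(TuningCurve("size", x, rep(12, 5)))
  expect_true(flat@converged)
  expect_lt(flat@amplitude, 1e-3)
  expect_equal(flat@baseline, 12, tolerance = 1e-3)
  ## monotonically increasing over the tested range: argmax beyond range
  inc <- 2 + 50 * gammaGain(x, shape = 2, scale = 2000)
  fiti <- fitGammaTuning(TuningCurve("size", x, inc))
  expect_true(fiti@converged)
  expect_identical(fiti@note, "unbounded_within_range")
  expect_gte(fiti@bestX, 800)
  expect_lte(fiti@bestX, 1600)
  expect_error(fitGammaTuning(TuningCurve("size", c(1, 2, 3), 1:3)),
               "4 points")
})

test_that("cutoff frequency interpolates on a log2 axis", {
  expect_equal(cutoffFrequency(c(1, 2, 4), c(100, 100, 50)), 4)
  expect_true(is.na(cutoffFrequency(c(1, 2, 4), c(100, 90, 80))))
  ## crossing between 2 and 4 Hz; compare with a dense-grid oracle
  resp <- c(100, 80, 20)
  got <- cutoffFrequency(c(1, 2, 4), resp)
  lf <- seq(0, 2, length.out = 20001)          # log2(f) in [0, 2]
  rr <- approx(log2(c(1, 2, 4)), resp, xout = lf)$y
  oracle <- 2^lf[which(rr <= 50)[1]]
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_true(is.na(cutoffFrequency(c(1, 2, 4), c(0, 0, 0))))
})

test_that("polarity labels follow the on-off index thresholds", {
  expect_equal(polarityFromPeaks(40, 0),
               list(polarity = "ON", on_off_index = 1))
  p <- polarityFromPeaks(25, 25)
  expect_equal(p$polarity, "ON_OFF")
  expect_equal(p$on_off_index, 0)
  ## boundary index of -0.5 counts as OFF
  pb <- polarityFromPeaks(10, 30)
  expect_equal(pb$on_off_index, -0.5)
  expect_equal(pb$polarity, "OFF")
  expect_true(is.na(polarityFromPeaks(0, 0)$polarity))
  ## responsiveness floor
  expect_true(is.na(polarityFromPeaks(3, 1, minResponse = 5)$polarity))
})

test_that("sustained templates yield longer durations than transient", {
  g <- (seq_len(2500) - 0.5) * 0.001
  ep <- data.frame(protocol = "size_series", onset_s = 0.5,
                   duration_s = 1, trial_duration_s = 2.5,
                   diameter_um = 400, contrast = 1)
  dur_of <- function(tau, bw) {
    p <- cellTypeParams("ON", 0, 100, tau)
    r <- rateValues(rateTemplate(p, ep, g))
    rfn <- RateFunction(0.0005, 0.001, r, bandwidth = bw)
    responseDuration(rfn, latency = 0.5)
  }
  for (bw in c(0.01, 0.025, 0.05)) {
    expect_gt(dur_of(0.4, bw), dur_of(0.08, bw))
    expect_gt(dur_of(0.6, bw), 0.4)
    expect_lt(dur_of(0.05, bw), 0.4)
  }
})
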