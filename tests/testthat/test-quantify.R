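# build a one-frame, one-chamber spectra series directly from an FID
seriesFromFid <- function(fid, acq, time = 0) {
  spec <- fidToSpectrum(fid, acq)
  new("ChamberSpectraSeries",
      spectra = array(spec$magnitude, c(1, 1, length(spec$magnitude))),
      ppm = spec$ppm, frameTimes = time, provenance = list(1L),
      apodizationHz = 0)
}

test_that("peak height matches the analytic on-grid Lorentzian height", {
  acq <- AcquisitionParams()
  np <- spectralPoints(acq)
  dw <- 1 / acq@spectralWidth
  t <- (seq_len(np) - 1) * dw
  # on-grid offset: integer multiple of the spectral resolution
  df <- 10 / acq@acqTime
  shift <- acq@offsetPPM + df / acq@frequencyMHz
  t2star <- 1 / (pi * 53)
  A <- 7
  fid <- A * exp((1i * 2 * pi * df - 1 / t2star) * t)
  q <- exp(-dw / t2star)
  hExpected <- A * (1 - q^np) / (1 - q)  # geometric sum at the peak bin
  cs <- seriesFromFid(fid, acq)
  pk <- peakTable(measurePeaks(cs, SpeciesSet("probe", shift)))
  expect_equal(pk$height, hExpected, tolerance = 0.01)
})

test_that("integrals of two species scale with their amplitudes", {
  lay <- ChamberLayout()
  acq <- AcquisitionParams(nFrames = 1L)
  sp <- SpeciesSet(c("pyruvate", "CO2"), c(176, 125))
  amp <- array(0, c(1, 8, 2), dimnames = list(NULL, NULL, c("pyruvate", "CO2")))
  amp[1, 2, ] <- c(10, 5)  # heights 2:1
  ds <- synthesizeCSI(lay, amp, sp, acq)
  cs <- aggregateChamber(ds, voxelChamberMap(lay, acq))
  pk <- peakTable(measurePeaks(cs, sp))
  r <- pk$integral[pk$species == "pyruvate" & pk$chamber == 2] /
    pk$integral[pk$species == "CO2" & pk$chamber == 2]
  expect_equal(r, 2, tolerance = 0.02)
})

test_that("overlapping or contaminated windows are refused", {
  acq <- AcquisitionParams()
  cs <- seriesFromFid(rep(0 + 0i, spectralPoints(acq)) + 1e-9, acq)
  sp <- SpeciesSet(c("a", "b"), c(181, 184))
  expect_error(
    measurePeaks(cs, sp, windows = list(a = c(179, 182.6),
                                        b = c(182.4, 185.5))),
    "configuration error")
  # touching windows (the defaults split at 182.5) are fine
  expect_silent(measurePeaks(cs, sp))
  expect_error(measurePeaks(cs, SpeciesSet("x", 140)), "noise region")
})

test_that("noise-only detectability matches the Rayleigh-quantile oracle", {
  # oracle: spectrum bins of i.i.d. complex Gaussian noise are independent
  # Rayleigh variates; a species is called detected when the max over its
  # ~5-point window exceeds 5 x the sample sd of the 25-point noise region.
  # Monte-Carlo of that abstract model gives P(no species detected) ~ 0.785
  # (computed with 2e4 replicates; the naive infinite-sample calculation
  # gives 0.89 - the sampling noise of the sd estimate matters).
  acq <- AcquisitionParams()
  sp <- defaultSpeciesSet()
  np <- spectralPoints(acq)
  set.seed(31)
  clear <- replicate(300, {
    fid <- complex(real = rnorm(np), imaginary = rnorm(np))
    pk <- peakTable(measurePeaks(seriesFromFid(fid, acq), sp))
    all(!pk$detectable)
  })
  expect_equal(mean(clear), 0.785, tolerance = 0.08)
})

test_that("mono-exponential fitting recovers exact and noisy series", {
  t <- seq(0, 36, by = 4)
  fit <- fitMonoexponential(t, 10 * exp(-0.33 * t))
  expect_equal(decayRate(fit), 0.33, tolerance = 1e-10)
  expect_equal(timeConstant(fit), 1 / 0.33, tolerance = 1e-10)
  expect_lt(fit@residualNorm, 1e-10)
  expect_equal(decayAmplitude(fit), 10, tolerance = 1e-10)

  expect_warning(fit0 <- fitMonoexponential(t, rep(5, 10)), "constant")
  expect_equal(decayRate(fit0), 0)

  # seeded noisy series, sd = 1% of the initial amplitude, 10 frames:
  # recovery within 3% of truth (frozen: seed 1 gives r = 0.3277)
  set.seed(1)
  y <- abs(10 * exp(-0.33 * t) + rnorm(10, sd = 0.1))
  fitN <- fitMonoexponential(t, y)
  expect_equal(decayRate(fitN), 0.3277, tolerance = 1e-3)
  expect_lt(abs(decayRate(fitN) - 0.33) / 0.33, 0.03)

  expect_error(fitMonoexponential(t[1:3], c(-1, -2, 0.5)), "positive")
})

# hand-built peak series with controlled heights (all marked detectable)
peaksFromHeights <- function(heights, times) {
  # heights: frame x species matrix for one chamber
  rows <- NULL
  for (f in seq_len(nrow(heights))) for (s in colnames(heights))
    rows <- rbind(rows, data.frame(
      frame = f, time = times[f], chamber = 1L, species = s,
      height = heights[f, s], amplitude = heights[f, s],
      integral = heights[f, s], noiseSd = 1,
      snr = 1e6, detectable = TRUE))
  new("PeakSeries", table = rows,
      windows = stats::setNames(rep(list(c(0, 1)), ncol(heights)),
                                colnames(heights)),
      noiseRegion = c(135, 150), snrThreshold = 5)
}

test_that("self-normalization leaves a reference-like species constant", {
  times <- 4 * (0:5)
  decay <- exp(-0.4 * times)
  h <- cbind(pyruvate = 10 * decay,
             twin = 3 * decay,            # same dynamics as the reference
             flatprod = 4 * decay)        # no production after t0, uniform T1
  pk <- peaksFromHeights(h, times)
  conc <- correctConcentration(pk, 1L, "pyruvate", initialConcentration = 17)
  tb <- concentrationTable(conc)
  for (s in colnames(h)) {
    v <- tb$value[tb$species == s]
    expect_equal(v, rep(v[1], length(v)), tolerance = 1e-10)
  }
  # scaled so the species total at the first frame is the initial substrate
  expect_equal(sum(tb$value[tb$frame == 1]), 17, tolerance = 1e-10)
})

test_that("frames with undetectable reference terminate the series", {
  times <- 4 * (0:5)
  decay <- exp(-0.4 * times)
  h <- cbind(pyruvate = 10 * decay, other = 3 * decay)
  pk <- peaksFromHeights(h, times)
  tb <- pk@table
  tb$detectable[tb$species == "pyruvate" & tb$frame >= 5] <- FALSE
  tb$snr[tb$species == "pyruvate" & tb$frame >= 5] <- 1
  pk2 <- new("PeakSeries", table = tb, windows = pk@windows,
             noiseRegion = pk@noiseRegion, snrThreshold = 5)
  conc <- correctConcentration(pk2, 1L, "pyruvate")
  expect_equal(sort(unique(concentrationTable(conc)$frame)), 1:4)
  expect_equal(conc@maskedFrames, 5:6)
})

test_that("mass sensitivity follows the SNR/(m sqrt(t)) definition", {
  expect_equal(massSensitivity(4229, 6e-6, 4), 352.4167, tolerance = 1e-4)
  expect_equal(massSensitivity(1, 1e-6, 1), 1)
  expect_equal(massSensitivity(100, 1e-6, 4), 50)
  # homogeneity: doubling m halves S_m; quadrupling t halves S_m
  expect_equal(massSensitivity(1, 2e-6, 1), massSensitivity(1, 1e-6, 1) / 2)
  expect_equal(massSensitivity(1, 1e-6, 4), massSensitivity(1, 1e-6, 1) / 2)
  expect_error(massSensitivity(1, 0, 1), "positive")
})

test_that("replicate dispersion is the percent coefficient of variation", {
  times <- 0
  h <- cbind(pyruvate = 100)
  pk <- peaksFromHeights(h, times)
  tb <- NULL
  for (ch in 1:3) {
    t1 <- pk@table; t1$chamber <- ch
    t1$height <- c(90, 100, 110)[ch]
    tb <- rbind(tb, t1)
  }
  pk3 <- new("PeakSeries", table = tb, windows = pk@windows,
             noiseRegion = pk@noiseRegion, snrThreshold = 5)
  expect_equal(replicateDispersion(pk3, 1:3, 1), 10)
  # identical replicates -> 0; invariant under common scaling
  tb$height <- 100
  pkEq <- new("PeakSeries", table = tb, windows = pk@windows,
              noiseRegion = pk@noiseRegion, snrThreshold = 5)
  expect_equal(replicateDispersion(pkEq, 1:3, 1), 0)
  tb2 <- tb; tb2$height <- c(90, 100, 110)[tb2$chamber] * 7.5
  pkSc <- new("PeakSeries", table = tb2, windows = pk@windows,
              noiseRegion = pk@noiseRegion, snrThreshold = 5)
  expect_equal(replicateDispersion(pkSc, 1:3, 1), 10)
  expect_error(replicateDispersion(pk3, 1L, 1), "at least 2")
})
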