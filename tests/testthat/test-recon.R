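test_that("a pure tone transforms to a peak at its frequency", {
  acq <- AcquisitionParams()
  np <- spectralPoints(acq)
  t <- (seq_len(np) - 1) / acq@spectralWidth
  fid <- exp((1i * 2 * pi * 100 - 30) * t)  # +100 Hz, decaying
  spec <- fidToSpectrum(fid, acq)
  fpeak <- (spec$ppm[which.max(spec$magnitude)] - acq@offsetPPM) *
    acq@frequencyMHz
  expect_lte(abs(fpeak - 100), acq@spectralWidth / np)
  expect_error(fidToSpectrum(fid[-1], acq), "shape error")
})

test_that("the transform satisfies Parseval's relation", {
  acq <- AcquisitionParams()
  np <- spectralPoints(acq)
  set.seed(3)
  fid <- complex(real = rnorm(np), imaginary = rnorm(np))
  spec <- fidToSpectrum(fid, acq)
  expect_equal(sum(spec$magnitude^2), np * sum(Mod(fid)^2),
               tolerance = 1e-10)
})

test_that("exponential apodization broadens the line by its bandwidth", {
  # linewidths are defined on the phased absorption spectrum, whose FWHM is
  # 1/(pi T2*) + apodization; the magnitude lineshape is sqrt(3) wider
  acq <- AcquisitionParams()
  np <- spectralPoints(acq)
  t <- (seq_len(np) - 1) / acq@spectralWidth
  t2star <- 1 / (pi * 53)
  fid <- exp((1i * 2 * pi * 200 - 1 / t2star) * t)
  for (lb in c(0, 40)) {
    spec <- fidToSpectrum(fid, acq, apodizationHz = lb)
    fw <- hpMRSI:::.peakFWHM(spec$ppm, spec$real) * acq@frequencyMHz
    expect_lte(abs(fw - (53 + lb)), 1 / acq@acqTime)
    fwMag <- hpMRSI:::.peakFWHM(spec$ppm, spec$magnitude) * acq@frequencyMHz
    expect_equal(fwMag, sqrt(3) * (53 + lb), tolerance = 0.07)
  }
})

test_that("aggregation sums complex FIDs coherently", {
  g <- singleSpeciesAmplitudes(rate = 0.3, nFrames = 2L)
  ds <- synthesizeCSI(g$layout, g$amplitudes, g$species, g$acq)
  mp <- voxelChamberMap(g$layout, g$acq)
  vox <- mp[[g$chamber]]
  # the four corner voxels carry identical quarter-signals: chamber FID = 4 s
  rc <- hpMRSI:::voxelRowCol(vox[1], g$acq)
  single <- fidArray(ds)[1, rc[1], rc[2], ]
  cs <- aggregateChamber(ds, mp)
  specSingle <- fidToSpectrum(4 * single, g$acq)$magnitude
  expect_equal(spectraArray(cs)[1, g$chamber, ], specSingle,
               tolerance = 1e-10)
  # permuting voxel order leaves the output bit-identical
  mp2 <- mp; mp2[[g$chamber]] <- rev(mp2[[g$chamber]])
  cs2 <- aggregateChamber(ds, mp2)
  expect_identical(spectraArray(cs2), spectraArray(cs))
  # provenance records exactly the mapped voxels
  expect_identical(provenance(cs)[[g$chamber]], vox)
  expect_error(aggregateChamber(ds, c(mp, list(integer(0)))),
               "aggregation error")
})

test_that("noise sd of a 4-voxel sum doubles relative to one voxel", {
  lay <- ChamberLayout()
  acq <- AcquisitionParams(nFrames = 1L)
  sp <- SpeciesSet("probe", 176)
  amp <- array(0, dim = c(1, 8, 1),
               dimnames = list(NULL, NULL, "probe"))
  ds <- synthesizeCSI(lay, amp, sp, acq, noiseSd = 1, seed = 21L)
  mp <- voxelChamberMap(lay, acq)
  nr <- acq@matrixSize[1]; nc <- acq@matrixSize[2]
  flat <- matrix(0 + 0i, nr * nc, spectralPoints(acq))
  for (row in seq_len(nr))
    flat[(row - 1) * nc + seq_len(nc), ] <- fidArray(ds)[1, row, , ]
  chamberFid <- colSums(flat[mp[[1]], ])
  ratio <- sd(Re(chamberFid)) / sd(Re(flat[mp[[1]][1], ]))
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("chamber-sum SNR is about twice the single-voxel SNR", {
  # noise level chosen so thermal noise dominates the lineshape tails that
  # leak into the noise region (with near-zero noise the SNR of synthetic
  # data is tail-limited and identical for voxel and chamber)
  g <- singleSpeciesPeaks(rate = 0.3, nFrames = 2L, noiseSd = 5,
                          seed = 8L)
  vox <- g$mapping[[g$chamber]][1]
  vs <- voxelSpectraSeries(g$dataset, vox)
  pkVox <- peakTable(measurePeaks(vs, g$species))
  pkCh <- peakTable(g$peaks)
  snrCh <- pkCh$snr[pkCh$chamber == g$chamber & pkCh$frame == 1]
  snrVox <- pkVox$snr[pkVox$frame == 1]
  expect_gt(snrCh, snrVox)            # aggregation before magnitude wins
  expect_equal(snrCh / snrVox, 2, tolerance = 0.35)
})

test_that("end-to-end chamber peak heights track simulated amplitudes", {
  g <- singleSpeciesPeaks(rate = 1 / 3.5, nFrames = 8L)
  tb <- peakTable(g$peaks)
  h <- tb$height[tb$chamber == g$chamber][order(tb$frame[tb$chamber == g$chamber])]
  a <- g$amplitudes[, g$chamber, 1]
  expect_equal(h / h[1], a / a[1], tolerance = 1e-6)
})

test_that("chamber spectra export to tidy CSV", {
  g <- singleSpeciesPeaks(rate = 0.3, nFrames = 2L)
  f <- tempfile(fileext = ".csv")
  writeSpectraCSV(g$spectra, f)
  df <- read.csv(f)
  expect_identical(names(df), c("frame", "time", "chamber", "ppm",
                                "magnitude"))
  expect_equal(nrow(df), 2 * 8 * spectralPoints(g$acq))
})
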