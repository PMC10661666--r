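test_that("dead-volume fit matches the closed form and the printed example", {
  # printed calibration pairs: injected vs mean delivered volume
  pairs <- cbind(c(1000, 1400, 1800, 2200), c(59, 108, 154, 191))
  cal <- fitDeadVolume(pairs)
  expect_equal(deadVolume(cal), 576)
  expect_equal(deadVolume(cal), mean(pairs[, 1] - 8 * pairs[, 2]),
               tolerance = 1e-15)
  expect_equal(cal@slope, 1 / 8)
  expect_lte(rSquared(cal), 1)

  # zero-dead-volume identity
  vt <- c(800, 1600, 2400)
  expect_equal(deadVolume(fitDeadVolume(cbind(vt, vt / 8))), 0)

  # exact synthetic dead volume (closed-form oracle: mean(Vt - 8 Vw) = 300)
  cal300 <- fitDeadVolume(cbind(vt, (vt - 300) / 8))
  expect_equal(deadVolume(cal300), 300, tolerance = 1e-12)
  expect_equal(cal300@residuals, rep(0, 3), tolerance = 1e-12)
})

test_that("dead-volume fit rejects insufficient or invalid input", {
  expect_error(fitDeadVolume(cbind(1000, 59)), "calibration-insufficient")
  expect_error(fitDeadVolume(cbind(c(1000, NA), c(59, 100))), "validation")
  expect_error(fitDeadVolume(cbind(c(1000, -5), c(59, 100))), "validation")
})

test_that("chamber-volume prediction applies the calibrated split", {
  expect_equal(predictChamberVolume(1600, 576), 128)
  expect_equal(predictChamberVolume(1000, 576), 53)
  expect_equal(predictChamberVolume(576, 576), 0)
  expect_warning(v <- predictChamberVolume(100, 576), "dead volume")
  expect_equal(v, 0)

  # prediction composed with fitting reproduces noiseless pairs exactly
  vt <- c(900, 1300, 1700, 2100)
  vw <- (vt - 410) / 8
  cal <- fitDeadVolume(cbind(vt, vw))
  expect_equal(predictChamberVolume(vt, cal), vw, tolerance = 1e-12)
})

test_that("layout invariants are enforced", {
  lay <- ChamberLayout()
  expect_equal(nChambers(lay), 8)
  expect_true(all(chamberRoles(lay) %in% c("reference", "reaction", "control")))
  # overlapping chambers rejected
  expect_error(ChamberLayout(pitch = 5), "overlap")
  # chambers outside the field of view rejected
  expect_error(ChamberLayout(pitch = 16), "field of view")
})

test_that("voxel-chamber map selects 4 disjoint voxels per chamber", {
  lay <- ChamberLayout()
  acq <- AcquisitionParams()
  mp <- voxelChamberMap(lay, acq)
  expect_equal(unname(lengths(mp)), rep(4L, 8))
  all_vox <- unlist(mp)
  expect_equal(length(all_vox), 32L)
  expect_equal(anyDuplicated(all_vox), 0L)

  # every default chamber sits on a 4-voxel corner: equal quarter overlaps
  areas <- hpMRSI:::voxelOverlapAreas(lay, acq)
  for (ch in 1:8) {
    a <- areas[mp[[ch]], ch]
    expect_equal(a, rep(pi * 3^2 / 4, 4), tolerance = 1e-8)
  }
})

test_that("overlap areas agree with a brute-force sub-grid oracle", {
  lay <- ChamberLayout()
  acq <- AcquisitionParams()
  areas <- hpMRSI:::voxelOverlapAreas(lay, acq)
  ex <- hpMRSI:::voxelEdges(acq@fov, acq@matrixSize[2])
  ey <- hpMRSI:::voxelEdges(acq@fov, acq@matrixSize[1])
  ctr <- chamberCenters(lay)
  # check an off-corner chamber too
  shifted <- ChamberLayout(centers = ctr + matrix(c(1.3, -0.7), 8, 2,
                                                  byrow = TRUE))
  areas2 <- hpMRSI:::voxelOverlapAreas(shifted, acq)
  ctr2 <- chamberCenters(shifted)
  for (ch in c(1, 4, 6)) {
    for (row in 1:8) for (col in 1:8) {
      idx <- (row - 1) * 8 + col
      for (case in 1:2) {
        a <- if (case == 1) areas[idx, ch] else areas2[idx, ch]
        cc <- if (case == 1) ctr[ch, ] else ctr2[ch, ]
        if (a < 1e-9) next
        brute <- bruteOverlap(cc[1], cc[2], 3, ex[col], ex[col + 1],
                              ey[row], ey[row + 1])
        expect_equal(a, brute, tolerance = 5e-3)
      }
    }
  }
})

test_that("voxel map is invariant under joint translation of layout and grid", {
  acq <- AcquisitionParams()
  lay <- ChamberLayout()
  d <- c(1.5, -1)
  shifted <- ChamberLayout(centers = sweep(chamberCenters(lay), 2, -d))
  expect_identical(voxelChamberMap(lay, acq),
                   stats::setNames(voxelChamberMap(shifted, acq, origin = d),
                                   names(voxelChamberMap(lay, acq))))
})

test_that("a chamber outside the grid raises a mapping error", {
  acq <- AcquisitionParams()
  lay <- ChamberLayout()
  expect_error(voxelChamberMap(lay, acq, origin = c(10, 0)), "mapping error")
})

test_that("layout and calibration round-trip through their file formats", {
  lay <- ChamberLayout(sampleVolume = c(100, rep(125, 6), 100))
  f <- tempfile(fileext = ".json")
  writeChamberLayout(lay, f)
  lay2 <- readChamberLayout(f)
  expect_equal(chamberCenters(lay2), chamberCenters(lay))
  expect_identical(chamberRoles(lay2), chamberRoles(lay))
  expect_equal(lay2@sampleVolume, lay@sampleVolume)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(total_injected_uL = c(1000, 1400, 1800, 2200),
                       chamber_volume_uL = c(59, 108, 154, 191)),
            csv, row.names = FALSE)
  cal <- fitDeadVolume(readVolumePairs(csv))
  expect_equal(deadVolume(cal), 576)
  jf <- tempfile(fileext = ".json")
  writeVolumeCalibration(cal, jf)
  obj <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(obj$dead_volume_uL, 576)
})
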