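test_that("RF depletion factor is cos^n of the flip angle", {
  expect_equal(rfDepletionFactor(15, 64), cos(15 * pi / 180)^64,
               tolerance = 1e-15)
  expect_equal(rfDepletionFactor(15, 64), 0.1087, tolerance = 1e-3)
  expect_equal(rfDepletionFactor(0, 1000), 1)
  expect_equal(rfDepletionFactor(90, 1), 0)
  expect_error(rfDepletionFactor(120, 1), "flipAngle")
})

test_that("effective flip angle inverts the apparent-rate model", {
  for (r in c(1 / 3.03, 1 / 2.96, 0.5, 0.09)) {
    th <- flipAngleForApparentRate(r, T1 = 60)
    expect_equal(apparentDecayRate(th, T1 = 60), r, tolerance = 1e-12)
  }
  expect_error(flipAngleForApparentRate(0.01, T1 = 60), "exceed")
})

test_that("dissolution dilution reproduces the printed trityl concentration", {
  expect_equal(dissolutionConcentration(15, 24, 4.5), 0.080, tolerance = 1e-12)
  expect_equal(dissolutionConcentration(1.5, 24, 4.5) * 1000, 8,
               tolerance = 1e-12)
  # identity dilution: stock volume equal to dissolution volume
  expect_equal(dissolutionConcentration(7, 4500, 4.5), 7)
  expect_error(dissolutionConcentration(15, -1, 4.5), "positive")
})

test_that("frame-lumped amplitudes of a non-relaxing species form a geometric series", {
  g <- singleSpeciesAmplitudes(rate = apparentDecayRate(15, T1 = Inf),
                               T1 = 1e9, nFrames = 8L)
  a <- g$amplitudes[, g$chamber, 1]
  ratios <- a[-1] / a[-length(a)]
  expect_equal(ratios, rep(cos(15 * pi / 180)^64, 7), tolerance = 1e-6)
})

test_that("per-pulse amplitudes match the continuous-depletion rate formula", {
  acq <- AcquisitionParams(nFrames = 8L)  # nominal 15 degrees
  sp <- SpeciesSet("probe", 176, T1 = 60)
  net <- ReactionNetwork("probe", data.frame(source = character(0),
                                             target = character(0),
                                             rate = numeric(0),
                                             oxidant = logical(0)))
  init <- matrix(0, 8, 1, dimnames = list(NULL, "probe")); init[2, 1] <- 80
  tr <- simulateKinetics(net, init, seq(0, 75, 0.5), oxidant = FALSE)
  amp <- simulateHpSignal(tr, sp, acq, mode = "per-pulse")
  t <- attr(amp, "frameTimes")
  fitRate <- -coef(lm(log(amp[, 2, 1]) ~ t))[[2]]
  train <- acq@nPulses * acq@repetitionTime
  expected <- acq@nPulses * (-log(cos(15 * pi / 180))) / train + 1 / 60
  expect_equal(fitRate, expected, tolerance = 0.02)
})

test_that("zero initial polarization gives zero signal everywhere", {
  g <- singleSpeciesAmplitudes(rate = 0.3, nFrames = 4L)
  amp0 <- simulateHpSignal(g$trajectory, g$species, g$acq,
                           initialPolarization = 0)
  expect_true(all(amp0 == 0))
})

test_that("per-pulse and frame-lumped modes agree for slow kinetics", {
  net <- ReactionNetwork(c("A", "B"),
                         data.frame(source = "A", target = "B", rate = 0.005))
  sp <- SpeciesSet(c("A", "B"), c(176, 125), T1 = 60)
  acq <- AcquisitionParams(nFrames = 8L)
  init <- matrix(0, 8, 2, dimnames = list(NULL, c("A", "B")))
  init[2, "A"] <- 80
  tr <- simulateKinetics(net, init, seq(0, 75, 0.5), oxidant = TRUE)
  lump <- simulateHpSignal(tr, sp, acq, mode = "frame-lumped")
  pulse <- simulateHpSignal(tr, sp, acq, mode = "per-pulse")
  a <- lump[, 2, "A"]; b <- pulse[, 2, "A"]
  expect_true(all(abs(a - b) / pmax(a, b) < 0.05))
})

test_that("polarization-weighted label never increases across frames", {
  # property over several random non-negative rate sets, fixed seed
  set.seed(11)
  for (rep in 1:5) {
    k <- runif(5, 0, 0.4)
    net <- defaultReactionNetwork(k[1], k[2], k[3], k[4], k[5])
    sp <- defaultSpeciesSet()
    acq <- AcquisitionParams(nFrames = 6L,
                             flipAngle = runif(1, 1, 30))
    init <- matrix(0, 8, 5,
                   dimnames = list(NULL, speciesNames(sp)))
    init[, "pyruvate"] <- 80
    tr <- simulateKinetics(net, init, seq(0, 75, 0.5),
                           oxidant = rep(c(TRUE, FALSE), 4))
    amp <- simulateHpSignal(tr, sp, acq)
    for (ch in 1:8) {
      tot <- rowSums(amp[, ch, ])
      expect_true(all(diff(tot) <= 1e-9 * tot[1]))
    }
  }
})

test_that("frame schedule outside the trajectory span is refused", {
  g <- singleSpeciesAmplitudes(rate = 0.3, nFrames = 4L)
  shortTr <- simulateKinetics(g$network, g$trajectory@initial, seq(0, 10, 1),
                              oxidant = FALSE)
  expect_error(simulateHpSignal(shortTr, g$species, g$acq), "coverage error")
})
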