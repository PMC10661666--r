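# shared builders for the test suite; everything is generated in code

# a single non-reacting species at `shift` ppm whose hyperpolarized signal
# decays with the requested apparent mono-exponential rate, pushed through
# the real forward model (kinetics -> spin physics)
singleSpeciesAmplitudes <- function(rate, shift = 176, nFrames = 10L,
                                    T1 = 60, chamber = 2L, conc = 80,
                                    mode = "frame-lumped") {
  acq <- AcquisitionParams(
    nFrames = as.integer(nFrames),
    flipAngle = flipAngleForApparentRate(rate, T1 = T1))
  sp <- SpeciesSet("probe", shift, T1 = T1)
  net <- ReactionNetwork("probe",
                         data.frame(source = character(0),
                                    target = character(0),
                                    rate = numeric(0), oxidant = logical(0)))
  initial <- matrix(0, 8, 1, dimnames = list(NULL, "probe"))
  initial[chamber, 1] <- conc
  tr <- simulateKinetics(net, initial, seq(0, 75, by = 0.5), oxidant = FALSE)
  amp <- simulateHpSignal(tr, sp, acq, mode = mode)
  list(acq = acq, species = sp, network = net, trajectory = tr,
       amplitudes = amp, layout = ChamberLayout(), chamber = chamber)
}

# full synthesize -> reconstruct -> measure chain for the single-species probe
singleSpeciesPeaks <- function(rate, shift = 176, nFrames = 10L,
                               noiseSd = 0, seed = NULL, ...) {
  g <- singleSpeciesAmplitudes(rate, shift = shift, nFrames = nFrames, ...)
  ds <- synthesizeCSI(g$layout, g$amplitudes, g$species, g$acq,
                      noiseSd = noiseSd, seed = seed)
  mp <- voxelChamberMap(g$layout, g$acq)
  cs <- aggregateChamber(ds, mp)
  pk <- measurePeaks(cs, g$species)
  c(g, list(dataset = ds, mapping = mp, spectra = cs, peaks = pk))
}

# brute-force circle/square overlap area on a fine sub-grid (midpoint rule);
# independent of the package's quadrature
bruteOverlap <- function(cx, cy, r, x1, x2, y1, y2, n = 500L) {
  xs <- x1 + (seq_len(n) - 0.5) * (x2 - x1) / n
  ys <- y1 + (seq_len(n) - 0.5) * (y2 - y1) / n
  inside <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
  sum(inside) * (x2 - x1) * (y2 - y1) / n^2
}

# two-compartment Bateman closed form for the chain A -(k1)-> B -(k2)-> C
batemanChain <- function(t, a0, k1, k2) {
  a <- a0 * exp(-k1 * t)
  b <- a0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  c <- a0 - a - b
  cbind(A = a, B = b, C = c)
}
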