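#' Synthetic chemical-shift-imaging dataset
#'
#' Complex free-induction decays indexed (frame, voxel row, voxel col,
#' spectral point), with the acquisition metadata, the noise level and the
#' RNG seed that produced them. Identical inputs and seed give a
#' bit-identical dataset.
#'
#' @slot fid complex array, frame x row x col x point.
#' @slot acq the \linkS4class{AcquisitionParams} used.
#' @slot noiseSd numeric, standard deviation of the additive complex white
#'   noise (per real/imaginary component, per point).
#' @slot seed integer seed used for the noise (NA when noiseSd = 0).
#' @export
setClass("CSIDataset",
  representation(fid = "array", acq = "AcquisitionParams",
                 noiseSd = "numeric", seed = "integer"))

setValidity("CSIDataset", function(object) {
  d <- dim(object@fid)
  msg <- character()
  if (length(d) != 4L) return("fid must be a 4-d array")
  if (d[1] != object@acq@nFrames ||
      d[2] != object@acq@matrixSize[1] || d[3] != object@acq@matrixSize[2] ||
      d[4] != spectralPoints(object@acq))
    msg <- c(msg, "fid shape inconsistent with acquisition parameters")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@noiseSd > 0 && is.na(object@seed))
    msg <- c(msg, "seed required when noiseSd > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn CSIDataset the complex FID array.
#' @param x a \code{CSIDataset}.
#' @export
setMethod("fidArray", "CSIDataset", function(x) x@fid)

setMethod("show", "CSIDataset", function(object) {
  d <- dim(object@fid)
  cat(sprintf("CSIDataset: %d frames x %d x %d voxels x %d points\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  noise sd %g, seed %s\n", object@noiseSd,
              ifelse(is.na(object@seed), "none", object@seed)))
})

# Complex basis FID of each species: nSpecies x nPoints,
# exp(i 2 pi df t - t/T2*) with T2* = 1/(pi FWHM).
.speciesBasis <- function(spdf, acq) {
  np <- spectralPoints(acq)
  dw <- 1 / acq@spectralWidth
  t <- (seq_len(np) - 1L) * dw
  df <- (spdf$shift - acq@offsetPPM) * acq@frequencyMHz  # Hz
  if (any(abs(df) >= acq@spectralWidth / 2))
    stop("aliasing error: species resonance outside the spectral width")
  t2star <- 1 / (pi * spdf$linewidth)
  B <- matrix(0 + 0i, nrow = nrow(spdf), ncol = np)
  for (s in seq_len(nrow(spdf)))
    B[s, ] <- exp((1i * 2 * pi * df[s] - 1 / t2star[s]) * t)
  B
}

#' Synthesize a CSI dataset from chamber signal amplitudes
#'
#' Renders per-frame, per-chamber, per-species signal amplitudes into
#' per-voxel complex FIDs. Each voxel receives every chamber's signal
#' weighted by the fraction of that chamber's circular cross-section lying
#' inside the voxel (so the voxel-summed signal of a chamber recovers its
#' full amplitude), and each species contributes a decaying complex
#' exponential at its chemical-shift offset with T2* = 1/(pi FWHM).
#' Optionally, i.i.d. complex Gaussian noise (sd per component
#' \code{noiseSd}) is added to every point.
#'
#' Data are synthesized voxel-wise — at the post-reconstruction level at
#' which the experiment is analysed; k-space encoding and its artifacts are
#' deliberately out of scope.
#'
#' @param layout a \linkS4class{ChamberLayout}.
#' @param amplitudes frame x chamber x species array (as returned by
#'   \code{\link{simulateHpSignal}}).
#' @param species a \linkS4class{SpeciesSet}; rows must match the species
#'   dimension of \code{amplitudes} (by name when dimnames are present).
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param noiseSd standard deviation of the complex noise per component;
#'   0 for noiseless.
#' @param seed integer RNG seed; mandatory when \code{noiseSd > 0}.
#' @return a \linkS4class{CSIDataset}.
#' @export
synthesizeCSI <- function(layout, amplitudes, species, acq, noiseSd = 0,
                          seed = NULL) {
  if (!all(is.finite(amplitudes)))
    stop("validation error: amplitudes must be finite")
  if (noiseSd > 0 && is.null(seed))
    stop("seed required when noiseSd > 0")
  spdf <- speciesTable(species)
  dn <- dimnames(amplitudes)[[3]]
  if (!is.null(dn)) {
    if (!setequal(dn, spdf$name))
      stop("amplitude species do not match the species set")
    spdf <- spdf[match(dn, spdf$name), ]
  } else if (dim(amplitudes)[3] != nrow(spdf))
    stop("species dimension mismatch")

  nf <- dim(amplitudes)[1]
  if (nf != acq@nFrames) stop("frame dimension mismatch with acq")
  nr <- acq@matrixSize[1]; nc <- acq@matrixSize[2]
  np <- spectralPoints(acq)

  W <- voxelOverlapAreas(layout, acq) / (pi * (layout@diameter / 2)^2)
  B <- .speciesBasis(spdf, acq)

  fid <- array(0 + 0i, dim = c(nf, nr, nc, np))
  for (f in seq_len(nf)) {
    A <- matrix(amplitudes[f, , ], nrow = dim(amplitudes)[2])  # chamber x species
    V <- (W %*% A) %*% B                                       # voxel x point
    fid[f, , , ] <- aperm(array(V, dim = c(nc, nr, np)), c(2, 1, 3))
  }
  # note: W rows are row-major (row,col); array(V, c(nc, nr, np)) unrolls the
  # first index fastest, i.e. col fastest, matching row-major order, then we
  # permute to (row, col, point).

  seedUsed <- NA_integer_
  if (noiseSd > 0) {
    seedUsed <- as.integer(seed)
    nvals <- length(fid)
    # local, reproducible RNG without disturbing the caller's stream
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seedUsed)
    fid <- fid + complex(real = stats::rnorm(nvals, sd = noiseSd),
                         imaginary = stats::rnorm(nvals, sd = noiseSd))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  new("CSIDataset", fid = fid, acq = acq, noiseSd = noiseSd, seed = seedUsed)
}
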