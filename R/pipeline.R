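#' Run configuration
#'
#' A validated bundle of the layout, species, network, acquisition and noise
#' settings driving a full simulate-reconstruct-quantify run. Configurations
#' serialize to YAML and round-trip losslessly
#' (\code{\link{writeRunConfig}} / \code{\link{readRunConfig}}).
#'
#' @slot config named list, see \code{\link{defaultRunConfig}}.
#' @export
setClass("RunConfig", representation(config = "list"))

.validateConfig <- function(cfg) {
  problems <- character()
  need <- c("seed", "noise_sd", "initial_pyruvate_mM", "initial_polarization",
            "mode", "layout", "species", "network", "acquisition")
  for (f in setdiff(need, names(cfg)))
    problems <- c(problems, sprintf("missing field: %s", f))
  if (!is.null(cfg$noise_sd) && cfg$noise_sd > 0 &&
      (is.null(cfg$seed) || !is.finite(cfg$seed)))
    problems <- c(problems, "seed: mandatory when noise_sd > 0")
  if (!is.null(cfg$mode) &&
      !cfg$mode %in% c("frame-lumped", "per-pulse"))
    problems <- c(problems, "mode: must be 'frame-lumped' or 'per-pulse'")
  if (!is.null(cfg$initial_pyruvate_mM) && cfg$initial_pyruvate_mM < 0)
    problems <- c(problems, "initial_pyruvate_mM: must be >= 0")
  if (!is.null(cfg$network) && any(unlist(
        lapply(cfg$network$edges, `[[`, "rate")) < 0))
    problems <- c(problems, "network.edges.rate: negative rate constant")
  problems
}

#' Construct a run configuration
#'
#' @param config a named list of settings.
#' @return a validated \linkS4class{RunConfig}.
#' @export
RunConfig <- function(config) {
  problems <- .validateConfig(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  new("RunConfig", config = config)
}

#' Default ("paper-default") run configuration
#'
#' Eight chambers (2 reference, 3 reaction, 3 control), the five-species
#' decarboxylation set with uniform T1 = 60 s and 53 Hz linewidth, the
#' default pseudo-first-order network, the standard CSI acquisition and
#' 80 mM initial hyperpolarized pyruvate.
#'
#' @param seed RNG seed.
#' @param noiseSd complex noise sd per FID point component.
#' @param nFrames number of frames.
#' @param mode integration mode for the spin physics.
#' @return a \linkS4class{RunConfig}.
#' @export
defaultRunConfig <- function(seed = 1L, noiseSd = 0, nFrames = 10L,
                             mode = "frame-lumped") {
  lay <- ChamberLayout()
  spdf <- speciesTable(defaultSpeciesSet())
  net <- defaultReactionNetwork()
  e <- edgeTable(net)
  acq <- AcquisitionParams(nFrames = as.integer(nFrames))
  cfg <- list(
    seed = as.integer(seed),
    noise_sd = noiseSd,
    initial_pyruvate_mM = 80,
    initial_polarization = 1,
    mode = mode,
    layout = list(centers_mm = unname(
                    apply(chamberCenters(lay), 1, as.numeric, simplify = FALSE)),
                  diameter_mm = lay@diameter, pitch_mm = lay@pitch,
                  roles = chamberRoles(lay),
                  sample_volume_uL = lay@sampleVolume, fov_mm = lay@fov),
    species = list(name = spdf$name, shift = spdf$shift, T1 = spdf$T1,
                   linewidth = spdf$linewidth),
    network = list(edges = lapply(seq_len(nrow(e)), function(i)
      list(source = e$source[i], target = e$target[i], rate = e$rate[i],
           oxidant = e$oxidant[i]))),
    acquisition = .acqToList(acq))
  RunConfig(cfg)
}

# materialize the S4 objects a config describes
.configObjects <- function(rc) {
  cfg <- rc@config
  layout <- ChamberLayout(
    centers = do.call(rbind, lapply(cfg$layout$centers_mm, as.numeric)),
    diameter = cfg$layout$diameter_mm, pitch = cfg$layout$pitch_mm,
    roles = cfg$layout$roles, sampleVolume = cfg$layout$sample_volume_uL,
    fov = cfg$layout$fov_mm)
  species <- SpeciesSet(cfg$species$name, cfg$species$shift,
                        cfg$species$T1, cfg$species$linewidth)
  edges <- do.call(rbind, lapply(cfg$network$edges, function(ed)
    data.frame(source = ed$source,
               target = if (is.null(ed$target)) NA_character_ else ed$target,
               rate = ed$rate, oxidant = isTRUE(ed$oxidant))))
  network <- ReactionNetwork(cfg$species$name, edges)
  acq <- .acqFromList(cfg$acquisition)
  list(layout = layout, species = species, network = network, acq = acq)
}

#' Write a run configuration to YAML
#'
#' @param rc a \linkS4class{RunConfig}.
#' @param path output file.
#' @export
writeRunConfig <- function(rc, path) {
  writeLines(yaml::as.yaml(rc@config, precision = 17L), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  RunConfig(yaml::read_yaml(path))
}

setMethod("show", "RunConfig", function(object) {
  cfg <- object@config
  cat("RunConfig:", cfg$acquisition$nFrames, "frames, mode", cfg$mode,
      ", noise sd", cfg$noise_sd, ", seed", cfg$seed, "\n")
})

#' Run the full simulate-reconstruct-quantify pipeline
#'
#' Executes the forward model (kinetics, spin physics, CSI synthesis), the
#' reconstruction (voxel aggregation, Fourier transform) and the
#' quantification (peak measurement, per-chamber pyruvate decay fits,
#' polarization-corrected concentrations), optionally writing all tabular
#' outputs and a JSON run manifest to \code{outDir}.
#'
#' Reference (urea) chambers receive no hyperpolarized substrate — they
#' mirror the thermally-detected geometry-QC wells — so decay fits and the
#' concentration correction use the reaction and control chambers; the
#' correction reference is the first control chamber's pyruvate signal.
#'
#' @param rc a \linkS4class{RunConfig}.
#' @param outDir output directory (created if needed); \code{NULL} to skip
#'   writing.
#' @param writeDataset also persist the full CSI dataset (large); default
#'   FALSE.
#' @param quiet suppress per-stage timing messages (default TRUE).
#' @return (invisibly) a list: \code{dataset}, \code{trajectory},
#'   \code{amplitudes}, \code{mapping}, \code{spectra}, \code{peaks},
#'   \code{fits} (data.frame), \code{concentration}, \code{manifest}.
#' @export
runPipeline <- function(rc, outDir = NULL, writeDataset = FALSE,
                        quiet = TRUE) {
  stopifnot(is(rc, "RunConfig"))
  cfg <- rc@config
  obj <- .configObjects(rc)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    if (!quiet)
      message(sprintf("[%s] %.2f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    v
  }

  roles <- chamberRoles(obj$layout)
  oxidant <- roles == "reaction"
  initial <- matrix(0, nrow = 8, ncol = length(cfg$species$name),
                    dimnames = list(rownames(chamberCenters(obj$layout)),
                                    cfg$species$name))
  initial[roles != "reference", "pyruvate"] <- cfg$initial_pyruvate_mM

  acq <- obj$acq
  spacing <- max(acq@frameInterval, acq@nPulses * acq@repetitionTime)
  tEnd <- acq@delayToFirstFrame + acq@nFrames * spacing
  times <- seq(0, ceiling(tEnd), by = 0.5)

  trajectory <- stage("kinetics",
    simulateKinetics(obj$network, initial, times, oxidant))
  amplitudes <- stage("spin physics",
    simulateHpSignal(trajectory, obj$species, acq,
                     initialPolarization = cfg$initial_polarization,
                     mode = cfg$mode))
  dataset <- stage("synthesis",
    synthesizeCSI(obj$layout, amplitudes, obj$species, acq,
                  noiseSd = cfg$noise_sd,
                  seed = if (cfg$noise_sd > 0) cfg$seed else NULL))
  mapping <- voxelChamberMap(obj$layout, acq)
  spectra <- stage("reconstruction",
    aggregateChamber(dataset, mapping, mode = cfg$mode))
  peaks <- stage("quantification", measurePeaks(spectra, obj$species))

  tb <- peakTable(peaks)
  fits <- NULL
  for (ch in which(roles != "reference")) {
    sub <- tb[tb$chamber == ch & tb$species == "pyruvate", ]
    fit <- tryCatch(fitMonoexponential(sub$time, sub$height),
                    error = function(e) NULL)
    if (!is.null(fit))
      fits <- rbind(fits, data.frame(
        chamber = ch, species = "pyruvate", role = roles[ch],
        rate = decayRate(fit), tau = timeConstant(fit),
        amplitude = decayAmplitude(fit), se = fit@se))
  }
  refChamber <- which(roles == "control")[1]
  concentration <- correctConcentration(
    peaks, refChamber, "pyruvate",
    initialConcentration = cfg$initial_pyruvate_mM)

  manifest <- list(
    package = "hpMRSI",
    version = as.character(utils::packageVersion("hpMRSI")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = .fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                          digits = NA)),
    config = cfg)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSpectraCSV(spectra, file.path(outDir, "chamber_spectra.csv"))
    writePeaksCSV(peaks, file.path(outDir, "peaks.csv"))
    utils::write.csv(fits, file.path(outDir, "decay_fits.csv"),
                     row.names = FALSE)
    writeConcentrationCSV(concentration,
                          file.path(outDir, "concentration.csv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (writeDataset) writeCSIDataset(dataset, file.path(outDir, "dataset"))
  }
  invisible(list(dataset = dataset, trajectory = trajectory,
                 amplitudes = amplitudes, mapping = mapping,
                 spectra = spectra, peaks = peaks, fits = fits,
                 concentration = concentration, manifest = manifest))
}

#' Generate a named test fixture
#'
#' Deterministic small datasets used throughout the test suite:
#' \describe{
#'   \item{\code{"two-chamber-minimal"}}{full 8-chamber layout with only two
#'     active chambers, two species (pyruvate and CO2, single conversion
#'     edge), 5 frames, noiseless.}
#'   \item{\code{"paper-default"}}{the default configuration (2 reference /
#'     3 reaction / 3 control chambers), 10 frames, mild noise, fixed seed.}
#'   \item{\code{"noiseless-kinetics"}}{the default configuration with zero
#'     noise and uniform T1, used by the concentration-recovery tests.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed (used by noisy fixtures).
#' @return a list: \code{config}, the realized pipeline pieces (see
#'   \code{\link{runPipeline}}), and for the minimal fixture the explicit
#'   objects.
#' @export
makeFixture <- function(name, seed = 20260101L) {
  registry <- c("two-chamber-minimal", "paper-default", "noiseless-kinetics")
  if (!name %in% registry)
    stop("registry error: unknown fixture '", name, "'; known: ",
         paste(registry, collapse = ", "))
  if (name == "two-chamber-minimal") {
    lay <- ChamberLayout()
    sp <- SpeciesSet(c("pyruvate", "CO2"), c(176, 125))
    net <- ReactionNetwork(c("pyruvate", "CO2"),
                           data.frame(source = "pyruvate", target = "CO2",
                                      rate = 0.1, oxidant = TRUE))
    acq <- AcquisitionParams(nFrames = 5L)
    initial <- matrix(0, 8, 2, dimnames = list(NULL, c("pyruvate", "CO2")))
    initial[c(2, 5), "pyruvate"] <- 80
    tr <- simulateKinetics(net, initial, seq(0, 70, by = 0.5),
                           oxidant = c(FALSE, TRUE, FALSE, FALSE,
                                       FALSE, FALSE, FALSE, FALSE))
    amp <- simulateHpSignal(tr, sp, acq)
    ds <- synthesizeCSI(lay, amp, sp, acq)
    return(list(name = name, layout = lay, species = sp, network = net,
                acq = acq, trajectory = tr, amplitudes = amp, dataset = ds,
                mapping = voxelChamberMap(lay, acq)))
  }
  rc <- if (name == "paper-default")
    defaultRunConfig(seed = seed, noiseSd = 2e-4, nFrames = 10L)
  else
    defaultRunConfig(seed = seed, noiseSd = 0, nFrames = 10L)
  res <- runPipeline(rc)
  c(list(name = name, config = rc), res, .configObjects(rc))
}
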