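#' Set of 13C-labelled species observed in the spectra
#'
#' One row per species: name, chemical shift (ppm), longitudinal relaxation
#' time T1 (s) and Lorentzian linewidth (full width at half maximum, Hz).
#' The default set is the five resonances of the pyruvate decarboxylation
#' spectrum: [1-13C]pyruvate (176 ppm), its hydrate (184 ppm), the
#' 2-hydroperoxy-2-hydroxypropanoate intermediate (181 ppm),
#' peroxymonocarbonate (161 ppm) and 13CO2 (125 ppm), all with a shared
#' T1 of 60 s and a 53 Hz linewidth.
#'
#' A uniform T1 across species is the default working assumption (it is also
#' the assumption under which polarization-corrected concentrations are
#' exact); per-species T1 values are supported.
#'
#' @slot species data.frame with columns \code{name}, \code{shift},
#'   \code{T1}, \code{linewidth}.
#' @export
setClass("SpeciesSet", representation(species = "data.frame"))

setValidity("SpeciesSet", function(object) {
  df <- object@species
  msg <- character()
  need <- c("name", "shift", "T1", "linewidth")
  if (!all(need %in% names(df)))
    return(paste("species table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$name)) msg <- c(msg, "species names must be distinct")
  if (anyDuplicated(df$shift)) msg <- c(msg, "chemical shifts must be distinct")
  if (any(df$T1 <= 0)) msg <- c(msg, "T1 must be positive")
  if (any(df$linewidth <= 0)) msg <- c(msg, "linewidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a species set
#'
#' @param name character vector of species names.
#' @param shift chemical shifts, ppm.
#' @param T1 longitudinal relaxation times, s (recycled; default uniform 60).
#' @param linewidth Lorentzian FWHM, Hz (recycled; default 53).
#' @return a \linkS4class{SpeciesSet}.
#' @examples
#' speciesTable(defaultSpeciesSet())
#' @export
SpeciesSet <- function(name, shift, T1 = 60, linewidth = 53) {
  df <- data.frame(name = as.character(name), shift = as.numeric(shift),
                   T1 = rep_len(T1, length(name)),
                   linewidth = rep_len(linewidth, length(name)),
                   stringsAsFactors = FALSE)
  new("SpeciesSet", species = df)
}

#' Default decarboxylation species set
#'
#' @param T1 shared T1, s.
#' @param linewidth shared FWHM, Hz.
#' @return a \linkS4class{SpeciesSet} with the five decarboxylation resonances.
#' @export
defaultSpeciesSet <- function(T1 = 60, linewidth = 53) {
  SpeciesSet(
    name = c("pyruvate", "pyruvate_hydrate", "hydroperoxy_intermediate",
             "peroxymonocarbonate", "CO2"),
    shift = c(176, 184, 181, 161, 125),
    T1 = T1, linewidth = linewidth)
}

#' @describeIn SpeciesSet the species table (data.frame).
#' @param x a \code{SpeciesSet}.
#' @export
setMethod("speciesTable", "SpeciesSet", function(x) x@species)

#' @describeIn SpeciesSet species names, in table order.
#' @export
setMethod("speciesNames", "SpeciesSet", function(x) x@species$name)

setMethod("show", "SpeciesSet", function(object) {
  cat("SpeciesSet:", nrow(object@species), "species\n")
  print(object@species, row.names = FALSE)
})

#' First-order reaction network for the labelled carbon
#'
#' Directed edges \code{source -> target} with first-order (or
#' pseudo-first-order) rate constants, tracking the C1 label of pyruvate
#' through the decarboxylation cascade. Each edge moves the label from one
#' species to exactly one other, so the label is conserved; a \code{target}
#' of \code{NA} denotes an escape (loss) pathway such as CO2 outgassing.
#'
#' Edges flagged \code{oxidant = TRUE} represent steps that require hydrogen
#' peroxide; their rates are pseudo-first-order constants valid when the
#' oxidant is in large excess, and they are silenced (rate 0) in chambers
#' without oxidant.
#'
#' The default network is
#' \preformatted{
#'   pyruvate --0.30/s (oxidant)--> hydroperoxy intermediate
#'   hydroperoxy intermediate --0.04/s--> CO2
#'   CO2 --0.015/s (oxidant)--> peroxymonocarbonate
#'   pyruvate <--0.01/s, 0.15/s--> pyruvate hydrate   (hydration exchange)
#' }
#' The rate constants are configuration, not physical constants: no rate law
#' is available for these conditions, so defaults were chosen once to
#' reproduce the qualitative time courses (near-complete pyruvate conversion
#' during the 25 s pre-acquisition delay, so its concentration plateaus near
#' zero; the intermediate acting as the reservoir that keeps draining during
#' acquisition; both end products still accumulating over the first frames).
#'
#' @slot species character, declared species names.
#' @slot edges data.frame with columns \code{source}, \code{target} (NA for
#'   escape), \code{rate} (1/s), \code{oxidant} (logical).
#' @export
setClass("ReactionNetwork",
  representation(species = "character", edges = "data.frame"))

setValidity("ReactionNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("source", "target", "rate", "oxidant")
  if (!all(need %in% names(e)))
    return(paste("edge table needs columns:", paste(need, collapse = ", ")))
  if (any(e$rate < 0)) msg <- c(msg, "validation error: negative rate constant")
  if (!all(e$source %in% object@species))
    msg <- c(msg, "edge source not among declared species")
  tt <- e$target[!is.na(e$target)]
  if (!all(tt %in% object@species))
    msg <- c(msg, "edge target not among declared species")
  if (length(msg)) msg else TRUE
})

#' Construct a reaction network
#'
#' @param species character vector of species names.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{rate}, and optionally \code{oxidant} (default FALSE). A
#'   \code{target} of NA is an escape (first-order loss) edge.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
ReactionNetwork <- function(species, edges) {
  edges <- as.data.frame(edges)
  if (is.null(edges$oxidant)) edges$oxidant <- FALSE
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  new("ReactionNetwork", species = as.character(species), edges = edges)
}

#' Default decarboxylation network
#'
#' @param kOxidation pseudo-first-order rate of pyruvate + H2O2 ->
#'   intermediate, 1/s.
#' @param kDecarboxylation intermediate -> CO2, 1/s.
#' @param kCarbonate CO2 + H2O2 -> peroxymonocarbonate, 1/s.
#' @param kHydrationF,kHydrationB hydration exchange rates, 1/s.
#' @param kEscape first-order CO2 escape (outgassing), 1/s; 0 disables.
#' @return a \linkS4class{ReactionNetwork} over the default species set.
#' @examples
#' edgeTable(defaultReactionNetwork())
#' @export
defaultReactionNetwork <- function(kOxidation = 0.30, kDecarboxylation = 0.04,
                                   kCarbonate = 0.015, kHydrationF = 0.01,
                                   kHydrationB = 0.15, kEscape = 0) {
  sp <- speciesNames(defaultSpeciesSet())
  e <- data.frame(
    source = c("pyruvate", "hydroperoxy_intermediate", "CO2",
               "pyruvate", "pyruvate_hydrate"),
    target = c("hydroperoxy_intermediate", "CO2", "peroxymonocarbonate",
               "pyruvate_hydrate", "pyruvate"),
    rate = c(kOxidation, kDecarboxylation, kCarbonate,
             kHydrationF, kHydrationB),
    oxidant = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  if (kEscape > 0)
    e <- rbind(e, data.frame(source = "CO2", target = NA_character_,
                             rate = kEscape, oxidant = FALSE))
  ReactionNetwork(sp, e)
}

#' @describeIn ReactionNetwork the edge table.
#' @param x a \code{ReactionNetwork}.
#' @export
setMethod("edgeTable", "ReactionNetwork", function(x) x@edges)

#' @describeIn ReactionNetwork declared species names.
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species)

#' Rate matrix of the network
#'
#' Builds the generator \eqn{K} of the linear ODE system
#' \eqn{dc/dt = K c} over the declared species (columns = source). Edges
#' requiring oxidant contribute only when \code{oxidant = TRUE}.
#'
#' @param x a \linkS4class{ReactionNetwork}.
#' @param oxidant logical: is H2O2 present in the chamber?
#' @return numeric nSpecies x nSpecies matrix with species dimnames.
#' @export
setMethod("rateMatrix", "ReactionNetwork", function(x, oxidant = TRUE) {
  sp <- x@species
  K <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_len(nrow(x@edges))) {
    ed <- x@edges[i, ]
    if (ed$oxidant && !oxidant) next
    K[ed$source, ed$source] <- K[ed$source, ed$source] - ed$rate
    if (!is.na(ed$target))
      K[ed$target, ed$source] <- K[ed$target, ed$source] + ed$rate
  }
  K
})

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", length(object@species), "species,",
      nrow(object@edges), "edges\n")
  e <- object@edges
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s -> %s  k = %g /s%s\n", e$source[i],
                ifelse(is.na(e$target[i]), "(escape)", e$target[i]),
                e$rate[i], ifelse(e$oxidant[i], "  [oxidant-dependent]", "")))
})
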