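#' Configuration of the synthetic imaging generator
#'
#' Describes one simulated well: field geometry, nucleus shape and intensity,
#' particle/decoy photometry, the per-genotype uptake kinetics, the imaging
#' time grid, and the noise model. True particles are rendered strictly
#' brighter than twice background and decoys at or below twice background, so
#' the fold-over-background filter has unambiguous truth.
#'
#' @slot fieldShape (height, width) in pixels.
#' @slot nNuclei nuclei per field.
#' @slot semiMajorRange,semiMinorRange nucleus semi-axis ranges, pixels.
#' @slot nucleusIntensity nuclear-stain amplitude over background, AU.
#' @slot cellBodyFold cell-body brightness as a fold over background in
#'   non-nuclear channels (faint autofluorescence).
#' @slot cellBodyScale cell-body semi-axes as a multiple of the nucleus axes.
#' @slot backgroundLevel flat background, AU.
#' @slot particleRadiusRange pHrodo particle radius range, pixels.
#' @slot particleFoldRange fold-over-background range for true particles;
#'   every value must exceed 2.
#' @slot decoyFoldRange fold range for decoys; every value must be <= 2
#'   (ceiling pinned at exactly 2 to probe the filter boundary).
#' @slot nDecoys decoy particles per field.
#' @slot uptakeRates named numeric: per-genotype rate constant k, min^-1.
#' @slot uptakePlateau lambda_max, the plateau beads/cell.
#' @slot timeGrid acquisition times in minutes (default 0..135 by 15).
#' @slot punctaRadius,punctaFold reporter/puncta dot radius (px) and
#'   brightness fold over background.
#' @slot nfkbSignal total per-cell NF-kB signal, AU (split between nucleus
#'   and cytoplasm by the requested nuclear fraction).
#' @slot poissonScale photons per AU for shot noise (0 disables).
#' @slot gaussianSd additive read-noise sd, AU (0 disables).
#' @slot backgroundGradientAmplitude peak of an optional linear background
#'   ramp across the field, AU (0 disables).
#' @slot rngSeed default seed for field simulation.
#' @exportClass ImagingSimConfig
setClass("ImagingSimConfig",
  representation(fieldShape = "integer", nNuclei = "integer",
    semiMajorRange = "numeric", semiMinorRange = "numeric",
    nucleusIntensity = "numeric", cellBodyFold = "numeric",
    cellBodyScale = "numeric", backgroundLevel = "numeric",
    particleRadiusRange = "numeric", particleFoldRange = "numeric",
    decoyFoldRange = "numeric", nDecoys = "integer",
    uptakeRates = "numeric", uptakePlateau = "numeric", timeGrid = "numeric",
    punctaRadius = "numeric", punctaFold = "numeric", nfkbSignal = "numeric",
    poissonScale = "numeric", gaussianSd = "numeric",
    backgroundGradientAmplitude = "numeric", rngSeed = "integer"))

setValidity("ImagingSimConfig", function(object) {
  if (any(object@fieldShape < 32L)) return("fieldShape must be at least 32 px")
  if (object@nNuclei < 1L) return("nNuclei must be >= 1")
  if (any(object@particleFoldRange <= 2))
    return("every true-particle fold must exceed 2.0")
  if (any(object@decoyFoldRange > 2) || any(object@decoyFoldRange <= 0))
    return("every decoy fold must lie in (0, 2.0]")
  if (diff(object@semiMajorRange) < 0 || diff(object@semiMinorRange) < 0 ||
      diff(object@particleRadiusRange) < 0)
    return("ranges must be (lo, hi) with lo <= hi")
  if (min(object@semiMajorRange) < min(object@semiMinorRange))
    return("semiMajorRange must dominate semiMinorRange")
  tg <- object@timeGrid
  if (any(tg < 0) || any(diff(tg) <= 0))
    return("timeGrid must be non-negative and strictly increasing")
  if (is.null(names(object@uptakeRates)) || any(object@uptakeRates < 0))
    return("uptakeRates must be a named, non-negative vector (per genotype)")
  if (object@uptakePlateau < 0) return("uptakePlateau must be >= 0")
  if (object@poissonScale < 0 || object@gaussianSd < 0)
    return("noise parameters must be >= 0")
  TRUE
})

#' Construct an ImagingSimConfig
#'
#' Defaults emulate a 20x high-content field of microglia: ~100 AU background,
#' bright elliptical nuclei, faint cell bodies, 3-5 px particles, shot plus
#' read noise. Uptake kinetics default to a fast and a slow genotype
#' (lambda_max = 6 beads/cell; k = 0.03 and 0.018 min^-1) sampled on the
#' 15-minute grid out to 135 min.
#'
#' @param fieldShape,nNuclei,semiMajorRange,semiMinorRange,nucleusIntensity
#'   field geometry and nucleus rendering; see \linkS4class{ImagingSimConfig}.
#' @param cellBodyFold,cellBodyScale,backgroundLevel rendering of the faint
#'   cell body and the flat background.
#' @param particleRadiusRange,particleFoldRange,decoyFoldRange,nDecoys
#'   particle photometry; true folds must exceed 2, decoys must not.
#' @param uptakeRates,uptakePlateau,timeGrid uptake kinetics and time grid.
#' @param punctaRadius,punctaFold,nfkbSignal reporter/NF-kB rendering.
#' @param poissonScale,gaussianSd,backgroundGradientAmplitude noise model.
#' @param rngSeed default simulation seed.
#' @return An \linkS4class{ImagingSimConfig}.
#' @examples
#' cfg <- imagingSimConfig(nNuclei = 5, fieldShape = c(192, 192))
#' @export
imagingSimConfig <- function(fieldShape = c(512L, 512L), nNuclei = 30L,
    semiMajorRange = c(8, 12), semiMinorRange = c(5, 8),
    nucleusIntensity = 500, cellBodyFold = 1.15, cellBodyScale = 2.2,
    backgroundLevel = 100, particleRadiusRange = c(3, 5),
    particleFoldRange = c(2.5, 5), decoyFoldRange = c(1.2, 2.0),
    nDecoys = 8L,
    uptakeRates = c(fast = 0.03, slow = 0.018), uptakePlateau = 6,
    timeGrid = seq(0, 135, by = 15),
    punctaRadius = 2.5, punctaFold = 4, nfkbSignal = 5e4,
    poissonScale = 1, gaussianSd = 5, backgroundGradientAmplitude = 0,
    rngSeed = 1L) {
  new("ImagingSimConfig", fieldShape = as.integer(fieldShape),
      nNuclei = as.integer(nNuclei),
      semiMajorRange = as.numeric(semiMajorRange),
      semiMinorRange = as.numeric(semiMinorRange),
      nucleusIntensity = nucleusIntensity, cellBodyFold = cellBodyFold,
      cellBodyScale = cellBodyScale, backgroundLevel = backgroundLevel,
      particleRadiusRange = as.numeric(particleRadiusRange),
      particleFoldRange = as.numeric(particleFoldRange),
      decoyFoldRange = as.numeric(decoyFoldRange), nDecoys = as.integer(nDecoys),
      uptakeRates = uptakeRates, uptakePlateau = uptakePlateau,
      timeGrid = as.numeric(timeGrid), punctaRadius = punctaRadius,
      punctaFold = punctaFold, nfkbSignal = nfkbSignal,
      poissonScale = poissonScale, gaussianSd = gaussianSd,
      backgroundGradientAmplitude = backgroundGradientAmplitude,
      rngSeed = as.integer(rngSeed))
}

#' Disable all noise sources of a simulation config
#'
#' Convenience for noise-free round-trip checks: zeroes shot noise, read
#' noise and the background gradient so rendered objects equal their truth
#' masks exactly.
#'
#' @param config an \linkS4class{ImagingSimConfig}.
#' @return The config with all noise off.
#' @export
noiseFree <- function(config) {
  config@poissonScale <- 0
  config@gaussianSd <- 0
  config@backgroundGradientAmplitude <- 0
  config
}

#' Configuration of the synthetic TMT generator
#'
#' Emulates an 8-plex GFP-Trap TMT immunoprecipitation protein-group table:
#' two conditions (control beads vs GFP pulldown) with
#' \code{nChannelsPerGroup} reporter channels each, log-normal intensities,
#' a set of spiked true interactors shifted in the GFP group, and flagged
#' contaminant and reverse rows.
#'
#' @slot nProteins total protein-group rows.
#' @slot nChannelsPerGroup reporter channels per condition (default 4, the
#'   8-plex two-replicate-by-four design).
#' @slot backgroundLog2Mean mean log2 intensity of the background binders.
#' @slot proteinLog2Sd between-protein sd of baseline log2 intensity.
#' @slot backgroundLog2Sd within-protein (per-channel) measurement sd on the
#'   log2 scale.
#' @slot nTrueInteractors spiked interactors.
#' @slot interactorLog2fc log2 fold-change applied to the GFP channels of
#'   spiked proteins.
#' @slot nContaminants,nReverse rows flagged as common contaminants / reverse
#'   database hits (disjoint from the spiked set).
#' @slot peptidePoissonMean unique-peptide counts are 1 + Poisson(mean), so a
#'   small fraction of rows fall below the 2-peptide filter.
#' @slot zeroRate fraction of intensity cells randomly set to zero (0 by
#'   default; exercises the zero-handling policy).
#' @slot rngSeed default simulation seed.
#' @exportClass TmtSimConfig
setClass("TmtSimConfig",
  representation(nProteins = "integer", nChannelsPerGroup = "integer",
    backgroundLog2Mean = "numeric", proteinLog2Sd = "numeric",
    backgroundLog2Sd = "numeric", nTrueInteractors = "integer",
    interactorLog2fc = "numeric", nContaminants = "integer",
    nReverse = "integer", peptidePoissonMean = "numeric",
    zeroRate = "numeric", rngSeed = "integer"))

setValidity("TmtSimConfig", function(object) {
  if (object@nProteins < 1L) return("nProteins must be >= 1")
  if (object@nChannelsPerGroup < 2L) return("need >= 2 channels per group")
  if (object@nTrueInteractors > object@nProteins)
    return("nTrueInteractors exceeds nProteins")
  if (object@nTrueInteractors + object@nContaminants + object@nReverse >
      object@nProteins)
    return("spiked + contaminant + reverse rows exceed nProteins")
  if (object@backgroundLog2Sd < 0 || object@proteinLog2Sd < 0)
    return("sds must be >= 0")
  if (object@zeroRate < 0 || object@zeroRate >= 1)
    return("zeroRate must lie in [0, 1)")
  TRUE
})

#' Construct a TmtSimConfig
#'
#' @param nProteins,nChannelsPerGroup table shape (default 2000 proteins,
#'   4 vs 4 channels).
#' @param backgroundLog2Mean,proteinLog2Sd,backgroundLog2Sd log-normal
#'   background model.
#' @param nTrueInteractors,interactorLog2fc spike-in design.
#' @param nContaminants,nReverse flagged rows.
#' @param peptidePoissonMean unique peptides ~ 1 + Poisson(mean).
#' @param zeroRate fraction of intensities zeroed.
#' @param rngSeed default simulation seed.
#' @return A \linkS4class{TmtSimConfig}.
#' @export
tmtSimConfig <- function(nProteins = 2000L, nChannelsPerGroup = 4L,
    backgroundLog2Mean = 20, proteinLog2Sd = 2, backgroundLog2Sd = 0.5,
    nTrueInteractors = 0L, interactorLog2fc = 2,
    nContaminants = 10L, nReverse = 5L, peptidePoissonMean = 5,
    zeroRate = 0, rngSeed = 1L) {
  new("TmtSimConfig", nProteins = as.integer(nProteins),
      nChannelsPerGroup = as.integer(nChannelsPerGroup),
      backgroundLog2Mean = backgroundLog2Mean, proteinLog2Sd = proteinLog2Sd,
      backgroundLog2Sd = backgroundLog2Sd,
      nTrueInteractors = as.integer(nTrueInteractors),
      interactorLog2fc = interactorLog2fc,
      nContaminants = as.integer(nContaminants), nReverse = as.integer(nReverse),
      peptidePoissonMean = peptidePoissonMean, zeroRate = zeroRate,
      rngSeed = as.integer(rngSeed))
}
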