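#' @import methods
NULL

#' Multi-channel fluorescence field
#'
#' A single imaged field: a named list of single-channel intensity matrices
#' (identical dimensions, arbitrary units, indexed \code{[row, col]}) plus
#' per-field metadata such as genotype, condition and timepoint.
#'
#' @slot channels named list of numeric matrices, one per channel.
#' @slot metadata named list; conventionally \code{genotype}, \code{condition},
#'   \code{timepoint} (minutes) and \code{well}.
#' @exportClass FieldImage
setClass("FieldImage",
  representation(channels = "list", metadata = "list"),
  prototype(channels = list(), metadata = list()))

setValidity("FieldImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must be uniquely named")
  if (!all(vapply(ch, function(x) is.matrix(x) && is.numeric(x), logical(1))))
    return("every channel must be a numeric matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share the same dimensions")
  if (any(vapply(ch, function(x) any(!is.finite(x)) || any(x < 0), logical(1))))
    return("channel intensities must be finite and non-negative")
  TRUE
})

#' Construct a FieldImage
#'
#' @param channels named list of numeric matrices (equal dimensions).
#' @param metadata named list of per-field metadata.
#' @return A \linkS4class{FieldImage}.
#' @examples
#' fieldImage(list(nuclear = matrix(1, 8, 8)), list(genotype = "wt"))
#' @export
fieldImage <- function(channels, metadata = list()) {
  new("FieldImage", channels = channels, metadata = metadata)
}

#' @describeIn fieldImage channel names of a field.
#' @param x a \code{FieldImage}.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn fieldImage extract one channel as a matrix.
#' @param name channel name.
#' @export
getChannel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "' (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
}

#' @describeIn fieldImage per-field metadata list.
#' @export
fieldMetadata <- function(x) x@metadata

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("FieldImage ", d[1], "x", d[2], " px, channels: ",
      paste(names(object@channels), collapse = ", "), "\n", sep = "")
  md <- object@metadata
  if (length(md))
    cat("  metadata: ", paste(names(md), unlist(lapply(md, format)),
                              sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("dim", "FieldImage", function(x) dim(x@channels[[1]]))

#' Segmentation parameters for nucleus detection and zone expansion
#'
#' Holds the rule-based parameters of the nucleus classifier: threshold
#' method, morphological smoothing radius (objects are shrunk and regrown by
#' this many pixels), area bounds, the elliptical-fit gate, and the
#' perinuclear zone radius.
#'
#' @slot thresholdMethod \code{"otsu"} or \code{"fixed"}.
#' @slot thresholdValue numeric; used when \code{thresholdMethod == "fixed"}.
#' @slot smoothingRadius integer pixels (default 2).
#' @slot areaBounds numeric length 2, (min, max) accepted area in px^2.
#' @slot ellipticalFitThreshold objects pass only with fit strictly above this
#'   (default 0.8).
#' @slot zoneRadius perinuclear expansion radius in pixels (default 50).
#' @slot connectivity 4 or 8 (connected-components neighbourhood).
#' @slot excludeBorder drop objects touching the field border (default FALSE;
#'   border objects are scored like any other).
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(thresholdMethod = "character", thresholdValue = "numeric",
    smoothingRadius = "integer", areaBounds = "numeric",
    ellipticalFitThreshold = "numeric", zoneRadius = "numeric",
    connectivity = "integer", excludeBorder = "logical"))

setValidity("SegmentationConfig", function(object) {
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    return("thresholdMethod must be 'otsu' or 'fixed'")
  if (object@thresholdMethod == "fixed" &&
      (length(object@thresholdValue) != 1L || !is.finite(object@thresholdValue)))
    return("fixed thresholdMethod requires a finite thresholdValue")
  if (object@ellipticalFitThreshold <= 0 || object@ellipticalFitThreshold >= 1)
    return("ellipticalFitThreshold must lie strictly in (0, 1)")
  if (length(object@areaBounds) != 2L || object@areaBounds[1] >= object@areaBounds[2])
    return("areaBounds must be (min, max) with min < max")
  if (object@smoothingRadius < 0L) return("smoothingRadius must be >= 0")
  if (object@zoneRadius <= 0) return("zoneRadius must be positive")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  TRUE
})

#' Construct a SegmentationConfig
#'
#' Defaults mirror the rule-based nucleus classifier: smoothing by 2 px,
#' elliptical-fit gate at 0.8, 50 px perinuclear zones. The area bounds have
#' no published values and default to a range suited to the synthetic nuclei
#' (see the methods vignette).
#'
#' @param thresholdMethod,thresholdValue global fluorescence threshold; Otsu
#'   by default, or a fixed intensity.
#' @param smoothingRadius pixels to shrink and regrow each object.
#' @param areaBounds (min, max) accepted nucleus area, px^2.
#' @param ellipticalFitThreshold acceptance gate on the elliptical fit.
#' @param zoneRadius perinuclear expansion radius, pixels.
#' @param connectivity 4 or 8.
#' @param excludeBorder drop border-touching objects.
#' @return A \linkS4class{SegmentationConfig}.
#' @export
segmentationConfig <- function(thresholdMethod = c("otsu", "fixed"),
    thresholdValue = NA_real_, smoothingRadius = 2L,
    areaBounds = c(60, 2500), ellipticalFitThreshold = 0.8,
    zoneRadius = 50, connectivity = 8L, excludeBorder = FALSE) {
  new("SegmentationConfig", thresholdMethod = match.arg(thresholdMethod),
      thresholdValue = as.numeric(thresholdValue),
      smoothingRadius = as.integer(smoothingRadius),
      areaBounds = as.numeric(areaBounds),
      ellipticalFitThreshold = ellipticalFitThreshold,
      zoneRadius = as.numeric(zoneRadius),
      connectivity = as.integer(connectivity),
      excludeBorder = excludeBorder)
}

#' Spot-detection parameters (pHrodo particles and puncta)
#'
#' Parameters of the local-contrast spot detector: white top-hat radius,
#' detection threshold in background-noise sigmas, binary smoothing radius,
#' area bounds, the fold-over-background retention threshold, and how the
#' background is estimated.
#'
#' @slot topHatRadius structuring-element radius (px); at least the largest
#'   expected spot radius.
#' @slot contrastSigma detection threshold = contrastSigma * robust background
#'   sigma (default 3).
#' @slot smoothingRadius binary opening radius after labelling (2 px for
#'   particles, 0 for small puncta).
#' @slot areaBounds (min, max) accepted spot area, px^2.
#' @slot foldThreshold spots are retained only when mean intensity exceeds
#'   foldThreshold times the background estimate, strictly (default 2).
#' @slot backgroundMethod \code{"outside_zones"} (median of pixels outside all
#'   zones), \code{"annulus"} (per-zone ring just outside the zone) or
#'   \code{"global"} (whole-image median).
#' @exportClass SpotConfig
setClass("SpotConfig",
  representation(topHatRadius = "integer", contrastSigma = "numeric",
    smoothingRadius = "integer", areaBounds = "numeric",
    foldThreshold = "numeric", backgroundMethod = "character"))

setValidity("SpotConfig", function(object) {
  if (object@topHatRadius < 1L) return("topHatRadius must be >= 1")
  if (object@contrastSigma < 0) return("contrastSigma must be >= 0")
  if (object@smoothingRadius < 0L) return("smoothingRadius must be >= 0")
  if (length(object@areaBounds) != 2L || object@areaBounds[1] > object@areaBounds[2])
    return("areaBounds must be (min, max)")
  if (object@foldThreshold < 0) return("foldThreshold must be >= 0")
  if (!object@backgroundMethod %in% c("outside_zones", "annulus", "global"))
    return("backgroundMethod must be outside_zones, annulus or global")
  TRUE
})

#' Construct a SpotConfig for pHrodo particle detection
#'
#' @param topHatRadius,contrastSigma,smoothingRadius,areaBounds,foldThreshold,backgroundMethod
#'   see \linkS4class{SpotConfig}.
#' @return A \linkS4class{SpotConfig}.
#' @export
particleConfig <- function(topHatRadius = 7L, contrastSigma = 3,
    smoothingRadius = 2L, areaBounds = c(4, Inf), foldThreshold = 2,
    backgroundMethod = c("outside_zones", "annulus", "global")) {
  new("SpotConfig", topHatRadius = as.integer(topHatRadius),
      contrastSigma = contrastSigma, smoothingRadius = as.integer(smoothingRadius),
      areaBounds = as.numeric(areaBounds), foldThreshold = foldThreshold,
      backgroundMethod = match.arg(backgroundMethod))
}

#' Construct a SpotConfig for puncta counting
#'
#' Puncta (p62/LC3/reporter dots) are smaller than zymosan particles: smaller
#' top hat, no binary opening, tight area bounds, and no fold filter.
#'
#' @inheritParams particleConfig
#' @return A \linkS4class{SpotConfig}.
#' @export
punctaConfig <- function(topHatRadius = 4L, contrastSigma = 3,
    smoothingRadius = 1L, areaBounds = c(3, 80), foldThreshold = 0,
    backgroundMethod = c("outside_zones", "annulus", "global")) {
  new("SpotConfig", topHatRadius = as.integer(topHatRadius),
      contrastSigma = contrastSigma, smoothingRadius = as.integer(smoothingRadius),
      areaBounds = as.numeric(areaBounds), foldThreshold = foldThreshold,
      backgroundMethod = match.arg(backgroundMethod))
}

#' Detected nuclei of one field
#'
#' Result of \code{\link{detectNuclei}}: an integer label mask (0 =
#' background) and a per-nucleus table with centroid, area, elliptical fit
#' and the accept flag. All detected objects are kept; \code{accepted}
#' records which passed the size and shape gates.
#'
#' @slot labelMask integer matrix of object labels.
#' @slot nuclei data.frame: \code{label}, \code{centroid_r}, \code{centroid_c}
#'   (1-based pixel centres), \code{area}, \code{elliptical_fit},
#'   \code{on_border}, \code{accepted}.
#' @exportClass NucleusSet
setClass("NucleusSet",
  representation(labelMask = "matrix", nuclei = "data.frame"))

setValidity("NucleusSet", function(object) {
  labs <- object@nuclei$label
  if (nrow(object@nuclei) > 0) {
    if (anyDuplicated(labs)) return("duplicate nucleus labels")
    if (!setequal(setdiff(unique(as.vector(object@labelMask)), 0L), labs))
      return("labelMask labels and nuclei table disagree")
    if (any(object@nuclei$area <= 0)) return("nucleus area must be positive")
    ef <- object@nuclei$elliptical_fit
    if (any(ef < 0 | ef > 1)) return("elliptical_fit must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet:", nrow(object@nuclei), "objects,",
      sum(object@nuclei$accepted), "accepted as nuclei\n")
})

#' @describeIn detectNuclei per-nucleus property table of a \code{NucleusSet}.
#' @param x a \code{NucleusSet}.
#' @export
nucleiTable <- function(x) x@nuclei

#' @describeIn detectNuclei integer label mask of a \code{NucleusSet}.
#' @export
labelMask <- function(x) x@labelMask

#' @describeIn detectNuclei number of accepted nuclei.
#' @export
acceptedCount <- function(x) sum(x@nuclei$accepted)

#' Perinuclear cell zones
#'
#' Result of \code{\link{expandZones}}: a partition of the pixels within
#' \code{radius} of any accepted nucleus, each assigned to its nearest
#' nucleus (ties to the lower label). Zone masks are pairwise disjoint and
#' contain their nucleus.
#'
#' @slot zoneMask integer matrix; 0 where no zone.
#' @slot radius expansion radius used, pixels.
#' @slot labels integer vector of zone labels (same ids as the nuclei).
#' @exportClass CellZoneSet
setClass("CellZoneSet",
  representation(zoneMask = "matrix", radius = "numeric", labels = "integer"))

setMethod("show", "CellZoneSet", function(object) {
  cat("CellZoneSet:", length(object@labels), "zones, radius",
      object@radius, "px\n")
})

#' @describeIn expandZones integer zone mask of a \code{CellZoneSet}.
#' @param x a \code{CellZoneSet}.
#' @export
zoneMask <- function(x) x@zoneMask

#' @describeIn expandZones zone labels.
#' @export
zoneLabels <- function(x) x@labels

#' Ground truth of a simulated field
#'
#' Complete truth tables emitted alongside every simulated field so that each
#' downstream stage can be scored exactly.
#'
#' @slot nuclei data.frame: id, centroid_r, centroid_c, semi_major,
#'   semi_minor, theta, area.
#' @slot particles data.frame: id, centroid_r, centroid_c, radius, fold,
#'   owner_nucleus, is_decoy.
#' @slot puncta data.frame: id, cell, centroid_r, centroid_c, kind
#'   ("dual" or "red").
#' @slot flux data.frame per cell: cell, n_dual_positive, n_red_only.
#' @slot nfkbFraction numeric; the true nuclear signal fraction f (NA when
#'   not an NF-kB field).
#' @slot expectedIndex data.frame: genotype, timepoint, expected beads/cell
#'   lambda_max * (1 - exp(-k t)) over the configured time grid.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(nuclei = "data.frame", particles = "data.frame",
    puncta = "data.frame", flux = "data.frame", nfkbFraction = "numeric",
    expectedIndex = "data.frame"),
  prototype(nuclei = data.frame(), particles = data.frame(),
    puncta = data.frame(), flux = data.frame(), nfkbFraction = NA_real_,
    expectedIndex = data.frame()))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@nuclei), "nuclei,",
      nrow(object@particles), "particles,", nrow(object@puncta), "puncta\n")
})

#' @describeIn simulateField truth nuclei table.
#' @param truth a \code{GroundTruth}.
#' @export
truthNuclei <- function(truth) truth@nuclei

#' @describeIn simulateField truth particle table.
#' @export
truthParticles <- function(truth) truth@particles

#' @describeIn simulateField truth puncta table.
#' @export
truthPuncta <- function(truth) truth@puncta

#' @describeIn simulateField truth per-cell flux counts.
#' @export
truthFlux <- function(truth) truth@flux

#' @describeIn simulateField true NF-kB nuclear fraction.
#' @export
truthNfkbFraction <- function(truth) truth@nfkbFraction

#' @describeIn simulateField expected beads/cell over the time grid.
#' @export
truthExpectedIndex <- function(truth) truth@expectedIndex
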