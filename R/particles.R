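#' Estimate the image background level
#'
#' Default: the median intensity of pixels outside all perinuclear zones.
#' \code{"annulus"} instead takes, per zone, the median of a ring just
#' outside the zone (useful under background gradients); \code{"global"}
#' uses the whole-image median. The estimate is floored at the smallest
#' positive observed intensity so the fold ratio stays defined.
#'
#' @param img single-channel numeric matrix.
#' @param zones a \linkS4class{CellZoneSet}.
#' @param config a \linkS4class{SpotConfig}.
#' @return For \code{"annulus"}: named numeric vector per zone label;
#'   otherwise a single number.
#' @export
estimateBackground <- function(img, zones, config = particleConfig()) {
  stopifnot(is.matrix(img), length(img) > 0)
  floorPos <- function(b) {
    pos <- img[img > 0]
    if (b > 0) b else if (length(pos)) min(pos) else 1
  }
  zm <- zones@zoneMask
  if (config@backgroundMethod == "global")
    return(floorPos(stats::median(img)))
  if (config@backgroundMethod == "annulus") {
    ring <- 10L
    out <- vapply(zones@labels, function(l) {
      src <- (zm == l) * 1
      d <- as.matrix(EBImage::imageData(EBImage::distmap(1 - src,
                                                         metric = "euclidean")))
      px <- img[d > 0 & d <= ring & zm == 0L]
      if (length(px) == 0L) px <- img[zm == 0L]
      if (length(px) == 0L) px <- as.vector(img)
      floorPos(stats::median(px))
    }, numeric(1))
    names(out) <- as.character(zones@labels)
    return(out)
  }
  outside <- img[zm == 0L]
  if (length(outside) == 0L) {
    warning("no pixels outside zones; falling back to the global median")
    outside <- as.vector(img)
  }
  floorPos(stats::median(outside))
}

# Shared spot detector: top-hat contrast detection inside the zone union,
# connected components, binary opening, per-object photometry.
detectSpots <- function(img, zones, config) {
  zm <- zones@zoneMask
  empty <- data.frame(label = integer(0), centroid_r = numeric(0),
    centroid_c = numeric(0), area = integer(0), mean_intensity = numeric(0),
    background_fold = numeric(0), owner = integer(0), retained = logical(0))
  if (length(zones@labels) == 0L) {
    warning("no zones supplied: no spots reported")
    return(empty)
  }
  bg <- estimateBackground(img, zones, config)
  outside <- img[zm == 0L]
  sigma <- robustSigma(outside)
  wth <- paddedTopHat(img, config@topHatRadius)
  # the top hat of a noisy background sits above zero (image minus its local
  # lower envelope); threshold relative to the in-zone top-hat baseline
  baseline <- stats::median(wth[zm > 0L])
  bw <- (wth > baseline + config@contrastSigma * sigma) & (zm > 0L)
  if (!any(bw)) return(empty)
  # binary smoothing (shrink and grow): removes sub-radius debris and
  # separates spots linked by thin bridges before labelling
  if (config@smoothingRadius > 0L) {
    brush <- EBImage::makeBrush(2L * config@smoothingRadius + 1L,
                                shape = "disc")
    bw <- EBImage::dilate(EBImage::erode(bw * 1, brush), brush) > 0.5
    if (!any(bw)) return(empty)
  }
  lab <- EBImage::bwlabel(bw * 1)
  nlab <- max(lab)
  rows <- list(); nspot <- 0L
  for (l in seq_len(nlab)) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) == 0L) next
    area <- nrow(px)
    if (area < config@areaBounds[1] || area > config@areaBounds[2]) next
    ctr <- c(mean(px[, 1]), mean(px[, 2]))
    # owner: zone containing the centroid; fallback = majority zone of mask
    zc <- zm[round(ctr[1]), round(ctr[2])]
    if (zc == 0L) {
      zl <- zm[px]; zl <- zl[zl > 0L]
      if (length(zl) == 0L) next
      zc <- as.integer(names(which.max(table(zl))))
    }
    mi <- mean(img[px])
    b <- if (length(bg) > 1L) unname(bg[as.character(zc)]) else bg
    nspot <- nspot + 1L
    rows[[nspot]] <- data.frame(label = nspot, centroid_r = ctr[1],
      centroid_c = ctr[2], area = area, mean_intensity = mi,
      background_fold = mi / b, owner = as.integer(zc),
      retained = (mi / b) > config@foldThreshold)
  }
  if (nspot == 0L) return(empty)
  do.call(rbind, rows)
}

#' Detect pHrodo particles within perinuclear zones
#'
#' Local-contrast detection restricted to the union of zones: white top-hat
#' (structuring-element radius \code{topHatRadius}) thresholded at
#' \code{contrastSigma} robust background sigmas, connected components,
#' binary opening by \code{smoothingRadius} (shrinking and growing, largest
#' fragment kept), then per-object photometry. Each particle's
#' \code{background_fold} is its mean intensity over the background
#' estimate; it is \code{retained} only when the fold strictly exceeds
#' \code{foldThreshold} (default 2). Objects outside every zone are never
#' reported; a particle's owner is the zone containing its centroid.
#'
#' @param img pHrodo channel matrix.
#' @param zones a \linkS4class{CellZoneSet} from \code{\link{expandZones}}.
#' @param config a \linkS4class{SpotConfig} (see \code{\link{particleConfig}}).
#' @return data.frame: label, centroid_r, centroid_c, area, mean_intensity,
#'   background_fold, owner, retained.
#' @export
detectParticles <- function(img, zones, config = particleConfig()) {
  stopifnot(is.matrix(img), all(img >= 0))
  validObject(config)
  detectSpots(img, zones, config)
}

#' Phagocytic index: beads per cell
#'
#' The per-field index: total retained spots normalized by the total number
#' of accepted nuclei.
#'
#' @param nNuclei accepted nucleus count (> 0).
#' @param nSpots retained particle count.
#' @return beads/cell (numeric).
#' @examples
#' phagocyticIndex(10, 30)  # 3
#' @export
phagocyticIndex <- function(nNuclei, nSpots) {
  if (length(nNuclei) != 1L || nNuclei <= 0)
    stop("phagocytic index undefined: field has no accepted nuclei")
  nSpots / nNuclei
}

#' Quantify one phagocytosis field end to end
#'
#' Convenience wrapper: detect nuclei, expand zones, detect particles, and
#' emit one uptake record.
#'
#' @param field a \linkS4class{FieldImage} with channels \code{nuclear} and
#'   \code{phrodo}.
#' @param segConfig a \linkS4class{SegmentationConfig}.
#' @param spotConfig a \linkS4class{SpotConfig}.
#' @return list with \code{nuclei} (NucleusSet), \code{zones} (CellZoneSet),
#'   \code{particles} (data.frame) and \code{record} (one-row UptakeRecord
#'   data.frame: genotype, condition, timepoint, n_nuclei, n_spots,
#'   beads_per_cell).
#' @export
quantifyPhagocytosis <- function(field, segConfig = segmentationConfig(),
                                 spotConfig = particleConfig()) {
  nuc <- detectNuclei(getChannel(field, "nuclear"), segConfig)
  zones <- expandZones(nuc, segConfig)
  parts <- detectParticles(getChannel(field, "phrodo"), zones, spotConfig)
  nNuc <- acceptedCount(nuc)
  md <- fieldMetadata(field)
  rec <- data.frame(
    genotype = if (is.null(md$genotype)) NA_character_ else md$genotype,
    condition = if (is.null(md$condition)) NA_character_ else md$condition,
    timepoint = if (is.null(md$timepoint)) NA_real_ else md$timepoint,
    n_nuclei = nNuc, n_spots = sum(parts$retained),
    beads_per_cell = if (nNuc > 0) sum(parts$retained) / nNuc else NA_real_)
  list(nuclei = nuc, zones = zones, particles = parts, record = rec)
}

#' Assemble per-genotype uptake curves (mean and SEM per timepoint)
#'
#' Aggregates replicate uptake records into per-(genotype, timepoint) mean
#' and standard error of beads/cell. Timepoints with a single record get
#' SEM 0 and are flagged via \code{n}. Missing timepoints are preserved as
#' gaps, never interpolated.
#'
#' @param records data.frame of uptake records (columns genotype, timepoint,
#'   beads_per_cell; optionally condition).
#' @return data.frame sorted by genotype then timepoint: genotype, timepoint,
#'   n, mean_beads_per_cell, sem.
#' @examples
#' recs <- data.frame(genotype = "g", timepoint = 0,
#'                    beads_per_cell = c(2, 3, 4))
#' assembleUptakeCurves(recs)  # mean 3, sem 0.577
#' @export
assembleUptakeCurves <- function(records) {
  need <- c("genotype", "timepoint", "beads_per_cell")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  records <- records[!is.na(records$beads_per_cell), , drop = FALSE]
  if (nrow(records) == 0L)
    return(data.frame(genotype = character(0), timepoint = numeric(0),
                      n = integer(0), mean_beads_per_cell = numeric(0),
                      sem = numeric(0)))
  key <- interaction(records$genotype, records$timepoint, drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(d) {
    n <- nrow(d)
    data.frame(genotype = d$genotype[1], timepoint = d$timepoint[1], n = n,
      mean_beads_per_cell = mean(d$beads_per_cell),
      sem = if (n > 1L) stats::sd(d$beads_per_cell) / sqrt(n) else 0)
  }))
  agg <- agg[order(agg$genotype, agg$timepoint), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
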