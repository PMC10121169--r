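#' Elliptical fit of a binary mask
#'
#' Shape score in [0, 1] used as the nucleus gate: the Jaccard overlap
#' between the mask M and its moment-equivalent ellipse E. E shares M's
#' centroid, takes its orientation and axis ratio from the eigendecomposition
#' of the second central moments of M's pixel centres, and is scaled so its
#' continuous area pi*a*b equals |M|; it is rasterized on the same
#' pixel-centre grid. The fit is |M intersect E| / |M union E|. A one-pixel
#' mask scores 1 by convention; for degenerate (collinear) masks the minor
#' semi-axis is floored at 0.5 px so E stays non-empty.
#'
#' @param mask logical or 0/1 matrix, or a two-column matrix of (row, col)
#'   pixel coordinates.
#' @return Numeric fit in [0, 1].
#' @examples
#' m <- matrix(FALSE, 40, 40); m[rasterEllipseMask(c(40,40), c(20,20), 12, 7)] <- TRUE
#' ellipticalFit(m)  # near 1
#' @export
ellipticalFit <- function(mask) {
  if (is.matrix(mask) && ncol(mask) == 2L && !is.logical(mask) &&
      all(mask == round(mask)) && nrow(mask) > 0 && max(mask) > 1) {
    px <- mask
  } else {
    px <- which(mask > 0, arr.ind = TRUE)
  }
  n <- nrow(px)
  if (is.null(n) || n == 0L) stop("elliptical fit is undefined for an empty mask")
  if (n == 1L) return(1.0)

  r <- px[, 1]; c <- px[, 2]
  mr <- mean(r); mc <- mean(c)
  crr <- mean((r - mr)^2); ccc <- mean((c - mc)^2)
  crc <- mean((r - mr) * (c - mc))
  C <- matrix(c(crr, crc, crc, ccc), 2, 2)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  theta <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])

  if (lam[2] <= .Machine$double.eps * lam[1]) {
    b <- 0.5
    a <- max(n / (pi * b), b)
  } else {
    ratio <- sqrt(lam[1] / lam[2])
    b <- sqrt(n / (pi * ratio))
    a <- ratio * b
  }

  # rasterize E over the union bounding box and count overlap with M
  r0 <- floor(min(r, mr - a) - 1); r1 <- ceiling(max(r, mr + a) + 1)
  c0 <- floor(min(c, mc - a) - 1); c1 <- ceiling(max(c, mc + a) + 1)
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  inM <- matrix(FALSE, nr, nc)
  inM[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
  rr <- matrix(r0:r1, nr, nc)
  cc <- matrix(c0:c1, nr, nc, byrow = TRUE)
  dr <- rr - mr; dc <- cc - mc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inE <- (u / a)^2 + (v / b)^2 <= 1
  inter <- sum(inM & inE)
  union <- sum(inM | inE)
  if (union == 0L) return(1.0)
  inter / union
}

#' Rasterize an ellipse mask (pixel-centre test)
#'
#' Utility used by the generator and by shape fixtures: logical matrix of
#' pixels whose centres fall inside the ellipse.
#'
#' @param shape (rows, cols) of the output matrix.
#' @param center (row, col) centre.
#' @param a,b semi-major and semi-minor axes, pixels.
#' @param theta rotation of the major axis, radians.
#' @return Logical matrix.
#' @export
rasterEllipseMask <- function(shape, center, a, b, theta = 0) {
  rasterEllipse(shape, center, a, b, theta)
}

#' Detect nuclei with the rule-based classifier
#'
#' Applies, in order: a global fluorescence threshold (Otsu by default) to
#' separate background from stained objects; connected components; hole
#' filling; morphological smoothing of each object (shrinking and regrowing
#' by \code{smoothingRadius} pixels, keeping the largest fragment if the
#' erosion splits an object); then classification — an object is accepted as
#' a nucleus iff its area lies within \code{areaBounds} and its elliptical
#' fit exceeds \code{ellipticalFitThreshold}. Border-touching objects are
#' scored like any other unless \code{excludeBorder} is set.
#'
#' @param img single-channel numeric matrix (nuclear stain), non-negative.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return A \linkS4class{NucleusSet}; empty (with a warning) when no
#'   foreground is found.
#' @examples
#' sim <- simulateField(noiseFree(imagingSimConfig(nNuclei = 4,
#'   fieldShape = c(192, 192))), "fast", 60)
#' detectNuclei(getChannel(sim$field, "nuclear"), segmentationConfig())
#' @export
detectNuclei <- function(img, config = segmentationConfig()) {
  stopifnot(is.matrix(img), all(img >= 0))
  validObject(config)
  emptySet <- function() new("NucleusSet",
    labelMask = matrix(0L, nrow(img), ncol(img)),
    nuclei = data.frame(label = integer(0), centroid_r = numeric(0),
      centroid_c = numeric(0), area = integer(0),
      elliptical_fit = numeric(0), on_border = logical(0),
      accepted = logical(0)))

  if (config@thresholdMethod == "otsu") {
    mx <- max(img)
    if (mx <= min(img)) {
      warning("constant image: no foreground under Otsu thresholding")
      return(emptySet())
    }
    thr <- EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
  } else thr <- config@thresholdValue

  bw <- img > thr
  if (!any(bw)) {
    warning("no pixels above the fluorescence threshold")
    return(emptySet())
  }

  lab <- EBImage::bwlabel(bw * 1)
  lab <- EBImage::fillHull(lab)

  # per-object smoothing (open by smoothingRadius, keep largest fragment)
  out <- matrix(0L, nrow(img), ncol(img))
  newLab <- 0L
  rows <- list()
  nlab <- max(lab)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    crop <- lab[r0:r1, c0:c1, drop = FALSE] == l
    sm <- openObject(crop, config@smoothingRadius)
    if (!any(sm)) next
    px <- which(sm, arr.ind = TRUE)
    px[, 1] <- px[, 1] + r0 - 1L
    px[, 2] <- px[, 2] + c0 - 1L
    onBorder <- any(px[, 1] == 1L) || any(px[, 1] == nrow(img)) ||
                any(px[, 2] == 1L) || any(px[, 2] == ncol(img))
    if (config@excludeBorder && onBorder) next
    newLab <- newLab + 1L
    out[px] <- newLab
    area <- nrow(px)
    fit <- ellipticalFit(px)
    rows[[newLab]] <- data.frame(label = newLab,
      centroid_r = mean(px[, 1]), centroid_c = mean(px[, 2]),
      area = area, elliptical_fit = fit, on_border = onBorder,
      accepted = area >= config@areaBounds[1] & area <= config@areaBounds[2] &
        fit > config@ellipticalFitThreshold)
  }
  if (newLab == 0L) {
    warning("all objects vanished under morphological smoothing")
    return(emptySet())
  }
  new("NucleusSet", labelMask = out, nuclei = do.call(rbind, rows))
}

#' Expand accepted nuclei into disjoint perinuclear zones
#'
#' Every pixel within \code{zoneRadius} (Euclidean distance to the nearest
#' nucleus mask pixel) of at least one accepted nucleus is assigned to the
#' nearest such nucleus; exact distance ties go to the lower label. Zones are
#' clipped at the field border, are pairwise disjoint, and contain their
#' nucleus.
#'
#' @param nuclei a \linkS4class{NucleusSet}; only accepted nuclei seed zones.
#' @param config a \linkS4class{SegmentationConfig} (supplies
#'   \code{zoneRadius}).
#' @return A \linkS4class{CellZoneSet}.
#' @export
expandZones <- function(nuclei, config = segmentationConfig()) {
  validObject(config)
  lab <- nuclei@labelMask
  keep <- nuclei@nuclei$label[nuclei@nuclei$accepted]
  zone <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep) == 0L)
    return(new("CellZoneSet", zoneMask = zone, radius = config@zoneRadius,
               labels = integer(0)))
  bestD <- matrix(Inf, nrow(lab), ncol(lab))
  pad <- ceiling(config@zoneRadius) + 2L
  for (l in sort(keep)) {
    idx <- which(lab == l, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(lab), max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(lab), max(idx[, 2]) + pad)
    src <- (lab[r0:r1, c0:c1, drop = FALSE] == l) * 1
    d <- as.matrix(EBImage::imageData(EBImage::distmap(1 - src,
                                                       metric = "euclidean")))
    win <- bestD[r0:r1, c0:c1, drop = FALSE]
    upd <- d < win   # strict: ties keep the earlier (lower) label
    win[upd] <- d[upd]
    bestD[r0:r1, c0:c1] <- win
    zwin <- zone[r0:r1, c0:c1, drop = FALSE]
    zwin[upd] <- l
    zone[r0:r1, c0:c1] <- zwin
  }
  zone[bestD > config@zoneRadius] <- 0L
  new("CellZoneSet", zoneMask = zone, radius = config@zoneRadius,
      labels = sort(as.integer(keep)))
}

#' Score detected nuclei against simulation truth
#'
#' A detected (accepted) nucleus matches a truth nucleus when its centroid
#' falls inside the truth ellipse. Recall is the fraction of truth nuclei
#' matched by at least one accepted object; precision is the fraction of
#' accepted objects matching some truth nucleus.
#'
#' @param nuclei a \linkS4class{NucleusSet}.
#' @param truth truth nuclei table (see \code{\link{truthNuclei}}).
#' @return list: \code{recall}, \code{precision}, \code{nTruth},
#'   \code{nAccepted}.
#' @export
scoreNucleusRecovery <- function(nuclei, truth) {
  acc <- nuclei@nuclei[nuclei@nuclei$accepted, , drop = FALSE]
  if (nrow(truth) == 0L)
    return(list(recall = NA_real_, precision = NA_real_, nTruth = 0L,
                nAccepted = nrow(acc)))
  inside <- function(r, c) {
    dr <- r - truth$centroid_r; dc <- c - truth$centroid_c
    u <- dr * cos(truth$theta) + dc * sin(truth$theta)
    v <- -dr * sin(truth$theta) + dc * cos(truth$theta)
    (u / truth$semi_major)^2 + (v / truth$semi_minor)^2 <= 1
  }
  hits <- matrix(FALSE, nrow(acc), nrow(truth))
  for (i in seq_len(nrow(acc)))
    hits[i, ] <- inside(acc$centroid_r[i], acc$centroid_c[i])
  list(recall = mean(colSums(hits) > 0),
       precision = if (nrow(acc)) mean(rowSums(hits) > 0) else NA_real_,
       nTruth = nrow(truth), nAccepted = nrow(acc))
}

#' Write the per-field nucleus table as CSV
#'
#' Pixel coordinates are exported 0-based (row, col) per the documented
#' interface convention.
#'
#' @param nuclei a \linkS4class{NucleusSet}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeNucleusTable <- function(nuclei, path) {
  tab <- nuclei@nuclei
  out <- data.frame(label = tab$label,
    centroid_row = tab$centroid_r - 1, centroid_col = tab$centroid_c - 1,
    area = tab$area, elliptical_fit = tab$elliptical_fit,
    accepted = tab$accepted)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
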