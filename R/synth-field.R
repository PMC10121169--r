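#' Expected beads/cell under saturating-exponential uptake
#'
#' The generator's kinetic law: the mean number of internalized particles per
#' cell at time t is \code{lambdaMax * (1 - exp(-k * t))}.
#'
#' @param k uptake rate constant, per minute.
#' @param lambdaMax plateau beads/cell.
#' @param t time in minutes (vectorized).
#' @return Expected beads/cell at each t.
#' @examples
#' expectedUptake(0.02, 6, 135)  # ~5.60
#' @export
expectedUptake <- function(k, lambdaMax, t) {
  stopifnot(k >= 0, lambdaMax >= 0, all(t >= 0))
  lambdaMax * (1 - exp(-k * t))
}

# Sample nucleus geometries and non-conflicting centroids.
# Enforces centroid separation >= sum of semi-major axes (+4 px slack).
placeNuclei <- function(config) {
  n <- config@nNuclei
  shape <- config@fieldShape
  a <- stats::runif(n, config@semiMajorRange[1], config@semiMajorRange[2])
  b <- stats::runif(n, config@semiMinorRange[1], config@semiMinorRange[2])
  theta <- stats::runif(n, 0, pi)
  cr <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    margin <- a[i] + 2
    if (2 * margin >= min(shape))
      stop("field too small to place nuclei: margin exceeds field half-size")
    ok <- FALSE
    for (try in seq_len(500L)) {
      r <- stats::runif(1, margin, shape[1] - margin)
      c <- stats::runif(1, margin, shape[2] - margin)
      if (i == 1L) { ok <- TRUE } else {
        d <- sqrt((cr[seq_len(i - 1L)] - r)^2 + (cc[seq_len(i - 1L)] - c)^2)
        ok <- all(d >= a[seq_len(i - 1L)] + a[i] + 4)
      }
      if (ok) { cr[i] <- r; cc[i] <- c; break }
    }
    if (!ok)
      stop("cannot place ", n, " nuclei in a ", shape[1], "x", shape[2],
           " field under the centroid-separation invariant ",
           "(separation >= sum of semi-major axes)")
  }
  data.frame(id = seq_len(n), centroid_r = cr, centroid_c = cc,
             semi_major = a, semi_minor = b, theta = theta)
}

# Paint the nuclear-stain channel (background + nuclei) and return the
# per-nucleus truth area from the rasterized masks.
renderNuclearChannel <- function(nuc, config) {
  shape <- config@fieldShape
  img <- matrix(config@backgroundLevel, shape[1], shape[2])
  area <- integer(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    m <- rasterEllipse(shape, c(nuc$centroid_r[i], nuc$centroid_c[i]),
                       nuc$semi_major[i], nuc$semi_minor[i], nuc$theta[i])
    img[m] <- config@backgroundLevel + config@nucleusIntensity
    area[i] <- sum(m)
  }
  list(img = img, area = area)
}

# Paint faint cell bodies (scaled nucleus ellipses) into a channel.
paintCellBodies <- function(img, nuc, config) {
  shape <- dim(img)
  level <- config@cellBodyFold * config@backgroundLevel
  for (i in seq_len(nrow(nuc))) {
    m <- rasterEllipse(shape, c(nuc$centroid_r[i], nuc$centroid_c[i]),
                       config@cellBodyScale * nuc$semi_major[i],
                       config@cellBodyScale * nuc$semi_minor[i], nuc$theta[i])
    img[m] <- pmax(img[m], level)
  }
  img
}

# Sample one particle/punctum centre in the perinuclear band of nucleus i:
# outside the nucleus ellipse, within `reach` px of the centroid disc, fully
# inside the field, and separated from previously placed centres.
samplePerinuclearSite <- function(nuc, i, radius, reach, placed, minSep,
                                  shape, what, ownGuard = FALSE) {
  r0 <- nuc$centroid_r[i]; c0 <- nuc$centroid_c[i]
  a <- nuc$semi_major[i]; b <- nuc$semi_minor[i]; th <- nuc$theta[i]
  rmax <- b + reach
  for (try in seq_len(2000L)) {
    ang <- stats::runif(1, 0, 2 * pi)
    d <- sqrt(stats::runif(1)) * rmax
    r <- r0 + d * cos(ang); c <- c0 + d * sin(ang)
    if (r < radius + 2 || c < radius + 2 ||
        r > shape[1] - radius - 1 || c > shape[2] - radius - 1) next
    u <- (r - r0) * cos(th) + (c - c0) * sin(th)
    v <- -(r - r0) * sin(th) + (c - c0) * cos(th)
    if ((u / a)^2 + (v / b)^2 < 1.0) next   # keep off the nucleus mask
    if (ownGuard && nrow(nuc) > 1L) {
      # keep the site strictly inside the owner's nearest-nucleus region:
      # lower-bound the distance to every other nucleus mask by
      # dist(centroid) - semi-major, upper-bound the own distance by
      # dist(centroid) - semi-minor
      own <- sqrt((r - r0)^2 + (c - c0)^2) - b
      oth <- sqrt((r - nuc$centroid_r[-i])^2 + (c - nuc$centroid_c[-i])^2) -
        nuc$semi_major[-i]
      if (any(oth < own + 2)) next
    }
    if (nrow(placed) > 0) {
      sep <- sqrt((placed[, 1] - r)^2 + (placed[, 2] - c)^2)
      if (any(sep < minSep + radius + placed[, 3])) next
    }
    return(c(r, c))
  }
  stop("cannot place ", what, " near nucleus ", i,
       ": local density too high for non-overlapping truth objects")
}

# Shot noise + read noise + optional linear background gradient; clamps at 0.
applyNoise <- function(img, config) {
  if (config@backgroundGradientAmplitude > 0) {
    ramp <- matrix(seq(0, 1, length.out = ncol(img)), nrow(img), ncol(img),
                   byrow = TRUE)
    img <- img + config@backgroundGradientAmplitude * ramp
  }
  if (config@poissonScale > 0)
    img <- matrix(stats::rpois(length(img), as.vector(img) * config@poissonScale) /
                    config@poissonScale, nrow(img), ncol(img))
  if (config@gaussianSd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, config@gaussianSd),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

#' Simulate one phagocytosis field with ground truth
#'
#' Renders a two-channel field (nuclear stain + pHrodo) for one genotype and
#' timepoint. Per-nucleus internalized-particle counts are Poisson with mean
#' \code{lambdaMax * (1 - exp(-k t))} where k is the genotype's uptake rate;
#' particles are bright discs painted at their fold over background inside
#' the perinuclear band of their owner nucleus. Decoy particles at folds at
#' or below 2 are added so the fold filter has falsifiable truth. Noise
#' (shot + read + optional gradient) is applied after object rendering.
#'
#' @param config an \linkS4class{ImagingSimConfig}.
#' @param genotype name of an entry of \code{config@uptakeRates}.
#' @param timepoint acquisition time, minutes.
#' @param seed RNG seed for this field (default \code{config@rngSeed}).
#' @param condition free-text condition label stored in the metadata.
#' @return \code{list(field = FieldImage, truth = GroundTruth)}.
#' @examples
#' sim <- simulateField(imagingSimConfig(nNuclei = 4, fieldShape = c(192, 192)),
#'                      genotype = "fast", timepoint = 60)
#' sim$field
#' @export
simulateField <- function(config, genotype, timepoint,
                          seed = config@rngSeed, condition = "untreated") {
  validObject(config)
  if (!genotype %in% names(config@uptakeRates))
    stop("genotype '", genotype, "' has no uptake rate in the config")
  k <- config@uptakeRates[[genotype]]
  lambda <- expectedUptake(k, config@uptakePlateau, timepoint)
  withSeed(seed, {
    nuc <- placeNuclei(config)
    nucRender <- renderNuclearChannel(nuc, config)
    nuc$area <- nucRender$area
    shape <- config@fieldShape
    phrodo <- matrix(config@backgroundLevel, shape[1], shape[2])
    phrodo <- paintCellBodies(phrodo, nuc, config)

    counts <- stats::rpois(nrow(nuc), lambda)
    nTrue <- sum(counts)
    owner <- rep(nuc$id, counts)
    decoyOwner <- if (config@nDecoys > 0)
      sample(nuc$id, config@nDecoys, replace = TRUE) else integer(0)
    isDecoy <- c(rep(FALSE, nTrue), rep(TRUE, length(decoyOwner)))
    owner <- c(owner, decoyOwner)
    nPart <- length(owner)
    radius <- stats::runif(nPart, config@particleRadiusRange[1],
                           config@particleRadiusRange[2])
    fold <- numeric(nPart)
    if (nTrue > 0)
      fold[!isDecoy] <- stats::runif(nTrue, config@particleFoldRange[1],
                                     config@particleFoldRange[2])
    if (length(decoyOwner) > 0)
      fold[isDecoy] <- stats::runif(length(decoyOwner),
                                    config@decoyFoldRange[1],
                                    config@decoyFoldRange[2])

    placed <- matrix(numeric(0), 0, 3)
    centers <- matrix(NA_real_, nPart, 2)
    for (j in seq_len(nPart)) {
      i <- match(owner[j], nuc$id)
      site <- samplePerinuclearSite(nuc, i, radius[j], reach = 40,
                                    placed = placed, minSep = 2,
                                    shape = shape, what = "particle")
      centers[j, ] <- site
      placed <- rbind(placed, c(site, radius[j]))
      px <- discPixels(site, radius[j], shape)
      phrodo[px] <- fold[j] * config@backgroundLevel
    }

    particles <- data.frame(
      id = seq_len(nPart), centroid_r = centers[, 1], centroid_c = centers[, 2],
      radius = radius, fold = fold, owner_nucleus = owner, is_decoy = isDecoy)

    field <- fieldImage(
      channels = list(nuclear = applyNoise(nucRender$img, config),
                      phrodo = applyNoise(phrodo, config)),
      metadata = list(genotype = genotype, condition = condition,
                      timepoint = timepoint, seed = seed))
    truth <- new("GroundTruth", nuclei = nuc, particles = particles,
      expectedIndex = data.frame(genotype = genotype,
        timepoint = config@timeGrid,
        expected = expectedUptake(k, config@uptakePlateau, config@timeGrid)))
    list(field = field, truth = truth)
  })
}

#' Simulate a tandem-reporter (mCherry-GFP) field with ground truth
#'
#' Renders nuclear, GFP and mCherry channels such that each cell carries
#' exactly \code{apPerCell} dual-positive puncta (painted in both reporter
#' channels at the same positions: autophagosomes) and \code{alPerCell}
#' mCherry-only puncta (autolysosomes, GFP quenched). Truth puncta are
#' non-overlapping by construction.
#'
#' @inheritParams simulateField
#' @param apPerCell dual-positive (GFP+ mCherry+) puncta per cell.
#' @param alPerCell mCherry-only puncta per cell.
#' @return \code{list(field = FieldImage, truth = GroundTruth)}.
#' @export
simulateReporterField <- function(config, apPerCell, alPerCell,
                                  seed = config@rngSeed,
                                  condition = "untreated") {
  validObject(config)
  stopifnot(apPerCell >= 0, alPerCell >= 0)
  withSeed(seed, {
    nuc <- placeNuclei(config)
    nucRender <- renderNuclearChannel(nuc, config)
    nuc$area <- nucRender$area
    shape <- config@fieldShape
    bg <- config@backgroundLevel
    gfp <- matrix(bg, shape[1], shape[2])
    mch <- matrix(bg, shape[1], shape[2])
    amp <- config@punctaFold * bg
    r <- config@punctaRadius

    rows <- list(); pid <- 0L
    placed <- matrix(numeric(0), 0, 3)   # global: truth puncta never overlap
    for (i in seq_len(nrow(nuc))) {
      kinds <- c(rep("dual", apPerCell), rep("red", alPerCell))
      for (kind in kinds) {
        site <- samplePerinuclearSite(nuc, i, r, reach = 34, placed = placed,
                                      minSep = 3, shape = shape,
                                      what = "punctum", ownGuard = TRUE)
        placed <- rbind(placed, c(site, r))
        px <- discPixels(site, r, shape)
        mch[px] <- amp
        if (kind == "dual") gfp[px] <- amp
        pid <- pid + 1L
        rows[[pid]] <- data.frame(id = pid, cell = nuc$id[i],
          centroid_r = site[1], centroid_c = site[2], kind = kind)
      }
    }
    puncta <- if (pid > 0) do.call(rbind, rows) else
      data.frame(id = integer(0), cell = integer(0), centroid_r = numeric(0),
                 centroid_c = numeric(0), kind = character(0))
    flux <- data.frame(cell = nuc$id,
                       n_dual_positive = rep(apPerCell, nrow(nuc)),
                       n_red_only = rep(alPerCell, nrow(nuc)))
    field <- fieldImage(
      channels = list(nuclear = applyNoise(nucRender$img, config),
                      gfp = applyNoise(gfp, config),
                      mcherry = applyNoise(mch, config)),
      metadata = list(condition = condition, seed = seed))
    truth <- new("GroundTruth", nuclei = nuc, puncta = puncta, flux = flux)
    list(field = field, truth = truth)
  })
}

#' Simulate an NF-kB translocation field with ground truth
#'
#' Each cell receives a fixed total NF-kB signal S, split as \code{f * S}
#' spread uniformly over the nucleus mask and \code{(1 - f) * S} over the
#' cytoplasmic annulus (the cell body minus the nucleus), on top of a flat
#' background. The truth records f.
#'
#' @inheritParams simulateField
#' @param nuclearFraction f in [0, 1]: fraction of each cell's NF-kB signal
#'   located in the nucleus.
#' @return \code{list(field = FieldImage, truth = GroundTruth)}.
#' @export
simulateNfkbField <- function(config, nuclearFraction,
                              seed = config@rngSeed, condition = "untreated") {
  validObject(config)
  if (nuclearFraction < 0 || nuclearFraction > 1)
    stop("nuclearFraction must lie in [0, 1]")
  withSeed(seed, {
    nuc <- placeNuclei(config)
    nucRender <- renderNuclearChannel(nuc, config)
    nuc$area <- nucRender$area
    shape <- config@fieldShape
    nfkb <- matrix(config@backgroundLevel, shape[1], shape[2])
    S <- config@nfkbSignal
    masks <- lapply(seq_len(nrow(nuc)), function(i)
      rasterEllipse(shape, c(nuc$centroid_r[i], nuc$centroid_c[i]),
                    nuc$semi_major[i], nuc$semi_minor[i], nuc$theta[i]))
    anyNucleus <- Reduce(`|`, masks)
    for (i in seq_len(nrow(nuc))) {
      ctr <- c(nuc$centroid_r[i], nuc$centroid_c[i])
      nmask <- masks[[i]]
      body <- rasterEllipse(shape, ctr,
                            config@cellBodyScale * nuc$semi_major[i],
                            config@cellBodyScale * nuc$semi_minor[i],
                            nuc$theta[i])
      # cytoplasm never overlaps any nucleus (the nuclear readout must not
      # be contaminated by a neighbour's cell body)
      annulus <- body & !anyNucleus
      if (sum(nmask) > 0)
        nfkb[nmask] <- nfkb[nmask] + nuclearFraction * S / sum(nmask)
      if (sum(annulus) > 0)
        nfkb[annulus] <- nfkb[annulus] + (1 - nuclearFraction) * S / sum(annulus)
    }
    field <- fieldImage(
      channels = list(nuclear = applyNoise(nucRender$img, config),
                      nfkb = applyNoise(nfkb, config)),
      metadata = list(condition = condition, seed = seed))
    truth <- new("GroundTruth", nuclei = nuc, nfkbFraction = nuclearFraction)
    list(field = field, truth = truth)
  })
}

#' Simulate beads/cell uptake records at the count level
#'
#' Draws per-field uptake records directly from the generative count model
#' (per-nucleus particle counts Poisson with mean
#' \code{lambdaMax * (1 - exp(-k t))}), without rendering pixels. This is the
#' same distribution the field renderer uses; it exists so that large
#' replicate designs (e.g. power studies of the genotype effect) can be
#' simulated cheaply once the pixel pipeline has been validated on rendered
#' fields.
#'
#' @param config an \linkS4class{ImagingSimConfig}.
#' @param genotypes genotypes to simulate (default: all configured).
#' @param nFields replicate fields per genotype x timepoint.
#' @param seed RNG seed.
#' @param condition condition label.
#' @return data.frame of \code{UptakeRecord} rows: genotype, condition,
#'   timepoint, field, n_nuclei, n_spots, beads_per_cell.
#' @export
simulateUptakeRecords <- function(config, genotypes = names(config@uptakeRates),
                                  nFields = 3L, seed = config@rngSeed,
                                  condition = "untreated") {
  validObject(config)
  withSeed(seed, {
    grid <- expand.grid(field = seq_len(nFields), timepoint = config@timeGrid,
                        genotype = genotypes, stringsAsFactors = FALSE)
    lambda <- expectedUptake(config@uptakeRates[grid$genotype],
                             config@uptakePlateau, grid$timepoint)
    nNuc <- config@nNuclei
    spots <- vapply(lambda, function(l) sum(stats::rpois(nNuc, l)), numeric(1))
    data.frame(genotype = grid$genotype, condition = condition,
               timepoint = grid$timepoint, field = grid$field,
               n_nuclei = nNuc, n_spots = spots,
               beads_per_cell = spots / nNuc)
  })
}
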