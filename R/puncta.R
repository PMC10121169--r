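#' Count puncta per cell
#'
#' Detects small bright objects (p62/LC3/reporter puncta) within each
#' perinuclear zone by white top-hat plus threshold, filters them to the
#' configured puncta area bounds, and returns per-cell counts. Because the
#' top hat removes any flat offset, counts are invariant to adding a
#' constant background.
#'
#' @param img puncta channel matrix.
#' @param zones a \linkS4class{CellZoneSet}.
#' @param config a \linkS4class{SpotConfig} (see \code{\link{punctaConfig}}).
#' @return list: \code{counts} — data.frame(cell, n) covering every zone
#'   (zeros included); \code{puncta} — per-punctum table (label, centroid_r,
#'   centroid_c, area, mean_intensity, owner).
#' @export
countPuncta <- function(img, zones, config = punctaConfig()) {
  stopifnot(is.matrix(img), all(img >= 0))
  validObject(config)
  spots <- detectSpots(img, zones, config)
  counts <- data.frame(cell = zones@labels,
    n = as.integer(table(factor(spots$owner,
                                levels = zones@labels))[as.character(zones@labels)]))
  counts$n[is.na(counts$n)] <- 0L
  list(counts = counts,
       puncta = spots[, c("label", "centroid_r", "centroid_c", "area",
                          "mean_intensity", "owner")])
}

#' Classify tandem-reporter puncta into autophagosomes and autolysosomes
#'
#' Greedy nearest-pair matching of GFP puncta to mCherry puncta within
#' \code{matchRadius}, per cell, each punctum used at most once. Matched
#' pairs are dual-positive (GFP+ mCherry+) autophagosomes; unmatched mCherry
#' puncta are autolysosomes (GFP quenched); unmatched GFP puncta are
#' biologically unexpected and reported separately as anomalies. The
#' AL/AP ratio is defined only when at least one autophagosome is present.
#'
#' @param gfpPuncta,mcherryPuncta data.frames with columns \code{owner} (cell
#'   id), \code{centroid_r}, \code{centroid_c} — e.g. the \code{puncta}
#'   element of \code{\link{countPuncta}}.
#' @param matchRadius maximum centre distance for a dual-positive pair,
#'   pixels (default 3).
#' @param cells optional vector of cell ids to report (default: all cells
#'   present in either list).
#' @return data.frame per cell: cell_id, n_autophagosome, n_autolysosome,
#'   n_gfp_only, ratio_al_ap (NA when no autophagosomes).
#' @examples
#' g <- data.frame(owner = 1, centroid_r = 1:4, centroid_c = 1)
#' m <- data.frame(owner = 1, centroid_r = c(1:4, 21:26), centroid_c = 1)
#' classifyFlux(g, m)  # AP = 4, AL = 6, ratio = 1.5
#' @export
classifyFlux <- function(gfpPuncta, mcherryPuncta, matchRadius = 3,
                         cells = NULL) {
  if (is.null(cells))
    cells <- sort(unique(c(gfpPuncta$owner, mcherryPuncta$owner)))
  out <- lapply(cells, function(cell) {
    g <- gfpPuncta[gfpPuncta$owner == cell, , drop = FALSE]
    m <- mcherryPuncta[mcherryPuncta$owner == cell, , drop = FALSE]
    ng <- nrow(g); nm <- nrow(m)
    matched <- 0L
    if (ng > 0L && nm > 0L) {
      d <- sqrt(outer(g$centroid_r, m$centroid_r, "-")^2 +
                outer(g$centroid_c, m$centroid_c, "-")^2)
      d[d > matchRadius] <- Inf
      gFree <- rep(TRUE, ng); mFree <- rep(TRUE, nm)
      repeat {
        d2 <- d[gFree, mFree, drop = FALSE]
        if (length(d2) == 0L || !any(is.finite(d2))) break
        hit <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
        gi <- which(gFree)[hit[1]]; mi <- which(mFree)[hit[2]]
        gFree[gi] <- FALSE; mFree[mi] <- FALSE
        matched <- matched + 1L
      }
    }
    ap <- matched
    al <- nm - matched
    data.frame(cell_id = cell, n_autophagosome = ap, n_autolysosome = al,
               n_gfp_only = ng - matched,
               ratio_al_ap = if (ap > 0L) al / ap else NA_real_)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = integer(0), n_autophagosome = integer(0),
               n_autolysosome = integer(0), n_gfp_only = integer(0),
               ratio_al_ap = numeric(0))
  rownames(res) <- NULL
  res
}

#' Quantify autophagy flux on a reporter field
#'
#' Counts puncta in the GFP and mCherry channels and classifies them with
#' \code{\link{classifyFlux}}.
#'
#' @param field a \linkS4class{FieldImage} with channels \code{nuclear},
#'   \code{gfp}, \code{mcherry}.
#' @param segConfig a \linkS4class{SegmentationConfig}.
#' @param spotConfig a \linkS4class{SpotConfig} for puncta.
#' @param matchRadius dual-positive matching radius, pixels.
#' @return list: \code{flux} (per-cell data.frame), \code{gfp},
#'   \code{mcherry} (puncta tables), \code{nuclei}, \code{zones}.
#' @export
quantifyFlux <- function(field, segConfig = segmentationConfig(),
                         spotConfig = punctaConfig(), matchRadius = 3) {
  nuc <- detectNuclei(getChannel(field, "nuclear"), segConfig)
  zones <- expandZones(nuc, segConfig)
  g <- countPuncta(getChannel(field, "gfp"), zones, spotConfig)
  m <- countPuncta(getChannel(field, "mcherry"), zones, spotConfig)
  flux <- classifyFlux(g$puncta, m$puncta, matchRadius = matchRadius,
                       cells = zones@labels)
  list(flux = flux, gfp = g$puncta, mcherry = m$puncta,
       nuclei = nuc, zones = zones)
}

#' Measure NF-kB nuclear localization per cell
#'
#' Two readouts per accepted nucleus, both reported. (1) Colocalized pixels:
#' the number of NF-kB-positive pixels (above an Otsu threshold on the NF-kB
#' channel, or a fixed override) inside the nucleus mask — the
#' colocalization count of the nuclear stain and NF-kB. (2) Nuclear signal
#' fraction: background-subtracted NF-kB intensity summed over the nucleus,
#' divided by the sum over the nucleus plus its cytoplasmic zone — a
#' continuous fraction in [0, 1].
#'
#' @param img NF-kB channel matrix, aligned to the nuclear channel.
#' @param nuclei a \linkS4class{NucleusSet}.
#' @param zones a \linkS4class{CellZoneSet} over the same nuclei.
#' @param threshold \code{"otsu"} (per field) or a fixed numeric intensity.
#' @return data.frame per accepted nucleus: cell_id, colocalized_pixels,
#'   nuclear_signal_fraction.
#' @export
nuclearLocalization <- function(img, nuclei, zones, threshold = "otsu") {
  stopifnot(is.matrix(img), all(img >= 0))
  if (identical(threshold, "otsu")) {
    mx <- max(img)
    thr <- if (mx > min(img))
      EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx else Inf
  } else thr <- as.numeric(threshold)
  positive <- img > thr

  bgCfg <- punctaConfig()
  bg <- estimateBackground(img, zones, bgCfg)
  net <- pmax(img - bg, 0)

  lab <- nuclei@labelMask
  zm <- zones@zoneMask
  cells <- zones@labels
  out <- lapply(cells, function(cell) {
    nmask <- lab == cell
    if (!any(nmask)) {
      message("cell ", cell, ": no nucleus mask; skipped")
      return(NULL)
    }
    zmask <- zm == cell
    denom <- sum(net[zmask | nmask])
    data.frame(cell_id = cell,
      colocalized_pixels = sum(positive & nmask),
      nuclear_signal_fraction = if (denom > 0) sum(net[nmask]) / denom
                                else NA_real_)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_id = integer(0), colocalized_pixels = integer(0),
                      nuclear_signal_fraction = numeric(0))
  rownames(res) <- NULL
  res
}

#' Quantify NF-kB translocation on a field
#'
#' Convenience wrapper: segment nuclei, expand zones, measure
#' \code{\link{nuclearLocalization}}.
#'
#' @param field a \linkS4class{FieldImage} with channels \code{nuclear} and
#'   \code{nfkb}.
#' @param segConfig a \linkS4class{SegmentationConfig}.
#' @param threshold see \code{\link{nuclearLocalization}}.
#' @return list: \code{localization} (data.frame), \code{nuclei},
#'   \code{zones}.
#' @export
quantifyNfkb <- function(field, segConfig = segmentationConfig(),
                         threshold = "otsu") {
  nuc <- detectNuclei(getChannel(field, "nuclear"), segConfig)
  zones <- expandZones(nuc, segConfig)
  loc <- nuclearLocalization(getChannel(field, "nfkb"), nuc, zones, threshold)
  list(localization = loc, nuclei = nuc, zones = zones)
}
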