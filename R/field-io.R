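#' Write a field as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per channel. Intensities are stored divided by a
#' per-field scale (the maximum intensity, at least 1) and the scale,
#' channel order and metadata are recorded in \code{<path>.json} so the
#' round trip is faithful.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param path output TIFF path (the sidecar is written next to it).
#' @return \code{path}, invisibly.
#' @export
writeFieldTiff <- function(field, path) {
  ch <- field@channels
  scale <- max(1, vapply(ch, max, numeric(1)))
  pages <- lapply(ch, function(x) x / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(channels = names(ch), intensity_scale = scale,
                  shape = dim(ch[[1]]), metadata = field@metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a field written by \code{\link{writeFieldTiff}}
#'
#' @param path TIFF path with an adjacent \code{.json} sidecar.
#' @return A \linkS4class{FieldImage}.
#' @export
readFieldTiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  ch <- lapply(pages, function(x) x * sidecar$intensity_scale)
  names(ch) <- sidecar$channels
  md <- sidecar$metadata
  fieldImage(ch, if (is.null(md)) list() else as.list(md))
}
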