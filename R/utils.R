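# Internal helpers: seeded RNG scopes, rasterization, padded morphology.

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Logical matrix of pixels (1-based centres) inside an ellipse.
# theta: rotation of the semi-major axis, radians, row/col coordinates.
rasterEllipse <- function(shape, center, a, b, theta = 0) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Indices (r, c) of pixels inside a disc; bounding-box enumeration.
discPixels <- function(center, radius, shape) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(shape[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(shape[2], ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(cbind(r = integer(0), c = integer(0)))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  keep <- (g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# Grayscale erosion/dilation with a disc structuring element, computed as a
# running min/max over the disc's pixel offsets on a replicate-padded image
# (EBImage's erode/dilate are binary-only, and zero padding would create
# border artifacts).
grayMorph <- function(img, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  off <- which(brush > 0, arr.ind = TRUE) - (radius + 1L)
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, radius), seq_len(nr), rep(nr, radius))
  ci <- c(rep(1L, radius), seq_len(nc), rep(nc, radius))
  big <- img[ri, ci]
  out <- NULL
  fun <- if (op == "erode") pmin else pmax
  for (k in seq_len(nrow(off))) {
    sub <- big[radius + off[k, 1] + seq_len(nr),
               radius + off[k, 2] + seq_len(nc)]
    out <- if (is.null(out)) sub else fun(out, sub)
  }
  out
}

# White top-hat: image minus its grayscale opening.
paddedTopHat <- function(img, radius) {
  img - grayMorph(grayMorph(img, radius, "erode"), radius, "dilate")
}

# Binary opening restricted to one object's crop; returns the largest
# fragment if erosion splits the object. mask: logical matrix.
openObject <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  pad <- radius + 1L
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- mask * 1
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  opened <- EBImage::dilate(EBImage::erode(big, brush), brush)
  out <- opened[pad + seq_len(nr), pad + seq_len(nc)] > 0.5
  lab <- EBImage::bwlabel(out * 1)
  nlab <- max(lab)
  if (nlab > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = nlab)
    out <- lab == which.max(sizes)
  }
  out
}

# Robust background sigma: MAD of the given pixel values (0 when noise-free).
robustSigma <- function(values) {
  if (length(values) == 0L) return(0)
  stats::mad(values, constant = 1.4826)
}

# Centroids / areas of a label mask, in raster-scan label order.
labelStats <- function(lab) {
  labs <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(labs) == 0L)
    return(data.frame(label = integer(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), area = integer(0)))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(
    label = labs,
    centroid_r = as.vector(tapply(idx[, 1], l, mean)[as.character(labs)]),
    centroid_c = as.vector(tapply(idx[, 2], l, mean)[as.character(labs)]),
    area = as.vector(table(factor(l, levels = labs))))
}
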