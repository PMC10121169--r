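# Independent oracles and shape fixtures, written from first principles so
# they share no code path with the package implementations.

# Brute-force elliptical-fit oracle: recompute moments with explicit loops,
# rasterize the moment-equivalent equal-area ellipse by direct point-in-
# ellipse tests over an enclosing grid, and pixel-count the Jaccard overlap.
oracleEllipticalFit <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 1L) return(1.0)
  mr <- sum(px[, 1]) / n
  mc <- sum(px[, 2]) / n
  srr <- 0; scc <- 0; src <- 0
  for (i in seq_len(n)) {
    dr <- px[i, 1] - mr; dc <- px[i, 2] - mc
    srr <- srr + dr * dr; scc <- scc + dc * dc; src <- src + dr * dc
  }
  srr <- srr / n; scc <- scc / n; src <- src / n
  tr <- srr + scc
  det <- srr * scc - src * src
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  theta <- if (abs(src) < 1e-300 && srr >= scc) 0 else atan2(l1 - srr, src)
  if (abs(src) < 1e-300) theta <- if (srr >= scc) 0 else pi / 2
  if (l2 <= .Machine$double.eps * l1) {
    b <- 0.5; a <- max(n / (pi * b), b)
  } else {
    ratio <- sqrt(l1 / l2)
    b <- sqrt(n / (pi * ratio)); a <- ratio * b
  }
  lo_r <- floor(min(px[, 1], mr - a) - 2); hi_r <- ceiling(max(px[, 1], mr + a) + 2)
  lo_c <- floor(min(px[, 2], mc - a) - 2); hi_c <- ceiling(max(px[, 2], mc + a) + 2)
  inter <- 0L; uni <- 0L
  maskSet <- paste(px[, 1], px[, 2])
  for (r in lo_r:hi_r) for (c in lo_c:hi_c) {
    dr <- r - mr; dc <- c - mc
    u <- dr * cos(theta) + dc * sin(theta)
    v <- -dr * sin(theta) + dc * cos(theta)
    inE <- (u / a)^2 + (v / b)^2 <= 1
    inM <- paste(r, c) %in% maskSet
    if (inE && inM) inter <- inter + 1L
    if (inE || inM) uni <- uni + 1L
  }
  inter / uni
}

# Shape rasterizers for the gate fixtures.
shapeEllipse <- function(a, b, theta = 0, pad = 6) {
  s <- ceiling(2 * a) + 2 * pad
  m <- matrix(FALSE, s, s)
  ctr <- (s + 1) / 2
  for (r in 1:s) for (c in 1:s) {
    dr <- r - ctr; dc <- c - ctr
    u <- dr * cos(theta) + dc * sin(theta)
    v <- -dr * sin(theta) + dc * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) m[r, c] <- TRUE
  }
  m
}

shapeSquare <- function(side, pad = 6) {
  s <- side + 2 * pad
  m <- matrix(FALSE, s, s)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

shapeCross <- function(arm, width, pad = 6) {
  s <- 2 * arm + width + 2 * pad
  m <- matrix(FALSE, s, s)
  mid <- pad + arm + seq_len(width)
  m[mid, pad + seq_len(2 * arm + width)] <- TRUE
  m[pad + seq_len(2 * arm + width), mid] <- TRUE
  m
}

shapeNotchedEllipse <- function(a, b, theta = 0, pad = 6) {
  m <- shapeEllipse(a, b, theta, pad)
  ctr <- (nrow(m) + 1) / 2
  notch <- round(ctr + c(0, a / 2))
  m[notch[1]:nrow(m), notch[2]:ncol(m)] <- FALSE
  m
}

# Brute-force balanced two-way ANOVA from cell/marginal means.
oracleTwoWayAnova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  n <- length(y)
  gm <- mean(y)
  cellMean <- tapply(y, list(A, B), mean)
  nPerCell <- table(A, B)[1, 1]
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  ssA <- sum(table(A) * (mA - gm)^2)
  ssB <- sum(table(B) * (mB - gm)^2)
  ssCell <- 0
  for (i in seq_along(levels(A))) for (j in seq_along(levels(B)))
    ssCell <- ssCell + nPerCell * (cellMean[i, j] - gm)^2
  ssAB <- ssCell - ssA - ssB
  ssTot <- sum((y - gm)^2)
  ssRes <- ssTot - ssCell
  dfA <- nlevels(A) - 1; dfB <- nlevels(B) - 1
  dfAB <- dfA * dfB; dfRes <- n - nlevels(A) * nlevels(B)
  list(ss = c(A = ssA, B = ssB, AB = ssAB, Residuals = ssRes),
       df = c(A = dfA, B = dfB, AB = dfAB, Residuals = dfRes),
       F = c(A = (ssA / dfA) / (ssRes / dfRes),
             B = (ssB / dfB) / (ssRes / dfRes),
             AB = (ssAB / dfAB) / (ssRes / dfRes)))
}

# Small default config for fast imaging tests.
testImagingConfig <- function(nNuclei = 4L, fieldShape = c(192L, 192L), ...) {
  imagingSimConfig(nNuclei = nNuclei, fieldShape = fieldShape, ...)
}

# Paint a shape mask into an image at a (row, col) offset.
placeShape <- function(img, mask, at = c(1L, 1L), value = 500) {
  rr <- at[1] + seq_len(nrow(mask)) - 1L
  cc <- at[2] + seq_len(ncol(mask)) - 1L
  stopifnot(max(rr) <= nrow(img), max(cc) <= ncol(img))
  sub <- img[rr, cc]
  sub[mask] <- value
  img[rr, cc] <- sub
  img
}
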