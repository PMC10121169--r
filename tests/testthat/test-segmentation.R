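test_that("elliptical fit: degenerate and near-perfect cases", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(ellipticalFit(one), 1.0)
  expect_error(ellipticalFit(matrix(FALSE, 4, 4)), "empty")
  solid <- shapeEllipse(10, 5)
  expect_gte(ellipticalFit(solid), 0.95)
  rot <- shapeEllipse(12, 6, theta = pi / 5)
  expect_gte(ellipticalFit(rot), 0.93)
})

test_that("elliptical fit matches the brute-force oracle on mixed shapes", {
  shapes <- list(shapeEllipse(10, 6), shapeEllipse(8, 8),
                 shapeSquare(21), shapeSquare(11),
                 shapeCross(8, 5), shapeCross(10, 3),
                 shapeNotchedEllipse(10, 6))
  for (m in shapes)
    expect_equal(ellipticalFit(m), oracleEllipticalFit(m), tolerance = 1e-9)
})

test_that("the 0.8 gate separates ellipses from crosses", {
  for (ab in list(c(9, 5), c(10, 7), c(12, 6)))
    expect_gt(ellipticalFit(shapeEllipse(ab[1], ab[2])), 0.8)
  for (aw in list(c(8, 5), c(10, 3), c(7, 4)))
    expect_lte(ellipticalFit(shapeCross(aw[1], aw[2])), 0.8)
})

test_that("detectNuclei recovers well-separated truth ellipses", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 5L, fieldShape = c(256L, 256L)))
  sim <- simulateField(cfg, "fast", 0, seed = 13)
  nuc <- detectNuclei(getChannel(sim$field, "nuclear"))
  expect_equal(acceptedCount(nuc), 5L)
  sc <- scoreNucleusRecovery(nuc, truthNuclei(sim$truth))
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
})

test_that("a cross-shaped blob of valid area is rejected by the shape gate", {
  img <- placeShape(matrix(50, 128, 128), shapeCross(10, 5),
                    at = c(40, 40))   # area 275, inside default bounds
  nuc <- detectNuclei(img, segmentationConfig(smoothingRadius = 0L))
  tab <- nucleiTable(nuc)
  expect_equal(nrow(tab), 1L)
  expect_lte(tab$elliptical_fit, 0.8)
  expect_false(tab$accepted)
})

test_that("holes are filled before scoring", {
  disc <- shapeEllipse(12, 12)
  img <- placeShape(matrix(50, 96, 96), disc, at = c(30, 30))
  img[44:52, 44:52] <- 50   # punch a hole
  nuc <- detectNuclei(img, segmentationConfig())
  expect_equal(nucleiTable(nuc)$area, sum(disc), tolerance = 0.02)
})

test_that("constant images yield an empty result with a warning", {
  expect_warning(nuc <- detectNuclei(matrix(7, 64, 64), segmentationConfig()),
                 "constant|foreground")
  expect_equal(nrow(nucleiTable(nuc)), 0L)
})

test_that("detection is idempotent on its own accepted masks", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 4L, fieldShape = c(224L, 224L)))
  sim <- simulateField(cfg, "fast", 0, seed = 3)
  nuc <- detectNuclei(getChannel(sim$field, "nuclear"))
  binary <- (labelMask(nuc) > 0) * 100
  again <- detectNuclei(binary, segmentationConfig(thresholdMethod = "fixed",
                                                   thresholdValue = 50))
  expect_equal(sort(nucleiTable(again)$area), sort(nucleiTable(nuc)$area))
  expect_equal(acceptedCount(again), acceptedCount(nuc))
})

test_that("detection is equivariant to integer translations", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 3L, fieldShape = c(192L, 192L)))
  sim <- simulateField(cfg, "fast", 0, seed = 17)
  img <- getChannel(sim$field, "nuclear")
  dy <- 7L; dx <- 11L
  shifted <- matrix(cfg@backgroundLevel, nrow(img), ncol(img))
  shifted[(1 + dy):nrow(img), (1 + dx):ncol(img)] <-
    img[1:(nrow(img) - dy), 1:(ncol(img) - dx)]
  n1 <- nucleiTable(detectNuclei(img))
  n2 <- nucleiTable(detectNuclei(shifted))
  o1 <- order(n1$centroid_r); o2 <- order(n2$centroid_r)
  expect_equal(n2$centroid_r[o2], n1$centroid_r[o1] + dy)
  expect_equal(n2$centroid_c[o2], n1$centroid_c[o1] + dx)
  expect_equal(n2$area[o2], n1$area[o1])
})

test_that("zones: single nucleus equals dilation by the zone radius", {
  img <- matrix(50, 160, 160)
  img[shapeEllipse(10, 7, pad = 70)] <- 500
  nuc <- detectNuclei(img, segmentationConfig())
  zones <- expandZones(nuc, segmentationConfig(zoneRadius = 50))
  zm <- zoneMask(zones)
  src <- (labelMask(nuc) == 1) * 1
  d <- as.matrix(EBImage::imageData(EBImage::distmap(1 - src,
                                                     metric = "euclidean")))
  expect_identical(zm == 1L, d <= 50)
})

test_that("zones split symmetrically and break ties to the lower label", {
  img <- matrix(0, 200, 200)
  img[rasterEllipseMask(c(200, 200), c(100, 70), 8, 8)] <- 500
  img[rasterEllipseMask(c(200, 200), c(100, 130), 8, 8)] <- 500
  nuc <- detectNuclei(img, segmentationConfig(thresholdMethod = "fixed",
                                              thresholdValue = 250))
  zones <- expandZones(nuc, segmentationConfig(zoneRadius = 50))
  zm <- zoneMask(zones)
  # perpendicular bisector at column 100: left half zone 1, right half zone 2
  expect_true(all(zm[, 1:99][zm[, 1:99] > 0] == 1L))
  expect_true(all(zm[, 101:200][zm[, 101:200] > 0] == 2L))
  # equidistant column goes to the lower label
  mid <- zm[, 100]
  expect_true(all(mid[mid > 0] == 1L))
  # invariants: disjoint by construction, every zone contains its nucleus
  lm <- labelMask(nuc)
  expect_true(all(zm[lm == 1L] == 1L))
  expect_true(all(zm[lm == 2L] == 2L))
})

test_that("zone pixels are within the radius of their nucleus", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 5L, fieldShape = c(256L, 256L)))
  sim <- simulateField(cfg, "fast", 0, seed = 29)
  nuc <- detectNuclei(getChannel(sim$field, "nuclear"))
  zones <- expandZones(nuc, segmentationConfig(zoneRadius = 50))
  zm <- zoneMask(zones)
  for (l in zoneLabels(zones)) {
    src <- (labelMask(nuc) == l) * 1
    d <- as.matrix(EBImage::imageData(EBImage::distmap(1 - src,
                                                       metric = "euclidean")))
    expect_lte(max(d[zm == l]), 50)
  }
})

test_that("border handling: objects on the edge are scored, flag excludes", {
  img <- matrix(50, 96, 96)
  img[rasterEllipseMask(c(96, 96), c(5, 48), 9, 6, pi / 2)] <- 500
  keep <- detectNuclei(img, segmentationConfig())
  expect_equal(nrow(nucleiTable(keep)), 1L)
  expect_true(nucleiTable(keep)$on_border)
  drop <- detectNuclei(img, segmentationConfig(excludeBorder = TRUE))
  expect_equal(nrow(nucleiTable(drop)), 0L)
})
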