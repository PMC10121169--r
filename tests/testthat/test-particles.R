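# One synthetic scene used across particle tests: a flat background with one
# detected nucleus and hand-placed discs of known fold.
particleScene <- function(folds, centers, bg = 100, radius = 4) {
  img <- matrix(bg, 256, 256)
  nucImg <- matrix(50, 256, 256)
  nucImg[rasterEllipseMask(c(256, 256), c(128, 128), 10, 7)] <- 500
  nuc <- detectNuclei(nucImg, segmentationConfig())
  zones <- expandZones(nuc, segmentationConfig(zoneRadius = 50))
  for (i in seq_along(folds)) {
    px <- which(rasterEllipseMask(c(256, 256), centers[[i]], radius, radius),
                arr.ind = TRUE)
    img[px] <- folds[i] * bg
  }
  list(img = img, zones = zones, nuc = nuc)
}

test_that("the strict 2-fold rule retains and rejects as printed", {
  sc <- particleScene(folds = c(3.0, 1.5, 2.0),
                      centers = list(c(128, 160), c(150, 128), c(105, 110)))
  parts <- detectParticles(sc$img, sc$zones)
  expect_equal(nrow(parts), 3L)
  parts <- parts[order(parts$background_fold), ]
  expect_equal(parts$background_fold, c(1.5, 2.0, 3.0), tolerance = 1e-10)
  # 1.5x and exactly 2.0x are detected but NOT retained; 3.0x is retained
  expect_equal(parts$retained, c(FALSE, FALSE, TRUE))
})

test_that("bright objects outside every zone are never reported", {
  sc <- particleScene(folds = 5, centers = list(c(20, 230)))  # far corner
  parts <- detectParticles(sc$img, sc$zones)
  expect_equal(nrow(parts), 0L)
})

test_that("empty zone list yields an empty result with a warning", {
  zones <- new("CellZoneSet", zoneMask = matrix(0L, 32, 32), radius = 50,
               labels = integer(0))
  expect_warning(parts <- detectParticles(matrix(1, 32, 32), zones),
                 "no zones")
  expect_equal(nrow(parts), 0L)
})

test_that("background estimation: flat, spotted and gradient images", {
  sc <- particleScene(folds = c(4, 4), centers = list(c(128, 160), c(150, 128)))
  # flat background of 100 with bright in-zone discs -> exactly 100
  expect_equal(estimateBackground(sc$img, sc$zones), 100)
  # no zones: global median of a uniform image is its value
  zones0 <- new("CellZoneSet", zoneMask = matrix(0L, 64, 64), radius = 50,
                labels = integer(0))
  expect_equal(estimateBackground(matrix(7.5, 64, 64), zones0,
                                  particleConfig(backgroundMethod = "global")),
               7.5)
  # linear gradient: median lies within the gradient's range, and equals
  # the directly enumerated median of out-of-zone pixels
  g <- matrix(seq(10, 90, length.out = 256), 256, 256, byrow = TRUE)
  b <- estimateBackground(g, sc$zones)
  expect_gte(b, 10); expect_lte(b, 90)
  expect_equal(b, median(g[zoneMask(sc$zones) == 0L]))
})

test_that("raising the fold threshold only lowers the retained count", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 5L, fieldShape = c(256L, 256L)))
  sim <- simulateField(cfg, "fast", 120, seed = 19)
  q <- quantifyPhagocytosis(sim$field)
  folds <- q$particles$background_fold
  thresholds <- c(1, 1.5, 2, 2.5, 3, 4)
  counts <- vapply(thresholds, function(th) sum(folds > th), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("decoys are fully rejected and true particles retained, noise-free", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 6L, fieldShape = c(256L, 256L)))
  nTrue <- 0; nTrueRet <- 0; nDecoyRet <- 0
  for (s in 1:3) {
    sim <- simulateField(cfg, "fast", 120, seed = 100 + s)
    q <- quantifyPhagocytosis(sim$field)
    tp <- truthParticles(sim$truth)
    det <- q$particles
    # match detections to truth by nearest centre
    for (i in seq_len(nrow(det))) {
      d <- sqrt((tp$centroid_r - det$centroid_r[i])^2 +
                (tp$centroid_c - det$centroid_c[i])^2)
      j <- which.min(d)
      if (d[j] < 3) {
        if (tp$is_decoy[j]) nDecoyRet <- nDecoyRet + det$retained[i]
        else nTrueRet <- nTrueRet + det$retained[i]
      }
    }
    nTrue <- nTrue + sum(!tp$is_decoy)
  }
  expect_equal(nDecoyRet, 0)
  expect_gte(nTrueRet / nTrue, 0.99)
})

test_that("phagocytic index is spots over nuclei with a zero-nuclei error", {
  expect_equal(phagocyticIndex(10, 30), 3.0)
  expect_equal(phagocyticIndex(7, 0), 0.0)
  expect_error(phagocyticIndex(0, 5), "no accepted nuclei")
})

test_that("noise-free field round-trips to the exact truth index", {
  cfg <- noiseFree(imagingSimConfig(nNuclei = 5L, fieldShape = c(256L, 256L)))
  sim <- simulateField(cfg, "fast", 135, seed = 7)
  q <- quantifyPhagocytosis(sim$field)
  tp <- truthParticles(sim$truth)
  expect_equal(q$record$n_nuclei, nrow(truthNuclei(sim$truth)))
  expect_equal(q$record$n_spots, sum(!tp$is_decoy))
  expect_equal(q$record$beads_per_cell,
               sum(!tp$is_decoy) / nrow(truthNuclei(sim$truth)))
})

test_that("uptake curves aggregate mean and SEM per genotype and timepoint", {
  recs <- data.frame(genotype = "g", timepoint = 0,
                     beads_per_cell = c(2, 3, 4))
  cv <- assembleUptakeCurves(recs)
  expect_equal(cv$mean_beads_per_cell, 3)
  expect_equal(cv$sem, sd(c(2, 3, 4)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(cv$sem, 3), 0.577)
  # single record: SEM 0 with n = 1 flagged
  one <- assembleUptakeCurves(data.frame(genotype = "g", timepoint = 15,
                                         beads_per_cell = 2.5))
  expect_equal(one$sem, 0); expect_equal(one$n, 1L)
  # full grid: 10 rows per genotype, sorted by time; gaps preserved
  cfg <- imagingSimConfig(nNuclei = 10L)
  recs <- simulateUptakeRecords(cfg, nFields = 2, seed = 4)
  cv <- assembleUptakeCurves(recs)
  expect_equal(nrow(cv), 2L * 10L)
  expect_equal(sum(cv$genotype == "fast"), 10L)
  expect_true(all(diff(cv$timepoint[cv$genotype == "fast"]) > 0))
  gap <- assembleUptakeCurves(recs[recs$timepoint != 45, ])
  expect_false(45 %in% gap$timepoint)
  expect_equal(nrow(gap), 2L * 9L)
})
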