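test_that("uptake law evaluates the saturating exponential", {
  expect_equal(expectedUptake(0.05, 6, 0), 0)
  expect_equal(expectedUptake(0.02, 6, 135), 6 * (1 - exp(-2.7)))
  expect_equal(round(expectedUptake(0.02, 6, 135), 2), 5.60)
  # default acquisition grid: 15-min intervals out to 135 min = 10 frames
  expect_equal(length(imagingSimConfig()@timeGrid), 10L)
  expect_equal(imagingSimConfig()@timeGrid, seq(0, 135, 15))
})

test_that("config validity enforces the fold and grid invariants", {
  expect_error(imagingSimConfig(particleFoldRange = c(1.5, 3)), "exceed 2")
  expect_error(imagingSimConfig(decoyFoldRange = c(1.0, 2.5)), "decoy")
  expect_error(imagingSimConfig(timeGrid = c(0, 30, 15)), "increasing")
  expect_error(imagingSimConfig(timeGrid = c(-5, 10)), "non-negative")
  cfg <- imagingSimConfig()
  expect_true(all(cfg@particleFoldRange > 2))
  expect_true(all(cfg@decoyFoldRange <= 2))
})

test_that("simulation is deterministic given the seed", {
  cfg <- testImagingConfig()
  a <- simulateField(cfg, "fast", 60, seed = 42)
  b <- simulateField(cfg, "fast", 60, seed = 42)
  expect_identical(truthNuclei(a$truth), truthNuclei(b$truth))
  expect_identical(truthParticles(a$truth), truthParticles(b$truth))
  expect_identical(a$field@channels, b$field@channels)
  c <- simulateField(cfg, "fast", 60, seed = 43)
  expect_false(identical(truthNuclei(a$truth), truthNuclei(c$truth)))
})

test_that("nuclei respect the centroid-separation invariant", {
  cfg <- testImagingConfig(nNuclei = 6L, fieldShape = c(256L, 256L))
  tn <- truthNuclei(simulateField(cfg, "fast", 0, seed = 5)$truth)
  for (i in seq_len(nrow(tn) - 1)) for (j in (i + 1):nrow(tn)) {
    d <- sqrt((tn$centroid_r[i] - tn$centroid_r[j])^2 +
              (tn$centroid_c[i] - tn$centroid_c[j])^2)
    expect_gte(d, tn$semi_major[i] + tn$semi_major[j])
  }
})

test_that("a field too small for its nuclei raises a placement error", {
  cfg <- imagingSimConfig(nNuclei = 60L, fieldShape = c(64L, 64L))
  expect_error(simulateField(cfg, "fast", 0, seed = 1), "separation|place")
})

test_that("t = 0 renders only decoys in the pHrodo channel", {
  cfg <- noiseFree(testImagingConfig())
  sim <- simulateField(cfg, "fast", 0, seed = 9)
  tp <- truthParticles(sim$truth)
  expect_true(all(tp$is_decoy))
  expect_equal(truthExpectedIndex(sim$truth)$expected[1], 0)
})

test_that("noise-free rendering matches truth photometry exactly", {
  cfg <- noiseFree(testImagingConfig())
  sim <- simulateField(cfg, "fast", 90, seed = 21)
  ph <- getChannel(sim$field, "phrodo")
  tp <- truthParticles(sim$truth)
  for (i in seq_len(nrow(tp))) {
    v <- ph[round(tp$centroid_r[i]), round(tp$centroid_c[i])]
    expect_equal(v, tp$fold[i] * cfg@backgroundLevel, tolerance = 1e-12)
  }
  nu <- getChannel(sim$field, "nuclear")
  tn <- truthNuclei(sim$truth)
  expect_equal(nu[round(tn$centroid_r[1]), round(tn$centroid_c[1])],
               cfg@backgroundLevel + cfg@nucleusIntensity)
})

test_that("per-cell particle counts follow the uptake mean", {
  cfg <- imagingSimConfig(nNuclei = 50L)
  k <- 0.03; t <- 75
  lambda <- expectedUptake(k, cfg@uptakePlateau, t)
  recs <- simulateUptakeRecords(cfg, genotypes = "fast", nFields = 5,
                                seed = 31)
  recs <- recs[recs$timepoint == t, ]
  nCells <- sum(recs$n_nuclei)   # 250 simulated cells
  expect_gte(nCells, 200)
  mu <- sum(recs$n_spots) / nCells
  se <- sqrt(lambda / nCells)
  expect_lt(abs(mu - lambda), 3 * se)
})

test_that("reporter fields carry exact dual/red truth", {
  cfg <- noiseFree(testImagingConfig())
  sim <- simulateReporterField(cfg, 4, 6, seed = 2)
  fx <- truthFlux(sim$truth)
  expect_true(all(fx$n_dual_positive == 4))
  expect_true(all(fx$n_red_only == 6))
  expect_equal(fx$n_red_only[1] / fx$n_dual_positive[1], 1.5)
  # ap = al = 0: reporter channels are pure background
  s0 <- simulateReporterField(cfg, 0, 0, seed = 2)
  expect_equal(max(getChannel(s0$field, "gfp")), cfg@backgroundLevel)
  expect_equal(max(getChannel(s0$field, "mcherry")), cfg@backgroundLevel)
})

test_that("nfkb fields place the requested signal split", {
  cfg <- noiseFree(testImagingConfig())
  s <- simulateNfkbField(cfg, 0, seed = 6)
  # f = 0: nothing above background inside nuclei
  ch <- getChannel(s$field, "nfkb")
  tn <- truthNuclei(s$truth)
  for (i in seq_len(nrow(tn)))
    expect_equal(ch[round(tn$centroid_r[i]), round(tn$centroid_c[i])],
                 cfg@backgroundLevel)
  expect_error(simulateNfkbField(cfg, 1.2), "0, 1")
  expect_equal(truthNfkbFraction(simulateNfkbField(cfg, 0.3, seed = 6)$truth),
               0.3)
})

test_that("TMT simulation encodes the spike-in design", {
  cfg <- tmtSimConfig(nProteins = 200L, nTrueInteractors = 10L,
                      interactorLog2fc = 1, backgroundLog2Sd = 0.1)
  se <- simulateTmt(cfg, seed = 8)
  expect_equal(dim(se), c(200L, 8L))
  truth <- S4Vectors::metadata(se)$truth
  expect_length(truth$spiked, 10L)
  expect_length(intersect(truth$spiked, truth$contaminant), 0L)
  expect_length(intersect(truth$spiked, truth$reverse), 0L)
  # spiked group-mean difference on log2 scale ~ the configured log2fc
  m <- log2(SummarizedExperiment::assay(se))
  grp <- SummarizedExperiment::colData(se)$group
  d <- rowMeans(m[, grp == "gfp"]) - rowMeans(m[, grp == "control"])
  spiked <- rownames(se) %in% truth$spiked
  expect_equal(mean(d[spiked]), 1, tolerance = 0.2)
  expect_equal(mean(d[!spiked]), 0, tolerance = 0.1)
  # null config: empty truth-positive set
  se0 <- simulateTmt(tmtSimConfig(nProteins = 50L), seed = 8)
  expect_length(S4Vectors::metadata(se0)$truth$spiked, 0L)
  expect_error(tmtSimConfig(nProteins = 10L, nTrueInteractors = 20L),
               "exceed")
  # determinism
  expect_identical(
    SummarizedExperiment::assay(simulateTmt(cfg, seed = 3)),
    SummarizedExperiment::assay(simulateTmt(cfg, seed = 3)))
})
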