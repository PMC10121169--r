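test_that("TMT preprocessing applies the three filters and log2", {
  ints <- matrix(2^seq(10, 10 + 39), 5, 8,
                 dimnames = list(paste0("p", 1:5), NULL))
  colnames(ints) <- c(paste0("control_", 1:4), paste0("gfp_", 1:4))
  se <- tmtTable(ints, rep(c("control", "gfp"), each = 4),
                 uniquePeptides = c(5L, 1L, 3L, 2L, 4L),
                 isReverse = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  prep <- preprocessTmt(se)
  # one reverse row and one row with a single unique peptide removed
  expect_equal(sort(prep$kept), c("p1", "p4", "p5"))
  expect_equal(unname(prep$filtered["reverse"]), 1L)
  expect_equal(unname(prep$filtered["min_peptides"]), 1L)
  # log2 transform: intensity 8 -> 3
  se8 <- tmtTable(matrix(8, 2, 8, dimnames = list(c("a", "b"), NULL)),
                  rep(c("control", "gfp"), each = 4), c(3L, 3L))
  expect_true(all(preprocessTmt(se8)$log2mat == 3))
})

test_that("zero intensities are dropped (or offset) as configured", {
  ints <- matrix(1000, 4, 8, dimnames = list(paste0("p", 1:4), NULL))
  ints[2, 5] <- 0
  se <- tmtTable(ints, rep(c("control", "gfp"), each = 4), rep(3L, 4))
  expect_message(prep <- preprocessTmt(se), "zero")
  expect_false("p2" %in% prep$kept)
  expect_equal(prep$nZeroDropped, 1L)
  off <- preprocessTmt(se, zeroPolicy = "offset")
  expect_true("p2" %in% off$kept)
  # everything filtered -> error naming the dominant filter
  seAll <- tmtTable(ints, rep(c("control", "gfp"), each = 4), rep(3L, 4),
                    isContaminant = rep(TRUE, 4))
  expect_error(preprocessTmt(seAll), "contaminant")
})

test_that("simulated tables filter by construction", {
  cfg <- tmtSimConfig(nProteins = 2000L, nContaminants = 10L, nReverse = 5L,
                      peptidePoissonMean = 50)  # no low-peptide rows
  se <- simulateTmt(cfg, seed = 2)
  prep <- preprocessTmt(se)
  expect_equal(length(prep$kept), 1985L)
})

test_that("Welch t handles identities and degenerate variance", {
  same <- welchT(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # equal variances and equal n collapse Satterthwaite to n1 + n2 - 2
  a <- c(1, 2, 3, 4); b <- a + 10
  w <- welchT(a, b)
  expect_equal(w$df, length(a) + length(b) - 2)
  # zero variance in both groups
  z <- welchT(c(5, 5, 5), c(5, 5, 5))
  expect_equal(z$t, 0); expect_equal(z$p, 1); expect_true(z$degenerate)
  zz <- welchT(c(5, 5, 5), c(7, 7, 7))
  expect_true(is.infinite(zz$t)); expect_equal(zz$p, 0)
  expect_error(welchT(1, c(1, 2)), ">= 2")
})

test_that("Welch t matches the independent implementation on random data", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      a <- rnorm(n1, sd = runif(1, 0.5, 3))
      b <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      w <- welchT(a, b)
      tt <- t.test(a, b)
      expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
      expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("permutation FDR: nesting, exhaustion and invariances", {
  cfg <- tmtSimConfig(nProteins = 300L, nTrueInteractors = 10L,
                      interactorLog2fc = 4, backgroundLog2Sd = 0.3)
  se <- simulateTmt(cfg, seed = 5)
  prep <- suppressMessages(preprocessTmt(se))
  expect_message(
    res <- permutationFdr(prep$log2mat, prep$group, nPermutations = 1000L),
    "exhaustive")
  expect_equal(attr(res, "nPermutations"), 34L)
  # 5% calls contain the 1% calls
  expect_true(all(res$id[res$sig_0.01] %in% res$id[res$sig_0.05]))
  # FDR curve is non-increasing in tau (tau sorted decreasing)
  curve <- attr(res, "fdrCurve")
  expect_true(all(diff(curve$fdr) >= -1e-12))
  # row order invariance
  perm <- withr::with_seed(1, sample(nrow(prep$log2mat)))
  res2 <- suppressMessages(
    permutationFdr(prep$log2mat[perm, ], prep$group, nPermutations = 1000L))
  m <- match(res$id, res2$id)
  expect_equal(res$qvalue, res2$qvalue[m])
  expect_equal(res$sig_0.01, res2$sig_0.01[m])
})

test_that("strong spike-ins are recovered exactly at 1% FDR", {
  cfg <- tmtSimConfig(nProteins = 1000L, nTrueInteractors = 25L,
                      interactorLog2fc = 5, backgroundLog2Sd = 0.2)
  se <- simulateTmt(cfg, seed = 6)
  res <- suppressMessages(tmtEnrichment(se, seed = 6))
  truth <- S4Vectors::metadata(se)$truth$spiked
  called <- callInteractors(res, foldMin = 2, fdrLevel = 0.01)
  expect_setequal(called, truth)
})

test_that("interactor calling is the conjunction of fold and FDR", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    log2fc = log2(c(1.9, 4.0, 2.5, 3.2)),
                    sig_0.01 = c(TRUE, FALSE, TRUE, TRUE))
  called <- callInteractors(res, foldMin = 2, fdrLevel = 0.01)
  # a: fold 1.9 (significant) excluded by the strict > 2 rule
  # b: fold 4.0 but not significant -> excluded
  expect_setequal(called, c("c", "d"))
  expect_error(callInteractors(res, fdrLevel = 0.2), "FDR level")
  # top set: fold >= 3 only, ordered by fold then id, capped at k
  res$sig_0.05 <- TRUE
  expect_equal(topSet(res, foldMin = 3, k = 50), c("b", "d"))
  expect_equal(topSet(res, foldMin = 3, k = 1), "b")
})

test_that("two-way ANOVA matches brute-force sums of squares", {
  withr::with_seed(11, {
    d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
    d$y <- rnorm(nrow(d)) + 2 * (d$A == "a1") + 0.5 * (d$B == "b2")
  })
  tab <- twoWayAnova(d$y, d$A, d$B)
  oracle <- oracleTwoWayAnova(d$y, d$A, d$B)
  expect_equal(tab$sumsq, unname(oracle$ss), tolerance = 1e-9)
  expect_equal(tab$df, unname(oracle$df))
  expect_equal(tab$statistic[1:3], unname(oracle$F), tolerance = 1e-9)
  # SS decomposition is exact: sources sum to total
  expect_equal(sum(tab$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-9)
})

test_that("ANOVA edge cases: degenerate data, empty cells, unbalance", {
  d <- expand.grid(A = c("x", "y"), B = c("u", "v"), rep = 1:2)
  d$y <- 5
  tab <- twoWayAnova(d$y, d$A, d$B)
  expect_true(attr(tab, "degenerate"))
  expect_equal(sum(tab$sumsq), 0)
  # empty cell
  d2 <- d[!(d$A == "x" & d$B == "u"), ]
  expect_error(twoWayAnova(d2$y, d2$A, d2$B), "empty design cell")
  # unbalanced design runs through Type II
  withr::with_seed(3, {
    d3 <- rbind(d, data.frame(A = "x", B = "u", rep = 3, y = 1))
    d3$y <- rnorm(nrow(d3))
  })
  expect_error(twoWayAnova(d3$y, d3$A, d3$B, type = "balanced"), "unbalanced")
  t2 <- twoWayAnova(d3$y, d3$A, d3$B)
  expect_equal(t2$source, c("A", "B", "A:B", "Residuals"))
  expect_true(all(is.finite(t2$p_value[1:3])))
})

test_that("Tukey and Sidak adjustments behave canonically", {
  withr::with_seed(7, {
    d <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2"), rep = 1:4)
    d$y <- rnorm(nrow(d)) + 3 * (d$A == "a3")
  })
  tk <- tukeyHsd(d$y, d$A, d$B)
  expect_true("A" %in% names(tk))
  pA <- tk$A[, "p adj"]
  expect_true(all(pA >= 0 & pA <= 1))
  expect_lt(pA["a3-a1"], 0.01)
  # Sidak: identity at m = 1, cap at 1, matches the closed form
  expect_equal(sidakAdjust(0.05, 1), 0.05)
  expect_equal(sidakAdjust(0.2, 10), 1 - 0.8^10)
  expect_equal(sidakAdjust(0.9, 50), 1)
  # Student t agrees with the base implementation
  st <- studentT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$p, t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$p.value)
})

test_that("cytokine normalization is proportional to the reference", {
  expect_equal(normalizeCytokine(200, 100, 100), 200)
  expect_equal(normalizeCytokine(200, 50, 100), 400)
  expect_equal(normalizeCytokine(100, 250, 500), 200)
  expect_error(normalizeCytokine(100, 0), "positive")
})
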