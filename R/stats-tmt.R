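#' Filter and log2-transform a TMT protein-group table
#'
#' Removes rows flagged as common contaminants or reverse database hits and
#' rows with fewer than \code{minPeptides} unique peptides, then
#' log2-transforms the reporter intensities. Rows containing zero
#' intensities in any used channel are, under the default policy, dropped
#' with a reported count (\code{zeroPolicy = "offset"} instead adds a small
#' constant before the transform).
#'
#' @param se a TMT \code{SummarizedExperiment} (see \code{\link{simulateTmt}}
#'   / \code{\link{tmtTable}}).
#' @param minPeptides minimum unique peptides retained (default 2).
#' @param zeroPolicy \code{"drop"} or \code{"offset"}.
#' @param offset constant added under the offset policy.
#' @return list: \code{log2mat} (retained proteins x channels),
#'   \code{group} (factor per channel), \code{kept} (retained protein ids),
#'   \code{nZeroDropped}, and \code{filtered} (counts removed per filter).
#' @export
preprocessTmt <- function(se, minPeptides = 2L,
                          zeroPolicy = c("drop", "offset"), offset = 1) {
  zeroPolicy <- match.arg(zeroPolicy)
  rd <- SummarizedExperiment::rowData(se)
  ints <- SummarizedExperiment::assay(se, "intensity")
  group <- SummarizedExperiment::colData(se)$group
  nContam <- sum(rd$is_contaminant)
  nRev <- sum(rd$is_reverse & !rd$is_contaminant)
  lowPep <- rd$unique_peptides < minPeptides
  nPep <- sum(lowPep & !rd$is_contaminant & !rd$is_reverse)
  keep <- !rd$is_contaminant & !rd$is_reverse & !lowPep
  ints <- ints[keep, , drop = FALSE]
  nZero <- 0L
  if (zeroPolicy == "drop") {
    hasZero <- rowSums(ints <= 0) > 0L
    nZero <- sum(hasZero)
    if (nZero > 0L) {
      message(nZero, " protein(s) with zero reporter intensity dropped ",
              "before log2 transform")
      ints <- ints[!hasZero, , drop = FALSE]
    }
  } else ints <- ints + offset
  if (nrow(ints) == 0L) {
    dominant <- c(contaminant = nContam, reverse = nRev, min_peptides = nPep,
                  zero_intensity = nZero)
    stop("all rows removed; dominant filter: ",
         names(which.max(dominant)))
  }
  list(log2mat = log2(ints), group = factor(group), kept = rownames(ints),
       nZeroDropped = nZero,
       filtered = c(contaminant = nContam, reverse = nRev,
                    min_peptides = nPep, zero_intensity = nZero))
}

#' Welch's two-sample t test (closed form)
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite degrees
#' of freedom and a two-sided p value. When both groups have zero variance:
#' equal means give t = 0, p = 1; unequal means give an infinite t (p = 0),
#' flagged via the \code{degenerate} element.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @return list: \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @examples
#' welchT(c(1, 2, 3, 4), c(11, 12, 13, 14))
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  dm <- mean(a) - mean(b)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(dm) * Inf, df = n1 + n2 - 2, p = 0, degenerate = TRUE))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

# Vectorized Welch d-statistic over matrix rows, with variance fudge s0
# added to the denominator (s0 = 0 gives the plain Welch t).
rowWelchD <- function(mat, idx1, idx2, s0 = 0) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- mat[, idx1, drop = FALSE]; x2 <- mat[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  (m1 - m2) / (sqrt(v1 / n1 + v2 / n2) + s0)
}

# All balanced relabelings of the channels as index sets for "group 1",
# reduced to distinct partitions (a labeling and its mirror give the same
# |d|), excluding the observed grouping.
balancedRelabelings <- function(group) {
  idxAll <- seq_along(group)
  g2 <- which(group == levels(group)[2])
  n2 <- length(g2)
  sets <- utils::combn(idxAll, n2)
  anchor <- idxAll[1]
  keep <- apply(sets, 2, function(s) anchor %in% s == (anchor %in% g2))
  sets <- sets[, keep, drop = FALSE]
  obs <- sort(g2)
  notObs <- apply(sets, 2, function(s) !identical(sort(s), obs))
  sets[, notObs, drop = FALSE]
}

#' Permutation-based FDR for TMT enrichment
#'
#' For each protein the observed statistic is a Welch d (group 2 minus
#' group 1 on the log2 scale, with variance fudge \code{s0} in the
#' denominator). Group labels are permuted over the distinct balanced
#' relabelings of the channels (exhaustively when there are no more than
#' \code{nPermutations}, otherwise a seeded uniform sample without
#' replacement). At each candidate threshold tau (the observed |d| values)
#' the estimated FDR is the mean (or median) permuted count of |d| >= tau
#' divided by the observed count, monotonized step-down so the FDR is
#' non-increasing in tau; a protein is significant at level alpha iff its
#' |d| meets the smallest tau whose monotonized FDR is <= alpha.
#'
#' @param log2mat numeric matrix, proteins x channels.
#' @param group two-level factor over the channels (enrichment is level 2
#'   minus level 1).
#' @param levels FDR levels to call (default 1\% and 5\%).
#' @param nPermutations requested permutations (default 1000; capped at the
#'   exhaustive set with a message).
#' @param s0 variance fudge (default 0).
#' @param seed RNG seed for permutation sampling.
#' @param estimator \code{"mean"} (default) or \code{"median"} permuted
#'   count.
#' @return data.frame per protein: id, d, qvalue, and one logical
#'   \code{sig_*} column per level; the FDR curve (tau, raw and monotonized
#'   FDR) is attached as \code{attr(, "fdrCurve")}.
#' @export
permutationFdr <- function(log2mat, group, levels = c(0.01, 0.05),
                           nPermutations = 1000L, s0 = 0, seed = 1L,
                           estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, min(table(group)) >= 2L)
  idx1 <- which(group == levels(group)[1])
  idx2 <- which(group == levels(group)[2])
  dObs <- rowWelchD(log2mat, idx1, idx2, s0)

  perms <- balancedRelabelings(group)
  nAvail <- ncol(perms)
  if (nPermutations < nAvail) {
    sel <- withSeed(seed, sample.int(nAvail, nPermutations))
    perms <- perms[, sel, drop = FALSE]
  } else if (nPermutations > nAvail) {
    message("only ", nAvail, " distinct balanced relabelings exist; ",
            "using the exhaustive set")
  }
  nPerm <- ncol(perms)
  all <- seq_len(ncol(log2mat))
  absPerm <- matrix(0, nrow(log2mat), nPerm)
  for (j in seq_len(nPerm)) {
    i2 <- perms[, j]
    i1 <- setdiff(all, i2)
    absPerm[, j] <- abs(rowWelchD(log2mat, i1, i2, s0))
  }

  ord <- order(abs(dObs), decreasing = TRUE)
  tau <- abs(dObs)[ord]
  obsCount <- vapply(tau, function(th) sum(abs(dObs) >= th), numeric(1))
  if (estimator == "mean") {
    sortedPerm <- sort(as.vector(absPerm))
    permCount <- (length(sortedPerm) -
                    findInterval(tau - .Machine$double.eps^0.5, sortedPerm)) / nPerm
  } else {
    counts <- vapply(seq_len(nPerm), function(j) {
      sp <- sort(absPerm[, j])
      length(sp) - findInterval(tau - .Machine$double.eps^0.5, sp)
    }, numeric(length(tau)))
    permCount <- apply(matrix(counts, ncol = nPerm), 1, stats::median)
  }
  # pseudo-count floor: a finite permutation set cannot certify a tail
  # probability of zero, so the estimated false count is at least one
  # permuted exceedance over all permutations
  permCount <- pmax(permCount, 1 / nPerm)
  raw <- pmin(permCount / obsCount, 1)
  qmono <- rev(cummin(rev(raw)))   # non-increasing in tau
  qvalue <- numeric(length(dObs))
  qvalue[ord] <- qmono

  res <- data.frame(id = rownames(log2mat), d = dObs, qvalue = qvalue,
                    stringsAsFactors = FALSE)
  for (a in levels)
    res[[sprintf("sig_%g", a)]] <- qvalue <= a
  attr(res, "fdrCurve") <- data.frame(tau = tau, raw_fdr = raw,
                                      fdr = qmono, n_called = obsCount)
  attr(res, "nPermutations") <- nPerm
  rownames(res) <- NULL
  res
}

#' Full TMT enrichment analysis
#'
#' Preprocess (filters + log2), per-protein Welch t with two-sided p,
#' log2 fold enrichment (GFP minus control mean of log2 intensities), and
#' permutation-based FDR calls.
#'
#' @param se a TMT \code{SummarizedExperiment}.
#' @param fdrLevels FDR levels (default 1\% and 5\%).
#' @param nPermutations,s0,seed,estimator passed to
#'   \code{\link{permutationFdr}}.
#' @param minPeptides,zeroPolicy passed to \code{\link{preprocessTmt}}.
#' @return data.frame per retained protein: id, log2fc, t, welch_df,
#'   p_value, d, qvalue, sig_* columns. The FDR curve and permutation count
#'   are attached as attributes.
#' @export
tmtEnrichment <- function(se, fdrLevels = c(0.01, 0.05),
                          nPermutations = 1000L, s0 = 0, seed = 1L,
                          estimator = c("mean", "median"),
                          minPeptides = 2L, zeroPolicy = c("drop", "offset")) {
  prep <- preprocessTmt(se, minPeptides = minPeptides,
                        zeroPolicy = match.arg(zeroPolicy))
  mat <- prep$log2mat
  group <- prep$group
  idx1 <- which(group == levels(group)[1])
  idx2 <- which(group == levels(group)[2])
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)

  fdr <- permutationFdr(mat, group, levels = fdrLevels,
                        nPermutations = nPermutations, s0 = s0, seed = seed,
                        estimator = match.arg(estimator))
  res <- data.frame(id = prep$kept, log2fc = m2 - m1, t = t, welch_df = df,
                    p_value = p, d = fdr$d, qvalue = fdr$qvalue,
                    stringsAsFactors = FALSE)
  for (a in fdrLevels)
    res[[sprintf("sig_%g", a)]] <- fdr[[sprintf("sig_%g", a)]]
  attr(res, "fdrCurve") <- attr(fdr, "fdrCurve")
  attr(res, "nPermutations") <- attr(fdr, "nPermutations")
  attr(res, "filtered") <- prep$filtered
  rownames(res) <- NULL
  res
}

#' Call enriched interactors
#'
#' A protein is an interactor iff its fold enrichment strictly exceeds
#' \code{foldMin} (on the raw scale, i.e. log2fc > log2(foldMin)) AND it is
#' significant at \code{fdrLevel}.
#'
#' @param results output of \code{\link{tmtEnrichment}}.
#' @param foldMin minimum fold enrichment, strict (default 2).
#' @param fdrLevel FDR level whose calls to use (default 0.01).
#' @return Character vector of interactor ids, ordered by decreasing log2fc.
#' @export
callInteractors <- function(results, foldMin = 2, fdrLevel = 0.01) {
  col <- sprintf("sig_%g", fdrLevel)
  if (!col %in% names(results))
    stop("results were not computed at FDR level ", fdrLevel)
  hit <- results$log2fc > log2(foldMin) & results[[col]]
  ids <- results$id[hit]
  ids[order(-results$log2fc[hit], ids)]
}

#' Top enriched proteins by fold
#'
#' The k highest-log2fc proteins among those with fold enrichment at or
#' above \code{foldMin}, stable-sorted by decreasing log2fc then id.
#'
#' @param results output of \code{\link{tmtEnrichment}}.
#' @param foldMin minimum fold enrichment, inclusive (default 3).
#' @param k set size (default 50).
#' @return Character vector of at most k protein ids.
#' @export
topSet <- function(results, foldMin = 3, k = 50L) {
  cand <- results[results$log2fc >= log2(foldMin), , drop = FALSE]
  cand <- cand[order(-cand$log2fc, cand$id), , drop = FALSE]
  utils::head(cand$id, k)
}
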