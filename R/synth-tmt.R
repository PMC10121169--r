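#' Simulate an 8-plex TMT protein-group table
#'
#' Emulates the protein-group reporter-intensity table of a GFP-Trap TMT
#' immunoprecipitation: control and GFP-pulldown conditions with
#' \code{nChannelsPerGroup} reporter channels each. Every protein draws a
#' log-normal baseline; channel measurements add Gaussian noise on the log2
#' scale; spiked true interactors are shifted by \code{interactorLog2fc} in
#' the GFP channels. A configured number of rows is flagged as common
#' contaminants or reverse database hits (disjoint from the spiked set), and
#' unique-peptide counts are assigned so a small fraction of rows fall below
#' the two-peptide filter.
#'
#' @param config a \linkS4class{TmtSimConfig}.
#' @param seed RNG seed (default \code{config@rngSeed}).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"intensity"} (raw scale), \code{rowData} columns
#'   \code{protein_id}, \code{unique_peptides}, \code{is_contaminant},
#'   \code{is_reverse}, \code{is_spiked}, \code{colData} columns
#'   \code{channel} and \code{group} (\code{control}/\code{gfp}), and the
#'   truth (spiked/contaminant/reverse ids) in
#'   \code{metadata(.)$truth}.
#' @examples
#' se <- simulateTmt(tmtSimConfig(nProteins = 100, nTrueInteractors = 5,
#'                                interactorLog2fc = 5))
#' S4Vectors::metadata(se)$truth$spiked
#' @export
simulateTmt <- function(config, seed = config@rngSeed) {
  validObject(config)
  withSeed(seed, {
    n <- config@nProteins
    m <- config@nChannelsPerGroup
    ids <- sprintf("P%05d", seq_len(n))

    special <- sample.int(n, config@nTrueInteractors + config@nContaminants +
                            config@nReverse)
    spiked <- special[seq_len(config@nTrueInteractors)]
    contam <- special[config@nTrueInteractors + seq_len(config@nContaminants)]
    reverse <- special[config@nTrueInteractors + config@nContaminants +
                         seq_len(config@nReverse)]

    baseline <- stats::rnorm(n, config@backgroundLog2Mean, config@proteinLog2Sd)
    log2mat <- baseline +
      matrix(stats::rnorm(n * 2L * m, 0, config@backgroundLog2Sd), n, 2L * m)
    if (length(spiked) > 0)
      log2mat[spiked, m + seq_len(m)] <-
        log2mat[spiked, m + seq_len(m)] + config@interactorLog2fc

    intensity <- 2^log2mat
    if (config@zeroRate > 0) {
      z <- stats::runif(length(intensity)) < config@zeroRate
      intensity[z] <- 0
    }
    colnames(intensity) <- c(paste0("control_", seq_len(m)),
                             paste0("gfp_", seq_len(m)))
    rownames(intensity) <- ids

    peptides <- 1L + stats::rpois(n, config@peptidePoissonMean)
    # spiked interactors are real, well-identified proteins: keep them above
    # the two-peptide filter so the truth-positive set is recoverable
    peptides[spiked] <- pmax(peptides[spiked], 2L)
    rowdat <- S4Vectors::DataFrame(
      protein_id = ids,
      unique_peptides = peptides,
      is_contaminant = seq_len(n) %in% contam,
      is_reverse = seq_len(n) %in% reverse,
      is_spiked = seq_len(n) %in% spiked)
    coldat <- S4Vectors::DataFrame(
      channel = colnames(intensity),
      group = factor(rep(c("control", "gfp"), each = m),
                     levels = c("control", "gfp")))

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = intensity), rowData = rowdat,
      colData = coldat)
    S4Vectors::metadata(se)$truth <- list(
      spiked = ids[sort(spiked)], contaminant = ids[sort(contam)],
      reverse = ids[sort(reverse)], log2fc = config@interactorLog2fc)
    se
  })
}

#' Assemble a TMT SummarizedExperiment from plain tables
#'
#' Builds the container expected by \code{\link{preprocessTmt}} from a
#' delimited protein-group table already read into a data.frame.
#'
#' @param intensities numeric matrix (proteins x channels), raw reporter
#'   intensities; rownames are protein ids.
#' @param group factor/character of length \code{ncol(intensities)} with two
#'   levels, control first.
#' @param uniquePeptides integer vector per protein.
#' @param isContaminant,isReverse logical flags per protein.
#' @return A \code{SummarizedExperiment} shaped like \code{\link{simulateTmt}}
#'   output.
#' @export
tmtTable <- function(intensities, group, uniquePeptides,
                     isContaminant = logical(nrow(intensities)),
                     isReverse = logical(nrow(intensities))) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            length(group) == ncol(intensities),
            length(uniquePeptides) == nrow(intensities))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("channel_", seq_len(ncol(intensities)))
  if (any(intensities < 0)) stop("reporter intensities must be >= 0")
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(protein_id = rownames(intensities),
      unique_peptides = as.integer(uniquePeptides),
      is_contaminant = isContaminant, is_reverse = isReverse),
    colData = S4Vectors::DataFrame(channel = colnames(intensities),
      group = group))
}

#' Read a delimited protein-group table into a TMT SummarizedExperiment
#'
#' Expects columns \code{protein_id}, \code{unique_peptides},
#' \code{is_contaminant}, \code{is_reverse} plus one intensity column per
#' reporter channel, and a design table mapping channel column names to
#' groups.
#'
#' @param path delimited text file (tab or comma separated, autodetected).
#' @param design data.frame with columns \code{channel} and \code{group}, or
#'   path to such a file.
#' @return A \code{SummarizedExperiment}.
#' @export
readTmtTable <- function(path, design) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(design)) {
    dsep <- if (grepl("\t", readLines(design, n = 1L))) "\t" else ","
    design <- utils::read.table(design, header = TRUE, sep = dsep,
                                stringsAsFactors = FALSE)
  }
  need <- c("protein_id", "unique_peptides", "is_contaminant", "is_reverse")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("protein-group table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(c("channel", "group") %in% names(design)))
    stop("design must have columns 'channel' and 'group'")
  missCh <- setdiff(design$channel, names(tab))
  if (length(missCh))
    stop("design channel(s) absent from table: ", paste(missCh, collapse = ", "))
  ints <- as.matrix(tab[, design$channel, drop = FALSE])
  rownames(ints) <- tab$protein_id
  tmtTable(ints, design$group, tab$unique_peptides,
           as.logical(tab$is_contaminant), as.logical(tab$is_reverse))
}
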