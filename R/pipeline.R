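#' Run one assay end to end
#'
#' Orchestrates simulate -> segment -> quantify -> statistics for one assay
#' and writes CSV outputs plus a JSON run manifest into \code{outDir}. All
#' randomness derives from the single run \code{seed}; per-field child seeds
#' are logged in the manifest, so identical configs and seeds reproduce
#' byte-identical tables.
#'
#' Assays:
#' \describe{
#'   \item{\code{phago}}{Simulates (or loads) phagocytosis fields over the
#'     configured genotypes and time grid, quantifies beads/cell per field,
#'     and writes the per-field record table and the per-genotype curve
#'     table (mean +/- SEM).}
#'   \item{\code{flux}}{Simulates reporter fields and writes per-cell
#'     autophagosome/autolysosome counts.}
#'   \item{\code{nfkb}}{Simulates NF-kB fields at the requested nuclear
#'     fractions and writes per-cell localization measures.}
#'   \item{\code{interactome}}{Simulates (or loads) a TMT table and writes
#'     the per-protein enrichment results, interactor list and top set.}
#' }
#'
#' @param assay one of \code{"phago"}, \code{"flux"}, \code{"nfkb"},
#'   \code{"interactome"}.
#' @param outDir output directory (created; existing files are overwritten).
#' @param seed integer run seed.
#' @param imagingConfig an \linkS4class{ImagingSimConfig} (imaging assays).
#' @param segConfig,spotConfig segmentation and spot-detection parameters.
#' @param tmtConfig a \linkS4class{TmtSimConfig} (interactome assay), or
#'   NULL when \code{tmtTablePath} is given.
#' @param tmtTablePath,tmtDesignPath optional delimited protein-group table
#'   and channel design to analyse instead of simulating.
#' @param imagesDir,metaPath optional directory of field TIFFs (written by
#'   \code{\link{writeFieldTiff}}) plus a metadata CSV with columns
#'   \code{file}, \code{genotype}, \code{timepoint} for the phago assay.
#' @param nFields simulated fields per genotype x timepoint (phago) or per
#'   setting (flux/nfkb).
#' @param fluxCounts named list \code{list(ap =, al =)} for the flux assay.
#' @param nuclearFractions numeric vector of f values for the nfkb assay.
#' @param fdrLevels,nPermutations,s0 interactome statistics options.
#' @return The output directory, invisibly; side effect: CSV tables and
#'   \code{manifest.json}.
#' @export
runAssay <- function(assay = c("phago", "flux", "nfkb", "interactome"),
    outDir, seed = 1L,
    imagingConfig = imagingSimConfig(), segConfig = segmentationConfig(),
    spotConfig = NULL, tmtConfig = NULL,
    tmtTablePath = NULL, tmtDesignPath = NULL,
    imagesDir = NULL, metaPath = NULL,
    nFields = 3L, fluxCounts = list(ap = 5L, al = 5L),
    nuclearFractions = c(0.2, 0.8),
    fdrLevels = c(0.01, 0.05), nPermutations = 1000L, s0 = 0) {
  assay <- match.arg(assay)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  inputs <- character(0)

  writeTab <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    counts[[name]] <<- nrow(df)
    p
  }

  if (assay == "phago") {
    if (is.null(spotConfig)) spotConfig <- particleConfig()
    if (!is.null(imagesDir)) {
      meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
      need <- c("file", "genotype", "timepoint")
      miss <- setdiff(need, names(meta))
      if (length(miss))
        stop("metadata CSV lacks required column(s): ",
             paste(miss, collapse = ", "))
      inputs <- file.path(imagesDir, meta$file)
      recs <- lapply(seq_len(nrow(meta)), function(i) {
        f <- readFieldTiff(file.path(imagesDir, meta$file[i]))
        f@metadata$genotype <- meta$genotype[i]
        f@metadata$timepoint <- meta$timepoint[i]
        quantifyPhagocytosis(f, segConfig, spotConfig)$record
      })
      records <- do.call(rbind, recs)
    } else {
      grid <- expand.grid(field = seq_len(nFields),
                          timepoint = imagingConfig@timeGrid,
                          genotype = names(imagingConfig@uptakeRates),
                          stringsAsFactors = FALSE)
      seeds <- deriveSeeds(seed, nrow(grid))
      recs <- lapply(seq_len(nrow(grid)), function(i) {
        sim <- simulateField(imagingConfig, grid$genotype[i],
                             grid$timepoint[i], seed = seeds[i])
        cbind(quantifyPhagocytosis(sim$field, segConfig, spotConfig)$record,
              field = grid$field[i], field_seed = seeds[i])
      })
      records <- do.call(rbind, recs)
    }
    writeTab(records, "uptake_records.csv")
    writeTab(assembleUptakeCurves(records), "uptake_curves.csv")
  } else if (assay == "flux") {
    seeds <- deriveSeeds(seed, nFields)
    res <- lapply(seq_len(nFields), function(i) {
      sim <- simulateReporterField(imagingConfig, fluxCounts$ap,
                                   fluxCounts$al, seed = seeds[i])
      cbind(field = i, quantifyFlux(sim$field, segConfig)$flux)
    })
    writeTab(do.call(rbind, res), "flux_per_cell.csv")
  } else if (assay == "nfkb") {
    grid <- expand.grid(field = seq_len(nFields), f = nuclearFractions)
    seeds <- deriveSeeds(seed, nrow(grid))
    res <- lapply(seq_len(nrow(grid)), function(i) {
      sim <- simulateNfkbField(imagingConfig, grid$f[i], seed = seeds[i])
      cbind(field = grid$field[i], true_fraction = grid$f[i],
            quantifyNfkb(sim$field, segConfig)$localization)
    })
    writeTab(do.call(rbind, res), "nfkb_per_cell.csv")
  } else if (assay == "interactome") {
    se <- if (!is.null(tmtTablePath)) {
      inputs <- c(tmtTablePath, tmtDesignPath)
      readTmtTable(tmtTablePath, tmtDesignPath)
    } else {
      if (is.null(tmtConfig)) tmtConfig <- tmtSimConfig()
      simulateTmt(tmtConfig, seed = seed)
    }
    res <- tmtEnrichment(se, fdrLevels = fdrLevels,
                         nPermutations = nPermutations, s0 = s0, seed = seed)
    writeTab(res, "enrichment_results.csv")
    writeTab(data.frame(id = callInteractors(res, 2, min(fdrLevels))),
             "interactors.csv")
    writeTab(data.frame(id = topSet(res, 3, 50)), "top_set.csv")
  }

  manifest <- list(
    assay = assay, seed = seed,
    package_version = as.character(utils::packageVersion("phagoquant")),
    config_hash = rlang::hash(list(assay = assay, seed = seed,
      imaging = if (assay != "interactome") configDigest(imagingConfig),
      seg = configDigest(segConfig))),
    inputs = if (length(inputs))
      data.frame(file = inputs, md5 = unname(tools::md5sum(inputs)))
      else list(),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

# Slot list of an S4 config, for hashing/logging.
configDigest <- function(cfg) {
  sl <- methods::slotNames(class(cfg))
  stats::setNames(lapply(sl, function(s) methods::slot(cfg, s)), sl)
}

#' Summary plots for a finished run
#'
#' Writes static figures from the CSV outputs of \code{\link{runAssay}}:
#' uptake curves (mean +/- SEM per genotype), a volcano plot with the fold
#' and FDR thresholds highlighted, and per-cell flux counts, for whichever
#' outputs are present; missing stages are skipped with a warning.
#'
#' @param outDir a run directory.
#' @param foldMin,fdrLevel thresholds highlighted in the volcano plot.
#' @return Character vector of figure paths, invisibly.
#' @export
reportRun <- function(outDir, foldMin = 2, fdrLevel = 0.01) {
  made <- character(0)
  curvesPath <- file.path(outDir, "uptake_curves.csv")
  if (file.exists(curvesPath)) {
    cv <- utils::read.csv(curvesPath)
    p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$timepoint,
        y = .data$mean_beads_per_cell, colour = .data$genotype)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_beads_per_cell - .data$sem,
        ymax = .data$mean_beads_per_cell + .data$sem), width = 3) +
      ggplot2::labs(x = "time (min)", y = "beads/cell (mean +/- SEM)") +
      ggplot2::theme_bw()
    f <- file.path(outDir, "uptake_curves.pdf")
    ggplot2::ggsave(f, p, width = 6, height = 4)
    made <- c(made, f)
  } else warning("no uptake curves found; skipping uptake figure")
  enrPath <- file.path(outDir, "enrichment_results.csv")
  if (file.exists(enrPath)) {
    er <- utils::read.csv(enrPath)
    sigCol <- sprintf("sig_%g", fdrLevel)
    er$hit <- er$log2fc > log2(foldMin) & er[[sigCol]]
    p <- ggplot2::ggplot(er, ggplot2::aes(x = .data$log2fc,
        y = -log10(pmax(.data$p_value, 1e-300)), colour = .data$hit)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_vline(xintercept = log2(foldMin), linetype = 2) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                              `TRUE` = "red3")) +
      ggplot2::labs(x = "log2 fold enrichment (GFP - control)",
                    y = "-log10 p") +
      ggplot2::theme_bw()
    if (!any(er$hit))
      p <- p + ggplot2::annotate("text", x = 0, y = 0, vjust = -1,
                                 label = "no significant proteins")
    f <- file.path(outDir, "volcano.pdf")
    ggplot2::ggsave(f, p, width = 6, height = 4)
    made <- c(made, f)
  }
  fluxPath <- file.path(outDir, "flux_per_cell.csv")
  if (file.exists(fluxPath)) {
    fl <- utils::read.csv(fluxPath)
    long <- rbind(
      data.frame(cell = fl$cell_id, kind = "autophagosome",
                 n = fl$n_autophagosome),
      data.frame(cell = fl$cell_id, kind = "autolysosome",
                 n = fl$n_autolysosome))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$kind, y = .data$n)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = "puncta per cell") + ggplot2::theme_bw()
    f <- file.path(outDir, "flux_counts.pdf")
    ggplot2::ggsave(f, p, width = 4, height = 4)
    made <- c(made, f)
  }
  invisible(made)
}
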