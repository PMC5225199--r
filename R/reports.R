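# Pipeline entry points: per-cell analysis, population report, dataset
# simulation. These are the package's equivalents of command-line
# subcommands; all outputs are plain text (CSV / WKT / Newick / JSON) and
# deterministic for a fixed configuration and seed.

#' Analysis run configuration
#'
#' All defaults equal the study's stated values: varicosity ratio 1.8, Sholl
#' step 1 um, diameter-correction target 0.23 um, correlation threshold 0.80,
#' 10000 bootstrap replicates, z threshold 2, alpha 0.05.
#'
#' @param ... overrides of any default.
#' @return named list.
#' @export
runConfig <- function(...) {
  cfg <- list(varicosity_ratio = 1.8, flank_window = 5,
              sholl_step = 1, diameter_target = 0.23,
              correct_diameters = TRUE,
              r_threshold = 0.80, n_boot = 10000, n_null = 1000,
              alpha = 0.05, z_threshold = 2, seed = 1,
              y_split = NULL, gap_threshold = 2)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Analyze one reconstruction end to end
#'
#' Applies the diameter correction (when at least 10 segments are available),
#' detects varicosities, and computes the metric row, per-order profiles
#' under both ordering schemes, the Sholl profile, the laminar profile (when
#' a layer model is available), and the field hulls. When \code{outDir} is
#' given, everything is written as CSV.
#'
#' @param m a \linkS4class{Morphology}, or a path to an SWC file.
#' @param config list from \code{\link{runConfig}}.
#' @param annotationPath sidecar path when \code{m} is an SWC path.
#' @param outDir optional output directory.
#' @return list with \code{metrics}, \code{varicosities},
#'   \code{varicosity_stats}, \code{order_profiles}, \code{sholl},
#'   \code{laminar}, \code{fields}, \code{issues}, \code{correction_shift}.
#' @export
analyzeCell <- function(m, config = runConfig(), annotationPath = NULL,
                        outDir = NULL) {
  if (is.character(m)) m <- readMorphology(m, annotationPath)
  layers <- morphMetadata(m)$layers
  issues <- validateMorphology(m)
  shift <- NA_real_
  if (isTRUE(config$correct_diameters)) {
    cd <- tryCatch(correctDiameters(m, config$diameter_target),
                   error = function(e) NULL)
    if (!is.null(cd)) { m <- cd$morphology; shift <- cd$shift }
  }
  sg <- decomposeSegments(m)
  v <- detectVaricosities(m, ratio = config$varicosity_ratio,
                          flankWindow = config$flank_window,
                          layers = layers, segments = sg)
  ySplit <- config$y_split %||%
    (if (!is.null(layers)) tryCatch(autoSplitDepth(m), error = function(e) NULL))
  metrics <- cellSummary(m, layers = layers, ySplit = ySplit, varicosities = v)
  op <- list(central_shaft = orderProfiles(sg, "central_shaft", v),
             centrifugal = orderProfiles(sg, "centrifugal", v))
  sh <- shollProfile(m, step = config$sholl_step, varicosities = v)
  lam <- if (!is.null(layers)) laminarProfile(m, layers, v)
  fields <- if (!is.null(ySplit))
    tryCatch(fieldMetrics(m, ySplit), error = function(e) NULL)
  out <- list(metrics = metrics, varicosities = v,
              varicosity_stats = varicosityStats(v),
              order_profiles = op, sholl = sh$shells, laminar = lam,
              fields = fields, issues = issues, correction_shift = shift)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) if (!is.null(d))
      utils::write.csv(d, file.path(outDir, f), row.names = FALSE)
    wr(metrics, "metrics.csv")
    wr(v, "varicosities.csv")
    wr(op$central_shaft, "order_profile_central_shaft.csv")
    wr(op$centrifugal, "order_profile_centrifugal.csv")
    wr(sh$shells, "sholl.csv")
    wr(lam, "laminar.csv")
    if (!is.null(fields)) {
      for (fld in c("arboreal", "lobular")) {
        h <- fields[[fld]]
        if (is.null(h)) next
        writeLines(hullWKT(h), file.path(outDir, paste0("hull_", fld, ".wkt")))
      }
    }
  }
  out
}

hullWKT <- function(hull) {
  V <- rbind(hull$vertices, hull$vertices[1L, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", V[, 1], V[, 2]), collapse = ", "))
}

#' Population analysis report
#'
#' Builds the metric matrix (per-cell metrics plus per-layer totals), applies
#' redundancy exclusion, runs PCA with eigenvalue significance, bootstrap
#' coefficient z-scores and excluded-metric regressions, Ward clustering,
#' and the density-volume scaling fit.
#'
#' @param cellResults list of \code{\link{analyzeCell}} results (at least 3).
#' @param config list from \code{\link{runConfig}}.
#' @param outDir optional output directory for CSV / Newick outputs.
#' @return list with \code{matrix}, \code{pca}, \code{significance},
#'   \code{bootstrap}, \code{excluded_regressions}, \code{clustering},
#'   \code{scaling}.
#' @export
analyzePopulation <- function(cellResults, config = runConfig(),
                              outDir = NULL) {
  if (length(cellResults) < 3L) stop("need at least 3 analyzed cells")
  metrics <- do.call(rbind, lapply(cellResults, `[[`, "metrics"))
  laminar <- do.call(rbind, lapply(cellResults, function(cr) {
    lam <- cr$laminar
    if (is.null(lam)) return(NULL)
    stats::setNames(
      as.data.frame(as.list(c(lam$length, lam$n_nodes))),
      c(paste0("length_", lam$layer), paste0("nodes_", lam$layer)))
  }))
  mm <- buildMetricMatrix(metrics, laminar)
  mm <- normalizeAndExclude(mm, rThreshold = config$r_threshold)
  pca <- runPCA(mm)
  sig <- significantComponents(pca, nCells = mm$n_cells,
                               nNull = config$n_null, alpha = config$alpha,
                               seed = config$seed)
  boot <- bootstrapCoefficients(mm, pca, nBoot = config$n_boot,
                                seed = config$seed)
  reg <- regressExcluded(mm, pca)
  clu <- wardClustering(mm, gapThreshold = config$gap_threshold)
  scl <- densityScalingFit(metrics$hull3d_volume, metrics$dendritic_length)
  out <- list(matrix = mm, pca = pca, significance = sig, bootstrap = boot,
              excluded_regressions = reg, clustering = clu, scaling = scl)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(outDir, "metric_table.csv"),
                     row.names = FALSE)
    pcadf <- data.frame(component = paste0("PC", seq_along(pca$eigenvalues)),
                        eigenvalue = pca$eigenvalues,
                        fraction = pca$fractions,
                        significant = sig$significant)
    utils::write.csv(pcadf, file.path(outDir, "pca_components.csv"),
                     row.names = FALSE)
    co <- as.data.frame(pca$components[, 1:min(2, ncol(pca$components))])
    co$metric <- rownames(pca$components)
    nz <- min(2, ncol(boot$z))
    co$z_PC1 <- boot$z[, 1]
    if (nz >= 2) co$z_PC2 <- boot$z[, 2]
    utils::write.csv(co, file.path(outDir, "pca_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(reg, file.path(outDir, "excluded_regressions.csv"),
                     row.names = FALSE)
    writeLinkageNewick(clu$hclust, file.path(outDir, "ward_linkage.nwk"))
  }
  out
}

#' Simulate a synthetic dataset on disk
#'
#' Writes one SWC file, one annotation sidecar and one ground-truth
#' varicosity CSV per cell, plus a JSON manifest recording every seed, so the
#' dataset can be regenerated identically.
#'
#' @param n number of cells.
#' @param seed population seed.
#' @param outDir output directory.
#' @param params generator parameters.
#' @param plantScaling optional planted scaling, see
#'   \code{\link{generatePopulation}}.
#' @return the manifest, invisibly.
#' @export
simulateDataset <- function(n, seed, outDir, params = aiiGeneratorParams(),
                            plantScaling = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cells <- generatePopulation(n, seed, params, plantScaling)
  entries <- lapply(seq_along(cells), function(i) {
    g <- cells[[i]]
    base <- sprintf("cell_%03d", i)
    writeSWC(g$morphology, file.path(outDir, paste0(base, ".swc")))
    writeAnnotation(g$morphology, file.path(outDir, paste0(base, ".json")))
    utils::write.csv(g$truth$varicosities,
                     file.path(outDir, paste0(base, "_varicosities.csv")),
                     row.names = FALSE)
    list(cell = base, seed = g$truth$seed,
         n_varicosities = g$truth$n_varicosities)
  })
  manifest <- list(n = n, seed = seed,
                   planted_scaling = plantScaling, cells = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
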