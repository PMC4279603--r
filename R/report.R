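#' @include sweep.R simulate.R
NULL

#' Run the full intra-plate variability analysis
#'
#' Ties the pipeline together: validate NTCs, fit per-(setting, gene)
#' standard curves, build (or reuse) the seeded combination plan over the
#' sample-well pools, evaluate it into GMO-percentage populations for every
#' (setting, k) cell, and compute the statistics grid. Everything
#' downstream of the seed is deterministic: the same experiment, seed and
#' parameters reproduce the identical report, and re-running from an
#' exported plan ([exportPlan()]) is bit-identical.
#'
#' @param experiment a [PlateExperiment-class]
#' @param seed integer seed for the combination plan (ignored when `plan`
#'   is supplied)
#' @param plan optional pre-built or re-imported [ResamplingPlan-class]
#' @param ks replicate settings, default `2:16`
#' @param nCombinations combinations per k, default 5000
#' @param nClasses,coverageTarget,chiDf histogram/statistics parameters,
#'   see [replicateSweep()]
#' @param rsdThreshold RSD target (%) for [minReplicatesForRsd()]
#' @param config a [conversionConfig()]; defaults to the layout's
#'   conversion factor with the `"exclude"` missing-Cq policy
#' @param ntcMinCq NTC validation cut, see [validateNtc()]
#' @return a list of class `PlateReport`: `summary` (the grid table),
#'   `curves` (curve diagnostics table), `sweep` ([SweepGrid-class]),
#'   `plan`, `minReplicates`, `parameters`, `log` (character)
#' @examples
#' pe <- simulatePlate(simulationConfig(seed = 7))
#' rep <- runAnalysis(pe, seed = 7, ks = c(2, 8), nCombinations = 200)
#' head(rep$summary)
#' rep$minReplicates
#' @export
runAnalysis <- function(experiment, seed = 1, plan = NULL, ks = 2:16,
                        nCombinations = 5000, nClasses = 20,
                        coverageTarget = 0.95, rsdThreshold = 15,
                        config = NULL, chiDf = NULL, ntcMinCq = 40) {
  stopifnot(is(experiment, "PlateExperiment"))
  if (is.null(config))
    config <- conversionConfig(factor = conversionFactor(experiment))
  validateNtc(experiment, minCq = ntcMinCq)

  pools <- samplePools(experiment, config)
  if (is.null(plan))
    plan <- buildPlan(lengths(pools), ks = ks,
                      nCombinations = nCombinations, seed = seed)
  curves <- fitCurves(experiment)
  sweep <- replicateSweep(experiment, plan, nClasses = nClasses,
                          coverageTarget = coverageTarget, config = config,
                          chiDf = chiDf)
  minK <- minReplicatesForRsd(sweep, rsdThreshold)

  log <- c(
    sprintf("qpcrPlateVar %s", as.character(packageVersion("qpcrPlateVar"))),
    sprintf("settings: %s", paste(settingIds(experiment), collapse = ", ")),
    sprintf("plan: seed %d, %d combinations, k in {%s}", plan@seed,
            plan@nCombinations, paste(plan@ks, collapse = ", ")),
    sprintf("pools: %s",
            paste(sprintf("%s=%d", names(pools), lengths(pools)),
                  collapse = " ")),
    sprintf("conversion factor %g, missing-Cq policy '%s'",
            config$factor, config$missingCqPolicy),
    sprintf("nominal GMO %g%%, %d classes, coverage target %g%%, RSD target %g%%",
            nominalGmoPercent(experiment), as.integer(nClasses),
            100 * coverageTarget, rsdThreshold),
    sprintf("min replicates (2xk) for RSD <= %g%% in all settings: %s",
            rsdThreshold, ifelse(is.na(minK), "not reached", minK)),
    sprintf("cq digest: %s",
            paste(format(colSums(cqValues(experiment), na.rm = TRUE),
                         digits = 12), collapse = " ")))

  structure(list(
    summary = sweepSummary(sweep),
    curves = curveTable(curves),
    sweep = sweep,
    plan = plan,
    minReplicates = minK,
    parameters = list(
      ks = plan@ks, nCombinations = plan@nCombinations, seed = plan@seed,
      nClasses = as.integer(nClasses), coverageTarget = coverageTarget,
      rsdThreshold = rsdThreshold, config = config),
    log = log), class = "PlateReport")
}

#' Simulate a plate and analyse it in one call
#'
#' @param simConfig a [simulationConfig()]
#' @param ... passed on to [runAnalysis()] (`seed` defaults to the
#'   simulation seed)
#' @return a `PlateReport`, as from [runAnalysis()]; the simulated
#'   experiment is attached as `$experiment`
#' @export
runSimulation <- function(simConfig, ...) {
  experiment <- simulatePlate(simConfig)
  args <- list(...)
  if (is.null(args$seed)) args$seed <- simConfig$seed
  rep <- do.call(runAnalysis, c(list(experiment), args))
  rep$experiment <- experiment
  rep
}

#' Multi-seed simulation batch
#'
#' Repeats [runSimulation()] over a vector of seeds (each seed drives both
#' the plate generation and the combination plan) and aggregates the grid:
#' the per-(setting, k) mean over seeds of RSD, skewness and relative
#' deviation.
#'
#' @param simConfig a [simulationConfig()]; its `seed` field is overridden
#'   per run
#' @param seeds integer vector of seeds
#' @param ... passed on to [runAnalysis()]
#' @return list with `perSeed` (named list of summary tables) and
#'   `aggregate` (data.frame over (setting, k))
#' @export
runSimulationBatch <- function(simConfig, seeds, ...) {
  perSeed <- list()
  for (s in seeds) {
    cfg <- simConfig
    cfg$seed <- as.integer(s)
    perSeed[[as.character(s)]] <- runSimulation(cfg, ...)$summary
  }
  all <- do.call(rbind, perSeed)
  agg <- stats::aggregate(all[, c("rsd", "skewness", "rel_abs_deviation")],
                   by = list(setting = all$setting, k = all$k),
                   FUN = mean, na.rm = TRUE)
  agg <- agg[order(agg$setting, agg$k), ]
  rownames(agg) <- NULL
  list(perSeed = perSeed, aggregate = agg)
}

#' Frequency-distribution plot with the statistics panel
#'
#' The canonical per-cell report figure: one column per class at its
#' upper-limit label, the included (>= coverage cut-off) classes
#' highlighted, the count threshold as a dashed horizontal line, the
#' nominal value as a diamond, and the matching Gaussian curve overlaid.
#' The caption carries the population statistics (left) and the cut-off
#' summary (right).
#'
#' @param dist a [FrequencyDistribution-class]
#' @param cutoff the matching [CutoffSummary-class] (optional)
#' @param nominal nominal GMO percent (optional, drawn as a diamond)
#' @param stats optional [populationStats()] result for the Gaussian
#'   overlay and the caption
#' @param skewness,chiP optional panel values (chiP in percent)
#' @param title plot title
#' @return a ggplot object
#' @export
plotFrequencyDistribution <- function(dist, cutoff = NULL, nominal = NULL,
                                      stats = NULL, skewness = NULL,
                                      chiP = NULL, title = NULL) {
  stopifnot(is(dist, "FrequencyDistribution"))
  U <- upperLimits(dist)
  w <- U[2L] - U[1L]
  df <- data.frame(upper = U, count = classCounts(dist), included = FALSE)
  if (!is.null(cutoff)) df$included[cutoff@includedClasses] <- TRUE

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$upper, y = .data$count,
                                        fill = .data$included)) +
    ggplot2::geom_col(width = w * 0.9, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "forestgreen")) +
    ggplot2::labs(x = "GMO content, class upper limit [%]",
                  y = "number of values", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_hline(yintercept = cutoff@countThreshold,
                                 linetype = "dashed")
  if (!is.null(stats)) {
    gx <- seq(min(classEdges(dist)), max(classEdges(dist)), length.out = 200)
    gauss <- data.frame(
      x = gx,
      y = dnorm(gx, stats$mean, stats$sdPopulation) * dist@nTotal * w)
    p <- p + ggplot2::geom_line(
      data = gauss, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, colour = "brown")
  }
  if (!is.null(nominal))
    p <- p + ggplot2::annotate("point", x = nominal, y = 0, shape = 18,
                               size = 4, colour = "blue")
  cap <- character()
  if (!is.null(stats))
    cap <- c(cap, sprintf(
      "mean %.4g%%  StdDevP %.3g%%  rel.StdDevP %.1f%%  rel.|Dev| %.1f%%",
      stats$mean, stats$sdPopulation, stats$rsd, stats$relAbsDeviation))
  if (!is.null(skewness) && !is.na(skewness))
    cap <- c(cap, sprintf("SkewnessP %.3f", skewness))
  if (!is.null(chiP) && !is.na(chiP))
    cap <- c(cap, sprintf("ChiSq Norm.Distr. %.1f%%", chiP))
  if (!is.null(cutoff))
    cap <- c(cap, sprintf("middle class %.4g%% +/- %.4g%% (%.1f%% of values)",
                          cutoff@middleClass, cutoff@halfRange,
                          100 * cutoff@achievedCoverage))
  if (length(cap)) p <- p + ggplot2::labs(caption = paste(cap, collapse = "\n"))
  p
}

#' RSD against replicate number, per setting
#'
#' The replicate-design view: one line per baseline/threshold setting, RSD
#' on the ordinate, k on the abscissa, with the RSD target as a horizontal
#' line and the smallest k meeting the target in all settings marked by a
#' diamond.
#'
#' @param grid a [SweepGrid-class] or summary data.frame
#' @param rsdThreshold RSD target to draw (percent; default 15)
#' @return a ggplot object
#' @export
plotRsdSweep <- function(grid, rsdThreshold = 15) {
  summary <- if (is(grid, "SweepGrid")) grid@summary else grid
  minK <- minReplicatesForRsd(summary, rsdThreshold)
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$k, y = .data$rsd,
                                             colour = .data$setting)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = rsdThreshold, linetype = "dotted") +
    ggplot2::labs(x = "replicates per isolation (2x k)",
                  y = "rel. StdDevP [%]", colour = "setting") +
    ggplot2::theme_minimal()
  if (!is.na(minK))
    p <- p + ggplot2::annotate("point", x = minK, y = rsdThreshold,
                               shape = 18, size = 4, colour = "darkgreen")
  p
}

#' Write a report bundle to disk
#'
#' Writes `summary.csv`, `curves.csv`, the plan export (`plan.tsv`),
#' `log.txt`, the RSD sweep figure and one annotated histogram per
#' (setting, k) cell under `dir`.
#'
#' @param report a `PlateReport` from [runAnalysis()]
#' @param dir output directory (created if needed)
#' @param figures write figure files too (default TRUE)
#' @return `dir`, invisibly
#' @export
writeReportBundle <- function(report, dir, figures = TRUE) {
  stopifnot(inherits(report, "PlateReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv2 <- function(x, f)
    write.table(x, f, sep = ",", row.names = FALSE, quote = FALSE)
  write.csv2(report$summary, file.path(dir, "summary.csv"))
  write.csv2(report$curves, file.path(dir, "curves.csv"))
  exportPlan(report$plan, file.path(dir, "plan.tsv"))
  writeLines(report$log, file.path(dir, "log.txt"))
  if (figures) {
    figdir <- file.path(dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    ggplot2::ggsave(file.path(figdir, "rsd_sweep.png"),
                    plotRsdSweep(report$sweep,
                                 report$parameters$rsdThreshold),
                    width = 7, height = 5, dpi = 120)
    sw <- report$sweep
    for (key in names(sw@distributions)) {
      row <- report$summary[paste(report$summary$setting,
                                  report$summary$k, sep = "|") == key, ]
      fn <- file.path(figdir, paste0("hist_", gsub("\\|", "_k", key), ".png"))
      ggplot2::ggsave(fn, plotFrequencyDistribution(
        sw@distributions[[key]], cutoff = sw@cutoffs[[key]],
        nominal = sw@nominal,
        stats = list(mean = row$mean, sdPopulation = row$sd, rsd = row$rsd,
                     relAbsDeviation = row$rel_abs_deviation),
        skewness = row$skewness, chiP = row$chi_p,
        title = sprintf("%s, 2x%d replicates", row$setting, row$k)),
        width = 6, height = 4.5, dpi = 120)
    }
  }
  invisible(dir)
}
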