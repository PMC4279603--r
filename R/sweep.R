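#' @include resampling.R distribution-stats.R
NULL

#' Full replicate-number x setting sweep
#'
#' Evaluates the shared resampling plan under every baseline/threshold
#' setting and computes the complete statistics panel for every (setting,
#' k) cell: frequency distribution, population mean/SD/RSD, relative
#' absolute deviation from the nominal value, empirical skewness, the
#' simplified chi-square normality probability, and the coverage cut-off
#' summary. The grid has `|settings| x |ks|` cells.
#'
#' At k equal to the pool size only one combination of wells exists, so
#' the population collapses to a single repeated value; skewness and the
#' chi-square test are undefined there and reported as `NA` (the RSD is 0).
#' A chi-square failure from an empty expected class is likewise reported
#' as `NA` rather than aborting the sweep.
#'
#' In the summary table, `rsd`, `rel_abs_deviation`, `achieved_coverage`
#' and `chi_p` are percentages; `mean`, `sd`, `middle_class` and
#' `half_range` are GMO percent.
#'
#' @param experiment a [PlateExperiment-class]
#' @param plan a [ResamplingPlan-class] built for the experiment's pools
#' @param nClasses frequency classes per histogram (default 20)
#' @param coverageTarget cut-off coverage target (default 0.95)
#' @param config a [conversionConfig()]; defaults to the layout's factor
#' @param nominal nominal GMO percent; defaults to the layout's value
#' @param chiDf chi-square degrees of freedom; default `nClasses - 3`
#' @return a [SweepGrid-class]
#' @export
replicateSweep <- function(experiment, plan, nClasses = 20,
                           coverageTarget = 0.95, config = NULL,
                           nominal = NULL, chiDf = NULL) {
  stopifnot(is(experiment, "PlateExperiment"), is(plan, "ResamplingPlan"))
  if (is.null(nominal)) nominal <- nominalGmoPercent(experiment)
  if (is.null(config))
    config <- conversionConfig(factor = conversionFactor(experiment))
  pops <- evaluatePlan(plan, experiment, config = config)

  rows <- vector("list", length(pops))
  dists <- cuts <- list()
  for (i in seq_along(pops)) {
    pop <- pops[[i]]
    key <- names(pops)[i]
    vals <- pop@values
    st <- populationStats(vals, nominal)
    dist <- withCallingHandlers(
      binValues(vals, nClasses),
      warning = function(w) invokeRestart("muffleWarning"))
    co <- cutoffSummary(dist, coverageTarget)
    skew <- tryCatch(empiricalSkewness(vals), error = function(e) NA_real_)
    chiP <- tryCatch(
      chiSquareNormality(dist, st$mean, st$sdPopulation, df = chiDf)$p,
      error = function(e) NA_real_)
    dists[[key]] <- dist
    cuts[[key]] <- co
    rows[[i]] <- data.frame(
      setting = pop@setting, k = pop@k,
      mean = st$mean, sd = st$sdPopulation, rsd = st$rsd,
      skewness = skew, chi_p = 100 * chiP,
      rel_abs_deviation = st$relAbsDeviation,
      middle_class = co@middleClass, half_range = co@halfRange,
      achieved_coverage = 100 * co@achievedCoverage)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  new("SweepGrid", summary = summary, populations = pops,
      distributions = dists, cutoffs = cuts,
      nClasses = as.integer(nClasses),
      coverageTarget = coverageTarget, nominal = nominal)
}

#' Smallest replicate number reaching an RSD target in every setting
#'
#' Scans the sweep grid for the smallest k whose relative standard
#' deviation is at or below `rsdThreshold` under ALL baseline/threshold
#' settings — the replicate number a laboratory would have to run to keep
#' the intra-plate spread inside the target regardless of how baseline and
#' threshold are set. Returns `NA` if no k in the grid qualifies.
#'
#' The default threshold of 15 percent sits well below the 25 percent
#' relative repeatability standard deviation that EU GMO regulation
#' requires, leaving headroom for between-run variation.
#'
#' @param grid a [SweepGrid-class] or its summary data.frame
#' @param rsdThreshold maximum acceptable RSD, percent (default 15)
#' @return the smallest qualifying k (integer), or `NA_integer_`
#' @export
minReplicatesForRsd <- function(grid, rsdThreshold = 15) {
  summary <- if (is(grid, "SweepGrid")) grid@summary else grid
  stopifnot(is.data.frame(summary), all(c("setting", "k", "rsd") %in%
                                          names(summary)))
  worst <- vapply(split(summary$rsd, summary$k), function(r) {
    if (anyNA(r)) Inf else max(r)
  }, numeric(1))
  ks <- as.integer(names(worst))
  ok <- ks[worst <= rsdThreshold]
  if (length(ok)) min(ok) else NA_integer_
}
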