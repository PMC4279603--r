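#' @include AllClasses.R
NULL

#' Accessors for qpcrPlateVar classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `plateLayout()` returns the [PlateLayout] of a [PlateExperiment];
#' `cqValues()` the wells x settings Cq matrix; `settingIds()` the
#' baseline/threshold setting ids; `wellInfo()` the per-well role table;
#' `nominalGmoPercent()` and `conversionFactor()` the layout scalars;
#' `populationValues()` the raw values of a [GmoPopulation];
#' `classCounts()`, `classEdges()` and `upperLimits()` the pieces of a
#' [FrequencyDistribution]; `sweepSummary()` the summary table of a
#' [SweepGrid].
#'
#' @param x an object of the documented class
#' @return see the individual descriptions above
#' @name accessors
#' @aliases plateLayout cqValues settingIds wellInfo nominalGmoPercent
#'   conversionFactor populationValues classCounts classEdges upperLimits
#'   sweepSummary
NULL

#' @rdname accessors
#' @export
setGeneric("plateLayout", function(x) standardGeneric("plateLayout"))

#' @rdname accessors
#' @export
setMethod("plateLayout", "PlateExperiment", function(x) metadata(x)$layout)

#' @rdname accessors
#' @export
setGeneric("cqValues", function(x) standardGeneric("cqValues"))

#' @rdname accessors
#' @export
setMethod("cqValues", "PlateExperiment", function(x) assay(x, "cq"))

#' @rdname accessors
#' @export
setGeneric("settingIds", function(x) standardGeneric("settingIds"))

#' @rdname accessors
#' @export
setMethod("settingIds", "PlateExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("wellInfo", function(x) standardGeneric("wellInfo"))

#' @rdname accessors
#' @export
setMethod("wellInfo", "PlateExperiment", function(x) {
  df <- as.data.frame(rowData(x))
  df$position <- rownames(x)
  df[, c("position", "gene", "task", "isolation", "knownCopies")]
})

#' @rdname accessors
#' @export
setGeneric("nominalGmoPercent", function(x) standardGeneric("nominalGmoPercent"))

#' @rdname accessors
#' @export
setMethod("nominalGmoPercent", "PlateLayout", function(x) x@nominalGmoPercent)

#' @rdname accessors
#' @export
setMethod("nominalGmoPercent", "PlateExperiment",
          function(x) plateLayout(x)@nominalGmoPercent)

#' @rdname accessors
#' @export
setGeneric("conversionFactor", function(x) standardGeneric("conversionFactor"))

#' @rdname accessors
#' @export
setMethod("conversionFactor", "PlateLayout", function(x) x@conversionFactor)

#' @rdname accessors
#' @export
setMethod("conversionFactor", "PlateExperiment",
          function(x) plateLayout(x)@conversionFactor)

#' @rdname accessors
#' @export
setGeneric("populationValues", function(x) standardGeneric("populationValues"))

#' @rdname accessors
#' @export
setMethod("populationValues", "GmoPopulation", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setMethod("classCounts", "FrequencyDistribution", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("classEdges", function(x) standardGeneric("classEdges"))

#' @rdname accessors
#' @export
setMethod("classEdges", "FrequencyDistribution", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("upperLimits", function(x) standardGeneric("upperLimits"))

#' @rdname accessors
#' @export
setMethod("upperLimits", "FrequencyDistribution", function(x) x@edges[-1L])

#' @rdname accessors
#' @export
setGeneric("sweepSummary", function(x) standardGeneric("sweepSummary"))

#' @rdname accessors
#' @export
setMethod("sweepSummary", "SweepGrid", function(x) x@summary)

## ---- show methods -------------------------------------------------------

setMethod("show", "PlateLayout", function(object) {
  cat("PlateLayout\n")
  for (g in .GENES) {
    cat(sprintf("  %-9s standards: %d  ntc: %d  samples: %d (isolation 1: %d, 2: %d)\n",
      g,
      sum(object@standards$gene == g),
      sum(object@ntc$gene == g),
      sum(object@samples$gene == g),
      sum(object@samples$gene == g & object@samples$isolation == 1L),
      sum(object@samples$gene == g & object@samples$isolation == 2L)))
  }
  cat(sprintf("  nominal GMO: %g%%  conversion factor: %g\n",
              object@nominalGmoPercent, object@conversionFactor))
})

setMethod("show", "PlateExperiment", function(object) {
  cat(sprintf("PlateExperiment: %d wells x %d baseline/threshold setting(s)\n",
              nrow(object), ncol(object)))
  cat("  settings:", paste(colnames(object), collapse = ", "), "\n")
  nUndet <- colSums(is.na(assay(object, "cq")))
  cat("  undetermined Cq per setting:", paste(nUndet, collapse = ", "), "\n")
  show(plateLayout(object))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve [%s / %s]: Cq = %.4f * log10(copies) + %.4f  (R2 = %.4f, n = %d, eff = %.1f%%)\n",
    object@gene, object@setting, object@slope, object@intercept,
    object@rSquared, object@nPoints,
    100 * (10^(-1 / object@slope) - 1)))
})

setMethod("show", "ResamplingPlan", function(object) {
  cat(sprintf("ResamplingPlan: %d combinations, k in {%s}, seed %d\n",
              object@nCombinations,
              paste(object@ks, collapse = ", "), object@seed))
  cat("  pool sizes:",
      paste(sprintf("%s=%d", names(object@poolSizes), object@poolSizes),
            collapse = "  "), "\n")
})

setMethod("show", "GmoPopulation", function(object) {
  cat(sprintf("GmoPopulation [%s, 2x%d]: %d values, mean %.4g%%\n",
              object@setting, object@k, length(object@values),
              mean(object@values)))
})

setMethod("show", "FrequencyDistribution", function(object) {
  cat(sprintf("FrequencyDistribution: %d classes, width %.4g, n = %d\n",
              length(object@counts), diff(object@edges[1:2]), object@nTotal))
})

setMethod("show", "CutoffSummary", function(object) {
  cat(sprintf(
    "CutoffSummary: >= %.0f%% target; threshold %d; middle class %.4g%% +/- %.4g%% (achieved %.1f%%)\n",
    100 * object@coverageTarget, object@countThreshold,
    object@middleClass, object@halfRange, 100 * object@achievedCoverage))
})

setMethod("show", "SweepGrid", function(object) {
  cat(sprintf("SweepGrid: %d settings x %d replicate settings (%d cells)\n",
              length(unique(object@summary$setting)),
              length(unique(object@summary$k)),
              nrow(object@summary)))
  cat(sprintf("  nominal %g%%, %d classes, coverage target %.0f%%\n",
              object@nominal, object@nClasses, 100 * object@coverageTarget))
})
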