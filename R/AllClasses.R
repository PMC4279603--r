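#' @include qpcrPlateVar-package.R
NULL

.GENES <- c("transgene", "reference")
.TASKS <- c("sample", "standard", "ntc")

## 96-well alphanumeric labels, row-major: A1..A12, B1..B12, ..., H12
.PLATE_ROWS <- LETTERS[1:8]
.PLATE_COLS <- 1:12

.allWellLabels <- function() {
  as.vector(t(outer(.PLATE_ROWS, .PLATE_COLS, paste0)))
}

.isWellLabel <- function(x) {
  grepl("^[A-H]([1-9]|1[0-2])$", x)
}

## canonical plate ordering: row letter, then column number
.orderWells <- function(positions) {
  row <- substr(positions, 1, 1)
  col <- as.integer(substring(positions, 2))
  positions[order(row, col)]
}

#' PlateLayout: the roles of the wells on one 96-well plate
#'
#' A `PlateLayout` records, for each gene (transgene and reference), which
#' wells carry standards (with their known copy numbers), which well is the
#' no-template control (NTC), and which wells carry sample replicates,
#' including which of the two DNA isolations each sample well belongs to.
#' It also carries the certified nominal GMO content of the material on the
#' plate and the multiplicative conversion factor (zygosity / copy-ratio to
#' mass-fraction approximation) applied when copy ratios are turned into
#' GMO percentages.
#'
#' The layout is always supplied explicitly (from a config file or a
#' constructor), never inferred from a Cq export: instrument exports do not
#' reliably encode isolation membership.
#'
#' @slot standards data.frame with columns `gene`, `position`, `copies`.
#' @slot ntc data.frame with columns `gene`, `position`.
#' @slot samples data.frame with columns `gene`, `position`, `isolation`
#'   (integer 1 or 2).
#' @slot nominalGmoPercent certified GM content of the material, in percent.
#' @slot conversionFactor positive multiplicative factor applied to the
#'   copy ratio (default 1).
#'
#' @seealso [defaultPlateLayout()], [readPlateLayout()]
#' @export
setClass("PlateLayout",
  representation(
    standards = "data.frame",
    ntc = "data.frame",
    samples = "data.frame",
    nominalGmoPercent = "numeric",
    conversionFactor = "numeric"
  )
)

setValidity("PlateLayout", function(object) {
  msg <- character()
  std <- object@standards
  ntc <- object@ntc
  smp <- object@samples
  if (!all(c("gene", "position", "copies") %in% names(std)))
    msg <- c(msg, "standards must have columns gene, position, copies")
  if (!all(c("gene", "position") %in% names(ntc)))
    msg <- c(msg, "ntc must have columns gene, position")
  if (!all(c("gene", "position", "isolation") %in% names(smp)))
    msg <- c(msg, "samples must have columns gene, position, isolation")
  if (length(msg)) return(msg)

  pos <- c(std$position, ntc$position, smp$position)
  if (!all(.isWellLabel(pos)))
    msg <- c(msg, paste0("invalid well label(s): ",
                         paste(pos[!.isWellLabel(pos)], collapse = ", ")))
  if (anyDuplicated(pos))
    msg <- c(msg, paste0("duplicated well position(s) in layout: ",
                         paste(unique(pos[duplicated(pos)]), collapse = ", ")))
  genes <- unique(c(std$gene, ntc$gene, smp$gene))
  if (!all(genes %in% .GENES))
    msg <- c(msg, "gene must be 'transgene' or 'reference'")
  for (g in .GENES) {
    nwells <- sum(std$gene == g) + sum(ntc$gene == g) + sum(smp$gene == g)
    if (nwells > 48)
      msg <- c(msg, sprintf("gene '%s' occupies %d wells (max 48 per gene)",
                            g, nwells))
    iso <- smp$isolation[smp$gene == g]
    if (!all(iso %in% c(1L, 2L)))
      msg <- c(msg, sprintf("gene '%s': isolation must be 1 or 2", g))
    if (!all(c(1L, 2L) %in% iso))
      msg <- c(msg, sprintf("gene '%s': both isolations must be non-empty", g))
  }
  if (any(std$copies <= 0))
    msg <- c(msg, "standard copies must be positive")
  if (length(object@nominalGmoPercent) != 1L || object@nominalGmoPercent <= 0)
    msg <- c(msg, "nominalGmoPercent must be a single positive number")
  if (length(object@conversionFactor) != 1L || object@conversionFactor <= 0)
    msg <- c(msg, "conversionFactor must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PlateExperiment: one plate exported under several baseline/threshold settings
#'
#' A `PlateExperiment` extends [SummarizedExperiment::SummarizedExperiment]:
#' rows are wells (named by their alphanumeric plate label), columns are
#' baseline/threshold settings, and the single `"cq"` assay holds the Cq
#' value of each well under each setting (`NA` = undetermined, i.e. no
#' amplification signal crossed the threshold). `rowData` carries the well
#' roles (`gene`, `task`, `isolation`, `knownCopies`) and the
#' [PlateLayout] lives in `metadata(x)$layout`.
#'
#' All settings refer to the same physical wells; only the Cq values differ
#' between columns. This is what makes cross-setting comparisons with a
#' shared resampling plan meaningful.
#'
#' @seealso [assembleExperiment()], [simulatePlate()]
#' @export
setClass("PlateExperiment", contains = "SummarizedExperiment")

setValidity("PlateExperiment", function(object) {
  msg <- character()
  if (!"cq" %in% assayNames(object))
    msg <- c(msg, "assay 'cq' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "wells (rownames) must be unique and non-NULL")
  need <- c("gene", "task", "isolation", "knownCopies")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (is.null(metadata(object)$layout) ||
      !is(metadata(object)$layout, "PlateLayout"))
    msg <- c(msg, "metadata(x)$layout must be a PlateLayout")
  if (length(msg)) msg else TRUE
})

#' StandardCurve: linear calibration of Cq against log10 copy number
#'
#' Ordinary least-squares fit of Cq on log10(copies) over the standard wells
#' of one gene under one baseline/threshold setting. The slope is in cycles
#' per decade (expected negative; -3.32 corresponds to perfect per-cycle
#' doubling), the intercept is the Cq extrapolated for a single copy.
#'
#' @slot gene gene the curve belongs to ("transgene" or "reference").
#' @slot setting the baseline/threshold setting id.
#' @slot slope cycles per decade of template.
#' @slot intercept Cq at 1 copy.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nPoints number of calibration points used.
#'
#' @seealso [fitStandardCurve()], [cqToCopies()], [amplificationEfficiency()]
#' @export
setClass("StandardCurve",
  representation(
    gene = "character",
    setting = "character",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    nPoints = "integer"
  )
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || object@slope == 0)
    msg <- c(msg, "slope must be a single non-zero number")
  if (length(object@intercept) != 1L)
    msg <- c(msg, "intercept must be a single number")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ResamplingPlan: seeded well-index combinations, shared across settings
#'
#' The plan fixes, before any Cq value is looked at, which wells enter each
#' of the random combinations. For every replicate setting k it stores
#' `nCombinations` index tuples; each tuple selects k wells from each of the
#' four pools (transgene isolation 1, transgene isolation 2, reference
#' isolation 1, reference isolation 2), without replacement within a pool.
#' Combinations are drawn independently of each other, so the same tuple may
#' recur among the `nCombinations` draws.
#'
#' The plan is a pure function of `(seed, poolSizes, ks, nCombinations)`:
#' the same arguments always reproduce the identical plan, and the identical
#' plan is applied to every baseline/threshold setting, which is what makes
#' per-setting results directly comparable. The per-k random substream is
#' derived from the root seed as `(seed + 10007 * k) mod (2^31 - 1)`, so a
#' single k can be regenerated without replaying the others.
#'
#' @slot seed integer root seed.
#' @slot nCombinations number of combinations per replicate setting.
#' @slot ks integer vector of replicate settings (k wells per isolation).
#' @slot poolSizes named integer vector (`transgene.1`, `transgene.2`,
#'   `reference.1`, `reference.2`).
#' @slot combos per k (list named by k): list of four integer matrices
#'   (`nCombinations` x k) of pool-local well indices, in pool order
#'   transgene.1, transgene.2, reference.1, reference.2.
#'
#' @seealso [buildPlan()], [evaluatePlan()], [exportPlan()]
#' @export
setClass("ResamplingPlan",
  representation(
    seed = "integer",
    nCombinations = "integer",
    ks = "integer",
    poolSizes = "integer",
    combos = "list"
  )
)

setValidity("ResamplingPlan", function(object) {
  msg <- character()
  pools <- c("transgene.1", "transgene.2", "reference.1", "reference.2")
  if (!identical(names(object@poolSizes), pools))
    msg <- c(msg, "poolSizes must be named transgene.1, transgene.2, reference.1, reference.2")
  if (!identical(names(object@combos), as.character(object@ks)))
    msg <- c(msg, "combos must be named by ks")
  for (k in object@ks) {
    cs <- object@combos[[as.character(k)]]
    if (!identical(names(cs), pools)) {
      msg <- c(msg, sprintf("k=%d: pool matrices misnamed", k))
      next
    }
    for (p in pools) {
      m <- cs[[p]]
      if (!is.matrix(m) || nrow(m) != object@nCombinations || ncol(m) != k)
        msg <- c(msg, sprintf("k=%d pool %s: expected %d x %d index matrix",
                              k, p, object@nCombinations, k))
      else if (any(m < 1L) || any(m > object@poolSizes[[p]]))
        msg <- c(msg, sprintf("k=%d pool %s: index out of pool range", k, p))
      else if (any(apply(m, 1L, anyDuplicated) > 0L))
        msg <- c(msg, sprintf("k=%d pool %s: duplicated index within a tuple", k, p))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GmoPopulation: the GMO percentages of one (setting, k) cell
#'
#' Holds the `nCombinations` GMO-percentage values obtained by evaluating
#' every combination of a [ResamplingPlan] at one replicate setting k under
#' one baseline/threshold setting. The values are treated downstream as a
#' population (not a sample): summary statistics use the divisor n.
#'
#' @slot setting baseline/threshold setting id.
#' @slot k replicates per isolation (2k wells per gene enter each value).
#' @slot values numeric GMO percentages.
#' @export
setClass("GmoPopulation",
  representation(setting = "character", k = "integer", values = "numeric")
)

#' FrequencyDistribution: equal-width binning of a GMO-percentage population
#'
#' Classes are equal-width and span the population range; each class is
#' labelled by its upper limit, matching the histogram convention used for
#' plate reports. Intervals are half-open `(lower, upper]`, with the lower
#' edge of the first class closed so the minimum is counted.
#'
#' @slot edges ascending numeric class edges (length nClasses + 1), percent.
#' @slot counts integer occupancy per class.
#' @slot nTotal population size (= `sum(counts)`).
#' @seealso [binValues()], [cutoffSummary()], [chiSquareNormality()]
#' @export
setClass("FrequencyDistribution",
  representation(edges = "numeric", counts = "integer", nTotal = "integer")
)

setValidity("FrequencyDistribution", function(object) {
  msg <- character()
  if (length(object@edges) != length(object@counts) + 1L)
    msg <- c(msg, "edges must have length(counts) + 1")
  if (is.unsorted(object@edges, strictly = TRUE))
    msg <- c(msg, "edges must be strictly ascending")
  if (sum(object@counts) != object@nTotal)
    msg <- c(msg, "counts must sum to nTotal")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CutoffSummary: the classes that jointly hold >= 95 percent of values
#'
#' Summarises a [FrequencyDistribution] by the largest count threshold c
#' such that the classes with occupancy >= c together contain at least the
#' target share (default 95 percent) of the population. The summary reports
#' the included classes' upper-limit range as a midpoint ("middle class")
#' plus/minus a half range.
#'
#' @slot coverageTarget the requested minimum share (fraction, default 0.95).
#' @slot countThreshold the count cut-off c (the dashed line of the report).
#' @slot includedClasses integer indices of the included classes.
#' @slot firstUpper,lastUpper upper limits (percent) of the first and last
#'   included class.
#' @slot middleClass `(lastUpper + firstUpper) / 2`, percent.
#' @slot halfRange `(lastUpper - firstUpper) / 2`, percent.
#' @slot achievedCoverage share of values actually included (fraction).
#' @seealso [cutoffSummary()]
#' @export
setClass("CutoffSummary",
  representation(
    coverageTarget = "numeric",
    countThreshold = "integer",
    includedClasses = "integer",
    firstUpper = "numeric",
    lastUpper = "numeric",
    middleClass = "numeric",
    halfRange = "numeric",
    achievedCoverage = "numeric"
  )
)

setValidity("CutoffSummary", function(object) {
  if (object@achievedCoverage + 1e-12 < object@coverageTarget)
    return("achievedCoverage must be >= coverageTarget")
  TRUE
})

#' SweepGrid: the full (setting x k) grid of populations and statistics
#'
#' Result container of [replicateSweep()]: one row of the `summary` table
#' and one set of objects (population, frequency distribution, cut-off
#' summary) per (baseline/threshold setting, replicate setting k) cell.
#'
#' @slot summary data.frame with one row per cell; columns `setting`, `k`,
#'   `mean`, `sd`, `rsd`, `skewness`, `chi_p`, `rel_abs_deviation`,
#'   `middle_class`, `half_range`, `achieved_coverage`. `rsd`,
#'   `rel_abs_deviation`, `achieved_coverage` and `chi_p` are percentages;
#'   `mean`, `sd`, `middle_class`, `half_range` are GMO percent.
#' @slot populations list of [GmoPopulation], keyed `"setting|k"`.
#' @slot distributions list of [FrequencyDistribution], same keys.
#' @slot cutoffs list of [CutoffSummary], same keys.
#' @slot nClasses,coverageTarget,nominal the parameters used.
#' @seealso [replicateSweep()], [minReplicatesForRsd()]
#' @export
setClass("SweepGrid",
  representation(
    summary = "data.frame",
    populations = "list",
    distributions = "list",
    cutoffs = "list",
    nClasses = "integer",
    coverageTarget = "numeric",
    nominal = "numeric"
  )
)
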