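#' @include AllClasses.R
NULL

#' Population mean, SD, RSD and relative deviation
#'
#' The resampled GMO percentages are treated as the complete population of
#' values the plate supports, not as a sample from something larger; all
#' statistics therefore use the population form with divisor n (the
#' spreadsheet functions STDEVP etc.), never n - 1.
#'
#' * `mean` — arithmetic mean (GMO percent)
#' * `sdPopulation` — `sqrt(mean((x - mean)^2))`, divisor n
#' * `rsd` — relative standard deviation, `100 * sd / mean` (percent)
#' * `relAbsDeviation` — trueness measure, `100 * |mean - nominal| /
#'   nominal` (percent)
#'
#' @param values numeric population (non-empty)
#' @param nominal the nominal (certified) GMO percent, > 0
#' @return named list with elements `mean`, `sdPopulation`, `rsd`,
#'   `relAbsDeviation`, `n`
#' @examples
#' populationStats(c(1, 3), nominal = 2.5)  # sd 1 (divisor n), rsd 50
#' @export
populationStats <- function(values, nominal) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (length(nominal) != 1L || is.na(nominal) || nominal <= 0)
    stop("nominal must be a single positive number")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (m == 0) stop("population mean is zero: RSD undefined")
  list(mean = m,
       sdPopulation = s,
       rsd = 100 * s / m,
       relAbsDeviation = 100 * abs(m - nominal) / nominal,
       n = length(values))
}

#' Empirical skewness of a population
#'
#' `(1/n) * sum(((x - mean) / s)^3)` with s the population standard
#' deviation (divisor n). Zero for symmetric populations; positive values
#' indicate a right tail, as produced by low template copy numbers.
#' Location- and positive-scale-invariant; the sign flips under negative
#' scaling.
#'
#' @param values numeric population, at least 2 values with positive spread
#' @return the skewness (dimensionless)
#' @export
empiricalSkewness <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("population standard deviation is zero: skewness undefined")
  mean(((values - m) / s)^3)
}

#' Bin a population into equal-width frequency classes
#'
#' Classes span `[min(values), max(values)]` with equal widths; each class
#' is labelled by its upper limit. Intervals are `(lower, upper]` with the
#' first class additionally closed on its lower edge, so the minimum is
#' counted and the maximum falls in the last class. The class range follows
#' the data (no fixed round numbers), so class labels drift with the
#' population, as they do when the same plate is re-analysed under another
#' setting.
#'
#' If all values are identical there is no natural width; a fallback width
#' (1 percent of the value, or 1 if the value is 0) is used, every value
#' lands in the first class and a warning is issued.
#'
#' @param values numeric population (non-empty)
#' @param nClasses number of classes, >= 2 (default 20)
#' @return a [FrequencyDistribution-class]
#' @examples
#' binValues(0:9, nClasses = 5)   # counts 2,2,2,2,2
#' @export
binValues <- function(values, nClasses = 20) {
  nClasses <- as.integer(nClasses)
  if (length(values) == 0L) stop("values must be non-empty")
  if (nClasses < 2L) stop("nClasses must be at least 2")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    warning("all values identical; using a fallback class width")
    w <- if (lo == 0) 1 else abs(lo) * 0.01
    edges <- lo + (0:nClasses) * w
  } else {
    edges <- seq(lo, hi, length.out = nClasses + 1L)
  }
  w <- edges[2L] - edges[1L]
  idx <- ceiling((values - lo) / w)
  idx[idx < 1L] <- 1L
  idx[idx > nClasses] <- nClasses
  counts <- tabulate(idx, nbins = nClasses)
  new("FrequencyDistribution", edges = edges, counts = as.integer(counts),
      nTotal = length(values))
}

#' Simplified chi-square comparison with the Gaussian normal distribution
#'
#' Compares the observed class counts n against the counts m expected if
#' the population were Gaussian with the given mean and SD:
#' `chi2 = sum(d^2 / m)` with `d = n - m`. "Simplified" means sparse
#' marginal classes are NOT merged even when their expected count is below
#' 10 — the construction is kept deliberately plain so a spreadsheet user
#' can replicate it cell by cell.
#'
#' Expected counts are exact Gaussian interval masses (CDF differences)
#' times the population size, with the first class's lower edge extended to
#' -Inf and the last class's upper edge to +Inf so no probability mass is
#' lost in the tails.
#'
#' The p-value is the upper-tail chi-square probability at `df` degrees of
#' freedom (the CHIDIST convention) — the probability of a chi-square at
#' least this large if the population really were Gaussian; reports display
#' it as a percentage. Because mean and SD are estimated from the same
#' population, the default is `df = nClasses - 3`; set `df = nClasses - 1`
#' to reproduce the plain one-constraint convention.
#'
#' @param dist a [FrequencyDistribution-class] with at least 4 classes
#' @param mean,sd the population mean and (population) SD; `sd > 0`
#' @param df degrees of freedom; default `length(classCounts(dist)) - 3`
#' @return list with `chiSquare`, `df`, `p` (upper-tail probability,
#'   fraction in \[0, 1\])
#' @export
chiSquareNormality <- function(dist, mean, sd, df = NULL) {
  stopifnot(is(dist, "FrequencyDistribution"))
  nClasses <- length(dist@counts)
  if (nClasses < 4L) stop("need at least 4 classes")
  if (length(sd) != 1L || is.na(sd) || sd <= 0)
    stop("sd must be a single positive number")
  if (is.null(df)) df <- nClasses - 3L
  df <- as.integer(df)
  if (df < 1L) stop("df must be at least 1")

  edges <- dist@edges
  edges[1L] <- -Inf
  edges[length(edges)] <- Inf
  p <- diff(pnorm(edges, mean = mean, sd = sd))
  m <- p * dist@nTotal
  if (any(m == 0))
    stop("an expected class count is zero; use fewer classes")
  chi2 <- sum((dist@counts - m)^2 / m)
  list(chiSquare = chi2, df = df,
       p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' The >= 95 percent class cut-off summary
#'
#' Finds the largest count threshold c (the dashed horizontal line of the
#' frequency plot) such that the classes whose occupancy reaches c together
#' contain at least `coverageTarget` of all values. All classes at or above
#' the threshold are included (ties at the line are in). The included
#' classes are summarised by their upper limits: `middleClass = (U_last +
#' U_first) / 2` and `halfRange = (U_last - U_first) / 2`, giving the
#' "middle class +/- range" headline of a plate report.
#'
#' A threshold of 1 always satisfies the condition (every value lies in
#' some class), so the summary always exists.
#'
#' @param dist a [FrequencyDistribution-class]
#' @param coverageTarget minimum share of values to include (default 0.95)
#' @return a [CutoffSummary-class]
#' @export
cutoffSummary <- function(dist, coverageTarget = 0.95) {
  stopifnot(is(dist, "FrequencyDistribution"),
            coverageTarget > 0, coverageTarget <= 1)
  counts <- dist@counts
  candidates <- sort(unique(counts[counts > 0L]), decreasing = TRUE)
  threshold <- NA_integer_
  for (c0 in candidates) {
    if (sum(counts[counts >= c0]) >= coverageTarget * dist@nTotal) {
      threshold <- c0
      break
    }
  }
  included <- which(counts >= threshold)
  U <- dist@edges[-1L]
  firstU <- U[min(included)]
  lastU <- U[max(included)]
  new("CutoffSummary",
      coverageTarget = coverageTarget,
      countThreshold = threshold,
      includedClasses = as.integer(included),
      firstUpper = firstU, lastUpper = lastU,
      middleClass = (lastU + firstU) / 2,
      halfRange = (lastU - firstU) / 2,
      achievedCoverage = sum(counts[included]) / dist@nTotal)
}
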