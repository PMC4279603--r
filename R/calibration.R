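#' @include AllClasses.R
NULL

#' Fit a standard curve (Cq against log10 copy number)
#'
#' Ordinary least-squares regression of Cq on log10(copies) over calibration
#' wells with known copy numbers — the standard-curve method as performed by
#' qPCR instrument software. The regression direction (Cq as response)
#' matches that convention, so extrapolated copy numbers reproduce what the
#' cycler software would report. Replicate standards enter as individual
#' points, not as level means; for a balanced design both choices give the
#' same slope, but R-squared differs.
#'
#' Undetermined Cq values (`NA`) are excluded before fitting.
#'
#' @param copies known copy numbers of the calibration wells (positive)
#' @param cq measured Cq values (`NA` = undetermined, excluded)
#' @param gene,setting labels stored on the curve (informational)
#' @return a [StandardCurve-class]
#' @examples
#' # a perfect 100%-efficiency dilution series
#' copies <- rep(10^(5:1), each = 3)
#' cq <- -3.3219 * log10(copies) + 40
#' fitStandardCurve(copies, cq)
#' @export
fitStandardCurve <- function(copies, cq, gene = NA_character_,
                             setting = NA_character_) {
  stopifnot(length(copies) == length(cq))
  if (any(copies <= 0, na.rm = TRUE)) stop("copies must be positive")
  keep <- !is.na(cq)
  if (!any(keep)) stop("all Cq values are undetermined; cannot fit a curve")
  copies <- copies[keep]; cq <- cq[keep]
  lc <- log10(copies)
  if (length(unique(lc)) < 2L)
    stop("need at least 2 distinct concentration levels to fit a standard curve")
  fit <- lm(cq ~ lc)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  new("StandardCurve",
      gene = as.character(gene), setting = as.character(setting),
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      rSquared = min(max(r2, 0), 1), nPoints = length(cq))
}

#' Convert Cq values to copy numbers via a standard curve
#'
#' Inverts the calibration line: `copies = 10^((cq - intercept) / slope)`.
#' Undetermined Cq (`NA`) propagates as `NA` — whether such wells are
#' excluded or counted as zero copies is a downstream policy
#' ([conversionConfig()]), not decided here.
#'
#' @param curve a [StandardCurve-class]
#' @param cq numeric vector of Cq values (NA allowed)
#' @return numeric vector of estimated copy numbers
#' @export
cqToCopies <- function(curve, cq) {
  stopifnot(is(curve, "StandardCurve"))
  10^((cq - curve@intercept) / curve@slope)
}

#' @rdname cqToCopies
#' @param copies numeric vector of copy numbers (positive)
#' @export
copiesToCq <- function(curve, copies) {
  stopifnot(is(curve, "StandardCurve"))
  if (any(copies <= 0, na.rm = TRUE)) stop("copies must be positive")
  curve@slope * log10(copies) + curve@intercept
}

#' Amplification efficiency implied by a standard-curve slope
#'
#' `10^(-1/slope) - 1`; 1.0 (100 percent) means perfect per-cycle doubling,
#' which corresponds to a slope of -1/log10(2) = -3.3219 cycles per decade.
#' A useful diagnostic for curve quality.
#'
#' @param curve a [StandardCurve-class], or a single numeric slope
#' @return efficiency as a fraction (1 = 100 percent)
#' @export
amplificationEfficiency <- function(curve) {
  slope <- if (is(curve, "StandardCurve")) curve@slope else as.numeric(curve)
  if (length(slope) != 1L || is.na(slope) || slope >= 0)
    stop("amplification efficiency requires a negative slope")
  10^(-1 / slope) - 1
}

#' Fit standard curves for every gene under every setting
#'
#' @param experiment a [PlateExperiment-class]
#' @return nested list: `curves[[setting]][[gene]]` of
#'   [StandardCurve-class] objects
#' @export
fitCurves <- function(experiment) {
  stopifnot(is(experiment, "PlateExperiment"))
  cq <- cqValues(experiment)
  info <- wellInfo(experiment)
  out <- list()
  for (s in colnames(cq)) {
    out[[s]] <- list()
    for (g in .GENES) {
      sel <- info$task == "standard" & info$gene == g
      if (!any(sel)) next
      out[[s]][[g]] <- fitStandardCurve(
        copies = info$knownCopies[sel],
        cq = cq[sel, s],
        gene = g, setting = s)
    }
  }
  out
}

#' Validate no-template controls
#'
#' NTC wells must show no amplification (undetermined Cq) or amplify only
#' beyond a late-cycle cut; they never enter any fit or quantification.
#'
#' @param experiment a [PlateExperiment-class]
#' @param minCq wells with a determined Cq below this value fail (default 40)
#' @return `TRUE` invisibly; a warning names failing wells/settings
#' @export
validateNtc <- function(experiment, minCq = 40) {
  stopifnot(is(experiment, "PlateExperiment"))
  cq <- cqValues(experiment)
  info <- wellInfo(experiment)
  ntc <- info$task == "ntc"
  if (any(ntc)) {
    bad <- which(cq[ntc, , drop = FALSE] < minCq, arr.ind = TRUE)
    if (nrow(bad)) {
      wells <- info$position[ntc][bad[, 1L]]
      sets <- colnames(cq)[bad[, 2L]]
      warning("NTC amplification below Cq ", minCq, " in: ",
              paste(sprintf("%s (%s)", wells, sets), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Standard-curve summary table
#'
#' One row per (setting, gene): slope, intercept, R-squared, efficiency and
#' point count — the curve diagnostics block of a plate report.
#'
#' @param curves nested list from [fitCurves()]
#' @return data.frame
#' @export
curveTable <- function(curves) {
  rows <- list()
  for (s in names(curves)) for (g in names(curves[[s]])) {
    cv <- curves[[s]][[g]]
    rows[[paste(s, g)]] <- data.frame(
      setting = s, gene = g, slope = cv@slope, intercept = cv@intercept,
      r_squared = cv@rSquared,
      efficiency_percent = 100 * amplificationEfficiency(cv),
      n_points = cv@nPoints)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
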