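#' @include AllClasses.R
NULL

#' Conversion configuration for GMO-percentage calculation
#'
#' Two policy knobs sit between copy numbers and a GMO percentage:
#'
#' * `factor` — a single positive multiplicative constant applied to the
#'   transgene/reference copy ratio. The approximation that turns a copy
#'   ratio into a GM mass fraction reduces to such a material-specific
#'   constant (zygosity, genome sizes); it is user knowledge about the
#'   certified material, not something computable from the plate. Default 1
#'   (report the plain copy-number ratio).
#' * `missingCqPolicy` — what to do with wells whose Cq is undetermined:
#'   `"exclude"` (default) drops them from the well pools before resampling;
#'   `"zero_copies"` counts them as 0 copies, for detection-aware studies
#'   near the limit of quantification.
#'
#' @param factor positive multiplicative conversion factor
#' @param missingCqPolicy `"exclude"` or `"zero_copies"`
#' @return a list of class `ConversionConfig`
#' @export
conversionConfig <- function(factor = 1, missingCqPolicy = c("exclude", "zero_copies")) {
  missingCqPolicy <- match.arg(missingCqPolicy)
  factor <- as.numeric(factor)
  if (length(factor) != 1L || is.na(factor) || factor <= 0)
    stop("factor must be a single positive number")
  structure(list(factor = factor, missingCqPolicy = missingCqPolicy),
            class = "ConversionConfig")
}

## apply the missing-copy policy to a copies vector
.applyMissingPolicy <- function(copies, config) {
  if (config$missingCqPolicy == "zero_copies") {
    copies[is.na(copies)] <- 0
    copies
  } else {
    copies[!is.na(copies)]
  }
}

#' GMO percentage of one well combination
#'
#' Converts one chosen set of transgene wells and one chosen set of
#' reference-gene wells into a single GMO percentage:
#'
#'   `percent = factor * mean(tgCopies) / mean(refCopies) * 100`
#'
#' The ratio of means (average the copies per gene first, then divide) is
#' used rather than a mean of per-well ratios: transgene and reference wells
#' are unpaired on this plate design, ratio-of-means is the standard-curve
#' convention, and it makes the all-replicates case collapse to a single
#' value. The percentage is invariant under a common rescaling of all
#' copies and linear in a transgene-only rescaling.
#'
#' @param tgCopies transgene copy numbers (NA = undetermined well)
#' @param refCopies reference-gene copy numbers (NA = undetermined well)
#' @param config a [conversionConfig()]
#' @return GMO content in percent
#' @examples
#' combinationGmoPercent(c(1, 1), c(1000, 1000), conversionConfig())  # 0.1
#' @export
combinationGmoPercent <- function(tgCopies, refCopies,
                                  config = conversionConfig()) {
  stopifnot(inherits(config, "ConversionConfig"))
  tg <- .applyMissingPolicy(tgCopies, config)
  rf <- .applyMissingPolicy(refCopies, config)
  if (length(tg) == 0L || length(rf) == 0L)
    stop("no wells left after applying the missing-Cq policy")
  mrf <- mean(rf)
  if (mrf == 0)
    stop("mean reference copies is zero: GMO percentage undefined")
  config$factor * mean(tg) / mrf * 100
}
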