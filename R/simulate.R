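#' @include plate-io.R calibration.R
NULL

#' Simulation configuration for a synthetic plate
#'
#' Describes the ground truth behind a synthetic [PlateExperiment-class]:
#' a certified material of known GM content measured on the default
#' dual-target plate (5-point triplicate standard curves, 1 NTC and 2
#' isolations x 16 sample replicates per gene).
#'
#' The generative model, per sample well:
#' \enumerate{
#'   \item template copies — the nominal mean (`refCopiesPerReaction` for
#'     the reference gene, `refCopiesPerReaction * trueGmoPercent / 100`
#'     for the transgene), or a Poisson draw around it when
#'     `poissonTemplate = TRUE`. Poisson template sampling is what creates
#'     the right-skewed populations seen at low GM levels (at 0.1 percent,
#'     roughly 12-25 transgene copies reach a reaction): Gaussian Cq noise
#'     alone cannot produce that asymmetry. A Poisson draw of 0 copies
#'     gives an undetermined Cq.
#'   \item Cq = slope * log10(copies) + intercept, plus a per-isolation
#'     shift ~ N(0, `isolationEffectSd`) shared by ALL sample wells of that
#'     DNA isolation (both genes are measured from the same extract, so a
#'     template-amount difference between isolations moves them together
#'     and mostly cancels in the copy ratio), plus independent well noise
#'     ~ N(0, `cqNoiseSd`).
#'   \item per pseudo-setting jitter ~ N(0, `settingJitterSd`), drawn
#'     independently for each well under each setting. This emulates
#'     re-analysing the same run with different baseline/threshold
#'     settings: small perturbations of the SAME wells, not independent
#'     plates.
#' }
#' Standard wells get their level's nominal copies plus well noise (and
#' jitter); NTC wells are undetermined.
#'
#' @param trueGmoPercent true GM content of the simulated material (%);
#'   default 0.1, the regulatory minimum performance level at which
#'   quantification is hardest
#' @param refCopiesPerReaction mean reference-gene copies per reaction;
#'   default 20000 (roughly 60 ng of a mid-sized plant genome)
#' @param slopes,intercepts named numeric vectors (`transgene`,
#'   `reference`) of the generating standard-curve parameters; defaults:
#'   slope -3.3219 (100 percent efficiency), intercept 37
#' @param cqNoiseSd per-well Cq noise SD, cycles (default 0.2)
#' @param isolationEffectSd SD of the per-isolation Cq shift, cycles
#'   (default 0.1)
#' @param poissonTemplate draw per-well template copies as Poisson at the
#'   nominal mean (default TRUE)
#' @param nPseudoSettings number of emulated baseline/threshold settings
#'   (default 5)
#' @param settingJitterSd SD of the per-setting Cq jitter, cycles
#'   (default 0.05)
#' @param standardCopies the five calibration levels (default 1e5..1e1)
#' @param seed integer seed; a fixed seed reproduces the plate bit for bit
#' @return a list of class `SimulationConfig`
#' @seealso [simulatePlate()]
#' @export
simulationConfig <- function(trueGmoPercent = 0.1,
                             refCopiesPerReaction = 20000,
                             slopes = c(transgene = -3.3219, reference = -3.3219),
                             intercepts = c(transgene = 37, reference = 37),
                             cqNoiseSd = 0.2,
                             isolationEffectSd = 0.1,
                             poissonTemplate = TRUE,
                             nPseudoSettings = 5,
                             settingJitterSd = 0.05,
                             standardCopies = c(1e5, 1e4, 1e3, 1e2, 1e1),
                             seed = 1) {
  stopifnot(trueGmoPercent >= 0, refCopiesPerReaction > 0,
            all(.GENES %in% names(slopes)), all(.GENES %in% names(intercepts)),
            all(slopes < 0),
            cqNoiseSd >= 0, isolationEffectSd >= 0, settingJitterSd >= 0,
            nPseudoSettings >= 1, length(standardCopies) == 5L,
            all(standardCopies > 0))
  structure(list(
    trueGmoPercent = trueGmoPercent,
    refCopiesPerReaction = refCopiesPerReaction,
    slopes = slopes[.GENES], intercepts = intercepts[.GENES],
    cqNoiseSd = cqNoiseSd, isolationEffectSd = isolationEffectSd,
    poissonTemplate = isTRUE(poissonTemplate),
    nPseudoSettings = as.integer(nPseudoSettings),
    settingJitterSd = settingJitterSd,
    standardCopies = as.numeric(standardCopies),
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate a PlateExperiment with known ground truth
#'
#' Generates Cq values for the default dual-target 96-well layout under the
#' model described in [simulationConfig()]. The template copies of a well
#' are physical and therefore shared by all pseudo-settings; only the Cq
#' read-out jitters between settings. A fixed seed yields a bit-identical
#' experiment.
#'
#' @param config a [simulationConfig()]
#' @return a [PlateExperiment-class] with `config$nPseudoSettings` settings;
#'   the true per-well template copies are kept in
#'   `metadata(x)$trueCopies` for diagnostics
#' @examples
#' pe <- simulatePlate(simulationConfig(seed = 42))
#' pe
#' @export
simulatePlate <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  tgMean <- config$refCopiesPerReaction * config$trueGmoPercent / 100
  if (tgMean <= 0 && !config$poissonTemplate)
    stop("transgene mean of 0 copies requires poissonTemplate = TRUE ",
         "(log of zero copies is undefined)")
  layout <- defaultPlateLayout(
    nominalGmoPercent = if (config$trueGmoPercent > 0)
      config$trueGmoPercent else 0.1,
    conversionFactor = 1,
    standardCopies = config$standardCopies)
  lt <- .layoutWellTable(layout)
  nWells <- nrow(lt)

  set.seed(config$seed)
  ## fixed draw order: isolation effects, template copies (table order),
  ## base well noise (table order), then per-setting jitter.
  ## One Cq shift per isolation, shared by both genes: the two DNA
  ## extractions differ chiefly in template amount, which moves every well
  ## of that isolation together; the transgene/reference ratio is largely
  ## insensitive to it, by design of the dual-target assay.
  isoEff <- rnorm(2L, 0, config$isolationEffectSd)

  nominalCopies <- ifelse(lt$gene == "transgene", tgMean,
                          config$refCopiesPerReaction)
  copies <- ifelse(lt$task == "standard", lt$knownCopies, nominalCopies)
  isSample <- lt$task == "sample"
  if (config$poissonTemplate)
    copies[isSample] <- rpois(sum(isSample), nominalCopies[isSample])

  baseCq <- rep(NA_real_, nWells)
  noise <- rnorm(nWells, 0, config$cqNoiseSd)
  for (g in .GENES) {
    sel <- lt$gene == g & lt$task != "ntc" & copies > 0
    baseCq[sel] <- config$slopes[[g]] * log10(copies[sel]) +
      config$intercepts[[g]] + noise[sel]
    smp <- sel & isSample
    baseCq[smp] <- baseCq[smp] + isoEff[lt$isolation[smp]]
  }
  ## zero-template Poisson draws and NTCs stay undetermined (NA)

  cq <- matrix(NA_real_, nWells, config$nPseudoSettings,
               dimnames = list(lt$position,
                               paste0("setting", seq_len(config$nPseudoSettings))))
  for (s in seq_len(config$nPseudoSettings)) {
    jitter <- rnorm(nWells, 0, config$settingJitterSd)
    cq[, s] <- baseCq + jitter
  }

  se <- SummarizedExperiment(
    assays = list(cq = cq),
    rowData = S4Vectors::DataFrame(
      gene = lt$gene, task = lt$task,
      isolation = lt$isolation, knownCopies = lt$knownCopies,
      row.names = lt$position),
    metadata = list(layout = layout, simulation = config,
                    trueCopies = setNames(copies, lt$position)))
  new("PlateExperiment", se)
}
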