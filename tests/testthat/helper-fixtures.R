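suppressPackageStartupMessages(library(SummarizedExperiment))

## Shared fixture builders. Everything is generated in code; the "exact"
## experiments put all standards exactly on a known calibration line so that
## fitted curves, and hence well copy numbers, are recovered without error.

EXACT_SLOPE <- -3.3219
EXACT_INTERCEPT <- 40

## Cq exactly on the reference line for a given copy number
exactCq <- function(copies) EXACT_SLOPE * log10(copies) + EXACT_INTERCEPT

## A small layout with `n` sample wells per (gene, isolation) and a 3-level
## single-replicate standard curve per gene (wells fit in rows A/B).
tinyLayout <- function(n = 3, nominal = 0.1) {
  stopifnot(n <= 4)
  PlateLayout(
    standards = data.frame(
      gene = rep(c("transgene", "reference"), each = 3),
      position = c("A1", "A2", "A3", "B1", "B2", "B3"),
      copies = rep(c(1e4, 1e3, 1e2), 2)),
    ntc = data.frame(gene = character(), position = character()),
    samples = data.frame(
      gene = rep(c("transgene", "reference"), each = 2 * n),
      position = c(paste0("A", 3 + seq_len(2 * n)),
                   paste0("B", 3 + seq_len(2 * n))),
      isolation = rep(rep(1:2, each = n), 2)),
    nominalGmoPercent = nominal)
}

## Build a PlateExperiment whose sample wells carry exactly the given copy
## numbers (per pool, per setting). `copies` is a list keyed by setting id;
## each element a list over pools (transgene.1, transgene.2, reference.1,
## reference.2) of numeric vectors (NA = undetermined well).
exactExperiment <- function(copies, layout = NULL, nominal = 0.1) {
  pools <- c("transgene.1", "transgene.2", "reference.1", "reference.2")
  n <- length(copies[[1]][[pools[1]]])
  if (is.null(layout)) layout <- tinyLayout(n, nominal = nominal)
  lt <- qpcrPlateVar:::.layoutWellTable(layout)
  tables <- lapply(copies, function(cp) {
    cq <- numeric(nrow(lt))
    for (i in seq_len(nrow(lt))) {
      if (lt$task[i] == "standard") {
        cq[i] <- exactCq(lt$knownCopies[i])
      } else if (lt$task[i] == "ntc") {
        cq[i] <- NA_real_
      } else {
        pool <- paste(lt$gene[i], lt$isolation[i], sep = ".")
        ## wells are in plate order within each pool
        poolWells <- lt$position[lt$task == "sample" &
                                 lt$gene == lt$gene[i] &
                                 !is.na(lt$isolation) &
                                 lt$isolation == lt$isolation[i]]
        j <- match(lt$position[i], poolWells)
        v <- cp[[pool]][j]
        cq[i] <- if (is.na(v)) NA_real_ else exactCq(v)
      }
    }
    data.frame(position = lt$position, gene = lt$gene, task = lt$task,
               isolation = lt$isolation, knownCopies = lt$knownCopies,
               cq = cq)
  })
  assembleExperiment(layout, tables)
}

## A one-setting experiment with every sample well at the same copy number
constantExperiment <- function(tgCopies = 20, refCopies = 20000, n = 3) {
  pools <- list(
    transgene.1 = rep(tgCopies, n), transgene.2 = rep(tgCopies, n),
    reference.1 = rep(refCopies, n), reference.2 = rep(refCopies, n))
  exactExperiment(list(s1 = pools))
}

## Exhaustive enumeration of all C(n, k)^4 pool subsets for tiny pools:
## the exact population the Monte-Carlo draws estimate.
enumeratePopulation <- function(pools, k, factor = 1) {
  subsets <- lapply(pools, function(v) combn(length(v), k, simplify = FALSE))
  idx <- expand.grid(lapply(subsets, seq_along))
  vapply(seq_len(nrow(idx)), function(i) {
    pick <- function(p) pools[[p]][subsets[[p]][[idx[i, p]]]]
    tg <- c(pick("transgene.1"), pick("transgene.2"))
    rf <- c(pick("reference.1"), pick("reference.2"))
    factor * mean(tg) / mean(rf) * 100
  }, numeric(1))
}

## population (divisor n) moments
popSd <- function(x) sqrt(mean((x - mean(x))^2))
popMoment <- function(x, p) mean((x - mean(x))^p)

## write a one-setting canonical table for a simulated experiment
writeSettingTable <- function(experiment, setting, file) {
  info <- wellInfo(experiment)
  rec <- data.frame(position = info$position, gene = info$gene,
                    task = info$task, knownCopies = info$knownCopies,
                    cq = cqValues(experiment)[, setting])
  writePlateTable(rec, file)
  file
}
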