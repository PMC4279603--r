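#' @include quantification.R calibration.R
NULL

.POOLS <- c("transgene.1", "transgene.2", "reference.1", "reference.2")

## per-k substream seed, derived from the root seed (kept below 2^31)
.substreamSeed <- function(seed, k) {
  as.integer((as.double(seed) + 10007 * k) %% (2^31 - 1))
}

#' Build the seeded combination plan
#'
#' Fixes the random well combinations once, before any Cq value is
#' consulted, so that the identical combinations can be applied to every
#' baseline/threshold setting (and re-applied later to reproduce a report
#' exactly). For each replicate setting k, `nCombinations` index tuples are
#' drawn; a tuple takes k distinct wells from each of the four pools
#' (transgene/reference gene x isolation 1/2), i.e. 2k wells per gene.
#' Draws are uniform, without replacement within a pool, and independent
#' across pools and across combinations — so the same tuple may recur among
#' the `nCombinations` draws (exhaustive enumeration is astronomically
#' large at intermediate k).
#'
#' Determinism: the plan is a pure function of `(seed, poolSizes, ks,
#' nCombinations)`. Each k uses its own substream seed,
#' `(seed + 10007 * k) mod (2^31 - 1)`, so any single k can be regenerated
#' without replaying the rest of the plan.
#'
#' @param poolSizes wells available per pool: either a single integer
#'   (all four pools equal, e.g. 16 for the default full plate) or a named
#'   integer vector over `transgene.1`, `transgene.2`, `reference.1`,
#'   `reference.2`
#' @param ks replicate settings to cover (k wells per isolation);
#'   default `2:16`
#' @param nCombinations combinations per k; default 5000
#' @param seed integer root seed
#' @return a [ResamplingPlan-class]
#' @examples
#' plan <- buildPlan(16, ks = c(2, 8), nCombinations = 100, seed = 1)
#' plan
#' @export
buildPlan <- function(poolSizes, ks = 2:16, nCombinations = 5000, seed) {
  if (length(poolSizes) == 1L && is.null(names(poolSizes)))
    poolSizes <- setNames(rep(as.integer(poolSizes), 4L), .POOLS)
  if (!all(.POOLS %in% names(poolSizes)))
    stop("poolSizes must be a single integer or named over: ",
         paste(.POOLS, collapse = ", "))
  poolSizes <- setNames(as.integer(poolSizes[.POOLS]), .POOLS)
  ks <- sort(unique(as.integer(ks)))
  nCombinations <- as.integer(nCombinations)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed), nCombinations >= 1L, all(ks >= 1L))

  for (p in .POOLS)
    if (any(ks > poolSizes[[p]]))
      stop(sprintf("k = %d exceeds the %s pool size (%d wells)",
                   max(ks), p, poolSizes[[p]]))

  combos <- list()
  for (k in ks) {
    set.seed(.substreamSeed(seed, k))
    combos[[as.character(k)]] <- lapply(setNames(.POOLS, .POOLS), function(p) {
      n <- poolSizes[[p]]
      if (k == n) {
        ## only one k-subset exists; skip RNG so the degenerate case is exact
        matrix(rep(seq_len(n), each = nCombinations), nrow = nCombinations)
      } else {
        m <- vapply(seq_len(nCombinations),
                    function(i) sample.int(n, k), integer(k))
        if (k == 1L) matrix(m, ncol = 1L) else t(m)
      }
    })
  }
  new("ResamplingPlan", seed = seed, nCombinations = nCombinations,
      ks = ks, poolSizes = poolSizes, combos = combos)
}

#' Sample-well pools of an experiment under a missing-Cq policy
#'
#' Returns the ordered well positions of the four (gene, isolation) pools.
#' Under `missingCqPolicy = "exclude"`, a well whose Cq is undetermined in
#' ANY setting is removed from its pool for ALL settings — the pools must be
#' identical across settings or the shared plan would lose its cross-setting
#' comparability. Under `"zero_copies"` no well is removed.
#'
#' @param experiment a [PlateExperiment-class]
#' @param config a [conversionConfig()]
#' @return named list of character vectors of well positions, over
#'   `transgene.1`, `transgene.2`, `reference.1`, `reference.2`
#' @export
samplePools <- function(experiment, config = conversionConfig()) {
  stopifnot(is(experiment, "PlateExperiment"),
            inherits(config, "ConversionConfig"))
  info <- wellInfo(experiment)
  cq <- cqValues(experiment)
  pools <- list()
  for (g in .GENES) for (iso in 1:2) {
    sel <- info$task == "sample" & info$gene == g &
      !is.na(info$isolation) & info$isolation == iso
    wells <- .orderWells(info$position[sel])
    if (config$missingCqPolicy == "exclude") {
      undetAny <- rowSums(is.na(cq[wells, , drop = FALSE])) > 0L
      if (any(undetAny)) {
        warning(sprintf(
          "excluding %d well(s) with undetermined Cq from pool %s.%d: %s",
          sum(undetAny), g, iso,
          paste(wells[undetAny], collapse = ", ")))
        wells <- wells[!undetAny]
      }
    }
    pools[[paste(g, iso, sep = ".")]] <- wells
  }
  pools[.POOLS]
}

#' Evaluate a resampling plan into GMO-percentage populations
#'
#' Applies the plan's index tuples to the copy numbers of every
#' baseline/threshold setting: combination i at replicate setting k selects
#' the same wells in every setting, and each combination is converted to a
#' GMO percentage as `factor * mean(2k transgene copies) / mean(2k
#' reference copies) * 100`.
#'
#' Copy numbers come from the per-setting, per-gene standard curves
#' (refitted here via [fitCurves()] unless supplied). Under
#' `missingCqPolicy = "exclude"`, pools are pre-shrunk by [samplePools()];
#' the plan must have been built for the shrunken pool sizes, and an error
#' is raised if the sizes disagree or if a pool falls below `max(ks)`.
#'
#' @param plan a [ResamplingPlan-class]
#' @param experiment a [PlateExperiment-class]
#' @param config a [conversionConfig()]; defaults to the experiment
#'   layout's conversion factor with the `"exclude"` policy
#' @param curves optional result of [fitCurves()] on the same experiment
#' @return named list of [GmoPopulation-class], keyed `"setting|k"`
#' @export
evaluatePlan <- function(plan, experiment, config = NULL, curves = NULL) {
  stopifnot(is(plan, "ResamplingPlan"), is(experiment, "PlateExperiment"))
  if (is.null(config))
    config <- conversionConfig(factor = conversionFactor(experiment))
  if (is.null(curves)) curves <- fitCurves(experiment)
  pools <- samplePools(experiment, config)

  sizes <- lengths(pools)
  if (any(sizes < max(plan@ks)))
    stop("pool(s) smaller than max(ks) after the missing-Cq policy: ",
         paste(sprintf("%s=%d", names(sizes), sizes)[sizes < max(plan@ks)],
               collapse = ", "))
  if (!identical(unname(sizes[.POOLS]), unname(as.integer(plan@poolSizes))))
    stop("plan pool sizes (", paste(plan@poolSizes, collapse = ","),
         ") do not match the experiment's pools (",
         paste(sizes[.POOLS], collapse = ","), ")")

  cq <- cqValues(experiment)
  out <- list()
  for (s in colnames(cq)) {
    ## copies per pool well, in pool order
    copies <- lapply(setNames(.POOLS, .POOLS), function(p) {
      g <- sub("\\..*$", "", p)
      v <- cqToCopies(curves[[s]][[g]], cq[pools[[p]], s])
      .applyMissingPolicyKeepLength(v, config)
    })
    for (k in plan@ks) {
      cs <- plan@combos[[as.character(k)]]
      sums <- lapply(.POOLS, function(p) {
        m <- cs[[p]]
        rowSums(matrix(copies[[p]][m], nrow = nrow(m)))
      })
      names(sums) <- .POOLS
      tgMean <- (sums[["transgene.1"]] + sums[["transgene.2"]]) / (2 * k)
      rfMean <- (sums[["reference.1"]] + sums[["reference.2"]]) / (2 * k)
      if (any(rfMean == 0))
        stop("mean reference copies is zero in at least one combination (",
             s, ", k = ", k, ")")
      vals <- config$factor * tgMean / rfMean * 100
      out[[paste(s, k, sep = "|")]] <-
        new("GmoPopulation", setting = s, k = as.integer(k), values = vals)
    }
  }
  out
}

## like .applyMissingPolicy but never drops elements: under "exclude" the
## pools were already shrunk, so a residual NA is a logic error
.applyMissingPolicyKeepLength <- function(copies, config) {
  if (config$missingCqPolicy == "zero_copies") {
    copies[is.na(copies)] <- 0
  } else if (anyNA(copies)) {
    stop("internal error: undetermined well survived pool shrinking")
  }
  copies
}

#' Export / import a resampling plan as a plain text table
#'
#' The plan is written as a tab-separated table with comment headers
#' (`# seed`, `# n_combinations`, `# pool_sizes`) and one row per
#' (k, combination, pool) holding the space-separated well indices. An
#' imported plan is bit-identical to the exported one, so a report can be
#' regenerated exactly from its audit trail.
#'
#' @param plan a [ResamplingPlan-class]
#' @param file path of the plan table
#' @return `exportPlan()` returns `file` invisibly; `importPlan()` returns
#'   the reconstructed [ResamplingPlan-class]
#' @export
exportPlan <- function(plan, file) {
  stopifnot(is(plan, "ResamplingPlan"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed\t%d", plan@seed),
    sprintf("# n_combinations\t%d", plan@nCombinations),
    sprintf("# pool_sizes\t%s",
            paste(sprintf("%s=%d", names(plan@poolSizes), plan@poolSizes),
                  collapse = " ")),
    "k\tcombination\tpool\tindices"), con)
  for (k in plan@ks) {
    cs <- plan@combos[[as.character(k)]]
    for (p in .POOLS) {
      idx <- apply(cs[[p]], 1L, paste, collapse = " ")
      writeLines(sprintf("%d\t%d\t%s\t%s", k, seq_along(idx), p, idx), con)
    }
  }
  invisible(file)
}

#' @rdname exportPlan
#' @export
importPlan <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "# ")]
  getHdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    if (length(ln) != 1L) stop("plan file missing header: ", key)
    sub(paste0("^# ", key, "\t"), "", ln)
  }
  seed <- as.integer(getHdr("seed"))
  nComb <- as.integer(getHdr("n_combinations"))
  psRaw <- strsplit(getHdr("pool_sizes"), " ", fixed = TRUE)[[1L]]
  ps <- setNames(
    as.integer(sub("^.*=", "", psRaw)),
    sub("=.*$", "", psRaw))[.POOLS]

  body <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                     header = TRUE, colClasses = "character")
  body$k <- as.integer(body$k)
  ks <- sort(unique(body$k))
  combos <- list()
  for (k in ks) {
    bk <- body[body$k == k, , drop = FALSE]
    combos[[as.character(k)]] <- lapply(setNames(.POOLS, .POOLS), function(p) {
      bp <- bk[bk$pool == p, , drop = FALSE]
      bp <- bp[order(as.integer(bp$combination)), , drop = FALSE]
      m <- t(vapply(strsplit(bp$indices, " ", fixed = TRUE),
                    function(x) as.integer(x), integer(k)))
      if (k == 1L) matrix(as.integer(unlist(strsplit(bp$indices, " "))),
                          ncol = 1L) else m
    })
  }
  new("ResamplingPlan", seed = seed, nCombinations = nComb,
      ks = as.integer(ks), poolSizes = ps, combos = combos)
}
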