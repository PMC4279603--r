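#' @include AllClasses.R
NULL

#' Construct a PlateLayout
#'
#' @param standards data.frame with columns `gene`, `position`, `copies`
#'   (known copy number of each standard well).
#' @param ntc data.frame with columns `gene`, `position`.
#' @param samples data.frame with columns `gene`, `position`, `isolation`.
#' @param nominalGmoPercent certified nominal GM content of the material on
#'   the plate, in percent.
#' @param conversionFactor positive multiplicative factor applied to the
#'   transgene/reference copy ratio (zygosity / mass-fraction
#'   approximation); default 1.
#' @return a validated [PlateLayout-class] object
#' @export
PlateLayout <- function(standards, ntc, samples,
                        nominalGmoPercent, conversionFactor = 1) {
  standards$position <- as.character(standards$position)
  ntc$position <- as.character(ntc$position)
  samples$position <- as.character(samples$position)
  samples$isolation <- as.integer(samples$isolation)
  standards$copies <- as.numeric(standards$copies)
  new("PlateLayout",
      standards = standards, ntc = ntc, samples = samples,
      nominalGmoPercent = as.numeric(nominalGmoPercent),
      conversionFactor = as.numeric(conversionFactor))
}

#' The default 96-well dual-target layout
#'
#' Builds the canonical plate arrangement for intra-plate variability
#' studies: each gene occupies 48 wells, of which 15 are standards (5
#' calibration levels in triplicate), 1 is the no-template control and 32
#' are sample replicates split into two DNA isolations of 16 wells each
#' (48 - 15 - 1 = 32 per gene). The transgene occupies rows A-D, the
#' reference gene rows E-H.
#'
#' @param nominalGmoPercent certified GM content of the plate's material (%).
#' @param conversionFactor copy-ratio conversion factor, default 1.
#' @param standardCopies the five calibration levels (copies per reaction),
#'   highest first; each run in triplicate.
#' @return a [PlateLayout-class]
#' @examples
#' layout <- defaultPlateLayout(nominalGmoPercent = 0.1)
#' layout
#' @export
defaultPlateLayout <- function(nominalGmoPercent = 0.1,
                               conversionFactor = 1,
                               standardCopies = c(1e5, 1e4, 1e3, 1e2, 1e1)) {
  stopifnot(length(standardCopies) == 5L, all(standardCopies > 0))
  half <- function(gene, rows) {
    wells <- as.vector(t(outer(rows, .PLATE_COLS, paste0)))  # 48, row-major
    std <- data.frame(
      gene = gene,
      position = wells[1:15],
      copies = rep(as.numeric(standardCopies), each = 3L))
    ntc <- data.frame(gene = gene, position = wells[16])
    smp <- data.frame(
      gene = gene,
      position = wells[17:48],
      isolation = rep(c(1L, 2L), each = 16L))
    list(std = std, ntc = ntc, smp = smp)
  }
  tg <- half("transgene", LETTERS[1:4])
  rf <- half("reference", LETTERS[5:8])
  PlateLayout(
    standards = rbind(tg$std, rf$std),
    ntc = rbind(tg$ntc, rf$ntc),
    samples = rbind(tg$smp, rf$smp),
    nominalGmoPercent = nominalGmoPercent,
    conversionFactor = conversionFactor)
}

#' Read / write a plate layout config file
#'
#' The layout travels as a small YAML document so that isolation membership,
#' nominal value and conversion factor are explicit inputs rather than
#' guessed from an instrument export. Schema:
#' \preformatted{
#' nominal_gmo_percent: 0.1
#' conversion_factor: 1.0
#' genes:
#'   transgene:
#'     standards:            # one entry per standard well
#'       - {position: A1, copies: 100000}
#'     ntc: [B4]
#'     samples:
#'       isolation1: [B5, B6, ...]
#'       isolation2: [C9, ...]
#'   reference: ...
#' }
#' An example ships with the package:
#' `system.file("extdata", "example_layout.yaml", package = "qpcrPlateVar")`.
#'
#' @param file path to the YAML layout file
#' @return `readPlateLayout()` returns a [PlateLayout-class];
#'   `writePlateLayout()` returns `file` invisibly.
#' @export
readPlateLayout <- function(file) {
  doc <- yaml::read_yaml(file)
  need <- c("nominal_gmo_percent", "genes")
  if (!all(need %in% names(doc)))
    stop("layout config must contain: ", paste(need, collapse = ", "))
  std <- ntc <- smp <- list()
  for (g in names(doc$genes)) {
    gd <- doc$genes[[g]]
    stdg <- do.call(rbind, lapply(gd$standards, function(s)
      data.frame(gene = g, position = s$position, copies = s$copies)))
    std[[g]] <- stdg
    if (length(gd$ntc))
      ntc[[g]] <- data.frame(gene = g, position = unlist(gd$ntc))
    smp[[g]] <- rbind(
      data.frame(gene = g, position = unlist(gd$samples$isolation1),
                 isolation = 1L),
      data.frame(gene = g, position = unlist(gd$samples$isolation2),
                 isolation = 2L))
  }
  unrowname <- function(df) { rownames(df) <- NULL; df }
  PlateLayout(
    standards = unrowname(do.call(rbind, std)),
    ntc = if (length(ntc)) unrowname(do.call(rbind, ntc)) else
      data.frame(gene = character(), position = character()),
    samples = unrowname(do.call(rbind, smp)),
    nominalGmoPercent = doc$nominal_gmo_percent,
    conversionFactor = if (is.null(doc$conversion_factor)) 1
                       else doc$conversion_factor)
}

#' @rdname readPlateLayout
#' @param layout a [PlateLayout-class]
#' @export
writePlateLayout <- function(layout, file) {
  stopifnot(is(layout, "PlateLayout"))
  genes <- list()
  for (g in .GENES) {
    stdg <- layout@standards[layout@standards$gene == g, , drop = FALSE]
    smpg <- layout@samples[layout@samples$gene == g, , drop = FALSE]
    ntcg <- layout@ntc[layout@ntc$gene == g, , drop = FALSE]
    genes[[g]] <- list(
      standards = lapply(seq_len(nrow(stdg)), function(i)
        list(position = stdg$position[i], copies = stdg$copies[i])),
      ntc = as.list(ntcg$position),
      samples = list(
        isolation1 = as.list(smpg$position[smpg$isolation == 1L]),
        isolation2 = as.list(smpg$position[smpg$isolation == 2L])))
  }
  yaml::write_yaml(list(
    nominal_gmo_percent = layout@nominalGmoPercent,
    conversion_factor = layout@conversionFactor,
    genes = genes), file)
  invisible(file)
}

## all positions of a layout, with their roles, as one table (internal)
.layoutWellTable <- function(layout) {
  std <- data.frame(position = layout@standards$position,
                    gene = layout@standards$gene,
                    task = "standard",
                    isolation = NA_integer_,
                    knownCopies = layout@standards$copies)
  ntc <- if (nrow(layout@ntc))
    data.frame(position = layout@ntc$position, gene = layout@ntc$gene,
               task = "ntc", isolation = NA_integer_,
               knownCopies = NA_real_)
  else NULL
  smp <- data.frame(position = layout@samples$position,
                    gene = layout@samples$gene,
                    task = "sample",
                    isolation = layout@samples$isolation,
                    knownCopies = NA_real_)
  out <- rbind(std, ntc, smp)
  out[match(.orderWells(out$position), out$position), , drop = FALSE]
}
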