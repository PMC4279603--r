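#' @include plate-layout.R
NULL

## parse a Cq column: numeric, or the explicit missing marker "undetermined"
.parseCq <- function(x, file = "<table>") {
  x <- trimws(as.character(x))
  undet <- is.na(x) | x == "" | tolower(x) %in% c("undetermined", "undet", "n/a", "na")
  out <- rep(NA_real_, length(x))
  num <- suppressWarnings(as.numeric(x[!undet]))
  if (anyNA(num)) {
    bad <- x[!undet][is.na(num)]
    stop(sprintf("unparseable Cq value(s) in %s: %s", file,
                 paste(unique(bad), collapse = ", ")))
  }
  out[!undet] <- num
  out
}

#' Read one canonical plate Cq table
#'
#' The canonical export is a delimited text table (comma or tab,
#' autodetected) with a header row and the columns `Well`, `Target`,
#' `Task`, `Cq` and `Quantity` (column names are matched
#' case-insensitively; `Quantity` may be empty for non-standard wells).
#' Vendor exports from specific instruments are expected to be adapted to
#' this schema by thin per-dialect converters; the analysis itself only
#' ever sees the canonical form.
#'
#' Undetermined Cq values (empty cells or the word "undetermined") are kept
#' as an explicit missing marker (`NA`), never silently dropped or set to
#' zero: how non-amplifying wells enter the resampling is a downstream
#' policy decision (see [conversionConfig()]).
#'
#' When a `layout` is supplied the table is validated against it: every
#' layout position must be present exactly once, and gene/task annotations
#' must agree. The returned records then carry the layout's isolation
#' membership and known standard copies.
#'
#' @param file path to the delimited table
#' @param layout optional [PlateLayout-class] to validate and annotate against
#' @return data.frame of well records with columns `position`, `gene`,
#'   `task`, `isolation`, `knownCopies`, `cq` (NA = undetermined), ordered
#'   by plate position
#' @export
readPlateTable <- function(file, layout = NULL) {
  first <- readLines(file, n = 1L)
  if (length(first) == 0L) stop("no rows in ", file)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  tab <- read.table(file, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
  if (nrow(tab) == 0L) stop("no rows in ", file)
  names(tab) <- tolower(names(tab))
  need <- c("well", "target", "task", "cq")
  if (!all(need %in% names(tab)))
    stop("missing column(s) in ", file, ": ",
         paste(setdiff(need, names(tab)), collapse = ", "))

  rec <- data.frame(
    position = toupper(trimws(tab$well)),
    gene = tolower(trimws(tab$target)),
    task = tolower(trimws(tab$task)),
    isolation = NA_integer_,
    knownCopies = if ("quantity" %in% names(tab))
      suppressWarnings(as.numeric(tab$quantity)) else NA_real_,
    cq = .parseCq(tab$cq, file))

  if (anyDuplicated(rec$position))
    stop("duplicate well position(s) in ", file, ": ",
         paste(unique(rec$position[duplicated(rec$position)]), collapse = ", "))
  if (!all(.isWellLabel(rec$position)))
    stop("invalid well label(s) in ", file, ": ",
         paste(rec$position[!.isWellLabel(rec$position)], collapse = ", "))

  if (!is.null(layout)) {
    stopifnot(is(layout, "PlateLayout"))
    lt <- .layoutWellTable(layout)
    missing <- setdiff(lt$position, rec$position)
    if (length(missing))
      stop("layout position(s) absent from ", file, ": ",
           paste(missing, collapse = ", "))
    rec <- rec[match(lt$position, rec$position), , drop = FALSE]
    conflict <- rec$gene != lt$gene | rec$task != lt$task
    if (any(conflict))
      stop("gene/task conflict with layout at well(s): ",
           paste(rec$position[conflict], collapse = ", "))
    rec$isolation <- lt$isolation
    rec$knownCopies <- lt$knownCopies
  } else {
    rec <- rec[match(.orderWells(rec$position), rec$position), , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Write well records back to the canonical table format
#'
#' Inverse of [readPlateTable()]: a written table re-parses to the
#' identical record set.
#'
#' @param records data.frame of well records (as returned by
#'   [readPlateTable()])
#' @param file output path
#' @param sep field separator, `","` (default) or `"\t"`
#' @return `file`, invisibly
#' @export
writePlateTable <- function(records, file, sep = ",") {
  out <- data.frame(
    Well = records$position,
    Target = records$gene,
    Task = records$task,
    Cq = ifelse(is.na(records$cq), "undetermined",
                format(records$cq, digits = 15, trim = TRUE, scientific = FALSE)),
    Quantity = ifelse(is.na(records$knownCopies), "",
                      format(records$knownCopies, digits = 15, trim = TRUE,
                             scientific = FALSE)))
  write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Assemble a PlateExperiment from per-setting Cq tables
#'
#' One physical plate re-analysed under several instrument
#' baseline/threshold settings yields one Cq table per setting for the same
#' wells. `assembleExperiment()` stacks those tables into a
#' [PlateExperiment-class] (wells x settings) after checking that every
#' setting covers the identical set of wells with identical roles — the
#' precondition for applying one shared resampling plan to all settings.
#'
#' @param layout a [PlateLayout-class]
#' @param settingTables named list of well-record data.frames (one per
#'   baseline/threshold setting), each as returned by [readPlateTable()]
#' @return a [PlateExperiment-class]
#' @examples
#' layout <- defaultPlateLayout(nominalGmoPercent = 0.1)
#' tabfile <- system.file("extdata", "example_plate_setting1.csv",
#'                        package = "qpcrPlateVar")
#' pe <- assembleExperiment(layout, list(setting1 = readPlateTable(tabfile, layout)))
#' pe
#' @export
assembleExperiment <- function(layout, settingTables) {
  stopifnot(is(layout, "PlateLayout"))
  if (!is.list(settingTables) || length(settingTables) < 1L)
    stop("at least one setting table is required")
  if (is.null(names(settingTables)) || any(names(settingTables) == ""))
    names(settingTables) <- paste0("setting", seq_along(settingTables))

  lt <- .layoutWellTable(layout)
  ref <- settingTables[[1L]]
  for (s in names(settingTables)) {
    tab <- settingTables[[s]]
    d1 <- setdiff(lt$position, tab$position)
    d2 <- setdiff(tab$position, lt$position)
    if (length(d1) || length(d2))
      stop(sprintf(
        "setting '%s' position set differs from layout (missing: %s; extra: %s)",
        s,
        if (length(d1)) paste(d1, collapse = ", ") else "none",
        if (length(d2)) paste(d2, collapse = ", ") else "none"))
  }

  cq <- vapply(settingTables, function(tab) {
    tab$cq[match(lt$position, tab$position)]
  }, numeric(nrow(lt)))
  cq <- matrix(cq, nrow = nrow(lt),
               dimnames = list(lt$position, names(settingTables)))

  se <- SummarizedExperiment(
    assays = list(cq = cq),
    rowData = S4Vectors::DataFrame(
      gene = lt$gene, task = lt$task,
      isolation = lt$isolation, knownCopies = lt$knownCopies,
      row.names = lt$position),
    metadata = list(layout = layout))
  new("PlateExperiment", se)
}
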