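#' Read a Y-STR haplotype table
#'
#' Reads a delimited text file (CSV or TSV, detected from the header line)
#' with one row per sample: a sample-ID column followed by one column per
#' panel locus. Locus headers are matched case-insensitively through a fixed
#' alias map (`"Y-GATA-H4"`, `"YGATAH4"`, ... all resolve to the canonical
#' name). DYS385 may come as two columns (`DYS385a`, `DYS385b`) or as a
#' single column holding both calls (`"13,17"` or `"13-17"`).
#'
#' Empty cells (and `NA`/`-`/`.` placeholders) become missing loci; malformed
#' allele text such as `"x"` or `"24.15"` is an error naming the row and
#' column. Unknown locus columns and duplicate sample IDs are errors.
#'
#' @param path file path.
#' @param panel target [LocusPanel-class]; the file must provide every panel
#'   locus (default PPY23).
#' @param name dataset name (defaults to the file name).
#' @param boundsAction passed to [ystrPopulation()].
#' @return a [YstrPopulation-class].
#' @export
readHaplotypes <- function(path, panel = ystrPanel("PPY23"), name = NULL,
                           boundsAction = "missing") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("haplotype table needs a sample column plus loci",
                          call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  body <- df[, -1L, drop = FALSE]
  canon <- normalizeLocusName(names(body))

  cols <- panelColumns(panel)
  mat <- matrix(NA_character_, nrow = nrow(body), ncol = length(cols),
                dimnames = list(ids, cols))
  amel <- rep(FALSE, nrow(body))
  for (j in seq_along(canon)) {
    nm <- canon[j]
    cells <- trimws(body[[j]])
    cells[cells %in% c("-", ".", "")] <- NA_character_
    if (nm %in% c("AMELOGENIN", "AMELY")) {
      amel <- !is.na(cells) & toupper(cells) %in% c("DEL", "Y-", "YDEL", "1", "TRUE")
      next
    }
    if (nm %in% panel@multiCopy) {          # single combined DYS385 column
      parts <- strsplit(ifelse(is.na(cells), ",", cells), "[,;/-]")
      a <- trimws(vapply(parts, `[`, "", 1L))
      b <- trimws(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", ""))
      a[!nzchar(a)] <- NA_character_; b[!nzchar(b)] <- NA_character_
      .checkAlleles(a, ids, names(body)[j])
      .checkAlleles(b, ids, names(body)[j])
      lc <- locusColumns(panel, nm)
      mat[, lc[1L]] <- a; mat[, lc[2L]] <- b
    } else if (nm %in% cols) {
      .checkAlleles(cells, ids, names(body)[j])
      mat[, nm] <- cells
    } else {
      stop("unknown locus column: '", names(body)[j], "'", call. = FALSE)
    }
  }
  ystrPopulation(mat, panel = panel,
                 name = if (is.null(name)) basename(path) else name,
                 amelYDeleted = amel, boundsAction = boundsAction)
}

.checkAlleles <- function(x, ids, column) {
  bad <- !is.na(x) & !grepl("^[0-9]{1,2}(\\.[0-9])?$", x)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed allele '%s' at row '%s', column '%s'",
                 x[i], ids[i], column), call. = FALSE)
  }
}

#' Write a haplotype table
#'
#' One row per sample, sample ID first, then one column per locus slot;
#' missing calls are written as empty cells. The output reads back with
#' [readHaplotypes()].
#'
#' @param object a [YstrPopulation-class].
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
writeHaplotypes <- function(object, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = sampleIds(object), object@calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Split a dataset into complete and partial profiles
#'
#' Partial profiles (one or more loci failed to type) are excluded from all
#' downstream statistics; this partitions the dataset without loss or
#' duplication.
#'
#' @param object a [YstrPopulation-class].
#' @return list with elements `complete` and `excluded`, both
#'   [YstrPopulation-class] on the same panel.
#' @export
filterComplete <- function(object) {
  keep <- isComplete(object)
  list(complete = subsetSamples(object, keep),
       excluded = subsetSamples(object, !keep))
}

#' Restrict a dataset to a sub-panel
#'
#' Keeps only the target panel's loci; every target locus must belong to the
#' dataset's panel. A haplotype complete on the larger panel is complete on
#' any sub-panel.
#'
#' @param object a [YstrPopulation-class].
#' @param target a [LocusPanel-class] whose loci are a subset of the
#'   dataset's.
#' @return a [YstrPopulation-class] on `target`.
#' @export
subsetPanel <- function(object, target) {
  extra <- setdiff(target@loci, object@panel@loci)
  if (length(extra))
    stop("target panel loci absent from dataset panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  new("YstrPopulation", name = object@name, panel = target,
      calls = object@calls[, panelColumns(target), drop = FALSE],
      amelYDeleted = object@amelYDeleted)
}

#' Display formatting of forensic parameters
#'
#' Forensic summary tables conventionally show parameters truncated (not
#' rounded) to four decimals: DC = 94/95 = 0.98947... is displayed as
#' 0.9894. Full precision is always retained internally and in JSON output;
#' this helper only produces the display string.
#'
#' @param x numeric vector.
#' @param digits decimals kept (default 4).
#' @return character vector of fixed-width decimal strings.
#' @export
displayTrunc <- function(x, digits = 4L) {
  formatC(trunc(x * 10^digits) / 10^digits, format = "f", digits = digits)
}

#' Write / read a forensic report
#'
#' `writeReport()` writes a [ForensicReport-class] either as JSON (full
#' numeric precision; round-trips exactly through [readReport()]) or as a
#' human-readable CSV table with values rounded half-even to 4 decimals,
#' matching customary display precision.
#'
#' @param report a [ForensicReport-class].
#' @param path output path.
#' @param format `"json"` (lossless) or `"csv"` (display table).
#' @export
writeReport <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- list(
      n = report@n, h = report@h, singletons = report@singletons,
      haplotype_diversity = report@haplotypeDiversity,
      discrimination_capacity = report@discriminationCapacity,
      haplotype_match_probability = report@haplotypeMatchProbability,
      mean_gd = report@meanGD, se_gd = report@seGD,
      total_distinct_alleles = report@totalDistinctAlleles,
      mean_alleles_per_locus = report@meanAllelesPerLocus,
      per_locus = report@perLocus,
      freqs = lapply(report@freqs, as.list)
    )
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         na = "null")
  } else {
    tab <- report@perLocus
    num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "nAlleles"
    tab[num] <- lapply(tab[num], displayTrunc)
    hapRows <- data.frame(
      locus = c("[haplotype] n", "[haplotype] h", "[haplotype] singletons",
                "[haplotype] HD", "[haplotype] DC", "[haplotype] PM",
                "[haplotype] mean GD", "[haplotype] SE GD"),
      value = c(report@n, report@h, report@singletons,
                displayTrunc(c(report@haplotypeDiversity,
                               report@discriminationCapacity,
                               report@haplotypeMatchProbability,
                               report@meanGD, report@seGD))),
      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(hapRows, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE, append = TRUE)
  }
  invisible(path)
}

#' @rdname writeReport
#' @return `readReport()` returns the report fields as a list (numeric
#'   values at full precision).
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
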