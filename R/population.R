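#' Construct a Y-STR population dataset
#'
#' Builds a [YstrPopulation-class] from a matrix or data.frame of allele
#' designations (rows = samples, columns = panel locus slots, see
#' [panelColumns()]). The DYS385a/b pair is stored sorted ascending, so
#' haplotype comparison is order-insensitive. Allele designations outside the
#' sanity range of 5-45 repeats are treated as missing with a warning
#' (`boundsAction = "error"` turns this into a hard failure).
#'
#' @param calls character matrix or data.frame of allele designations;
#'   rownames (or a first column named `sample`/`sample_id`) give sample IDs.
#' @param panel a [LocusPanel-class] (default PPY23).
#' @param name dataset name.
#' @param amelYDeleted optional logical vector flagging samples carrying the
#'   amelogenin Y-deletion (metadata only, never a statistical locus).
#' @param boundsAction what to do with alleles outside 5-45 repeats:
#'   `"missing"` (warn and blank) or `"error"`.
#' @return a [YstrPopulation-class].
#' @export
ystrPopulation <- function(calls, panel = ystrPanel("PPY23"), name = "population",
                           amelYDeleted = NULL,
                           boundsAction = c("missing", "error")) {
  boundsAction <- match.arg(boundsAction)
  cols <- panelColumns(panel)
  if (is.data.frame(calls)) {
    idcol <- which(tolower(names(calls)) %in% c("sample", "sample_id", "sampleid", "id"))
    if (length(idcol)) {
      rn <- as.character(calls[[idcol[1]]])
      calls <- calls[, -idcol[1], drop = FALSE]
      rownames(calls) <- rn
    }
    calls <- as.matrix(calls)
  }
  storage.mode(calls) <- "character"
  calls[!is.na(calls) & !nzchar(trimws(calls))] <- NA_character_
  missingCols <- setdiff(cols, colnames(calls))
  if (length(missingCols))
    stop("call matrix lacks panel locus slot(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  calls <- calls[, cols, drop = FALSE]
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))

  p <- parseAllele(calls)   # validates designations
  out <- !is.na(p$repeats) & (p$repeats < 5L | p$repeats > 45L)
  if (any(out)) {
    offenders <- unique(calls[matrix(out, nrow(calls))])
    if (boundsAction == "error")
      stop("allele(s) outside sanity bounds 5-45 repeats: ",
           paste(offenders, collapse = ", "), call. = FALSE)
    warning("allele(s) outside sanity bounds 5-45 repeats treated as missing: ",
            paste(offenders, collapse = ", "), call. = FALSE)
    calls[matrix(out, nrow(calls))] <- NA_character_
  }

  # store multi-copy pairs sorted ascending
  for (loc in panel@multiCopy) {
    lc <- locusColumns(panel, loc)
    if (all(lc %in% cols) && nrow(calls) > 0) {
      pair <- calls[, lc, drop = FALSE]
      vals <- matrix(alleleValue(pair), ncol = 2)
      swap <- !is.na(vals[, 1]) & !is.na(vals[, 2]) & vals[, 1] > vals[, 2]
      if (any(swap)) {
        tmp <- pair[swap, 1]
        pair[swap, 1] <- pair[swap, 2]
        pair[swap, 2] <- tmp
        calls[, lc] <- pair
      }
    }
  }

  if (is.null(amelYDeleted)) amelYDeleted <- rep(FALSE, nrow(calls))
  new("YstrPopulation", name = name, panel = panel, calls = calls,
      amelYDeleted = amelYDeleted)
}

#' @describeIn ystrPopulation number of samples.
#' @param object a [YstrPopulation-class].
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname ystrPopulation
#' @export
setMethod("nSamples", "YstrPopulation", function(object) nrow(object@calls))

#' @describeIn ystrPopulation sample identifiers.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ystrPopulation
#' @export
setMethod("sampleIds", "YstrPopulation", function(object) rownames(object@calls))

#' @rdname ystrPopulation
#' @export
setMethod("loci", "YstrPopulation", function(object) object@panel@loci)

#' @describeIn ystrPopulation the dataset's [LocusPanel-class].
#' @export
setGeneric("panel", function(object) standardGeneric("panel"))

#' @rdname ystrPopulation
#' @export
setMethod("panel", "YstrPopulation", function(object) object@panel)

#' @describeIn ystrPopulation the call matrix (allele designations, `NA` =
#'   missing).
#' @export
setGeneric("alleleCalls", function(object) standardGeneric("alleleCalls"))

#' @rdname ystrPopulation
#' @export
setMethod("alleleCalls", "YstrPopulation", function(object) object@calls)

#' Per-sample missing loci
#'
#' A locus is missing for a sample when any of its slots failed to type (for
#' DYS385, either copy). A haplotype is complete when it has no missing loci.
#'
#' @param object a [YstrPopulation-class].
#' @return named list: sample ID -> character vector of missing locus names.
#' @export
missingLoci <- function(object) {
  pn <- object@panel
  res <- lapply(seq_len(nrow(object@calls)), function(i) {
    row <- object@calls[i, ]
    miss <- vapply(pn@loci, function(l) anyNA(row[locusColumns(pn, l)]), logical(1))
    pn@loci[miss]
  })
  names(res) <- rownames(object@calls)
  res
}

#' @describeIn missingLoci logical vector: which samples are complete.
#' @export
isComplete <- function(object) {
  !apply(is.na(object@calls), 1, any)
}

# subset a population by sample index, keeping metadata aligned
subsetSamples <- function(object, idx) {
  new("YstrPopulation", name = object@name, panel = object@panel,
      calls = object@calls[idx, , drop = FALSE],
      amelYDeleted = object@amelYDeleted[idx])
}

setMethod("show", "YstrPopulation", function(object) {
  comp <- sum(isComplete(object))
  cat(sprintf("YstrPopulation '%s' on panel %s\n", object@name, object@panel@name))
  cat(sprintf("  %d samples (%d complete, %d partial), %d locus slots\n",
              nSamples(object), comp, nSamples(object) - comp,
              ncol(object@calls)))
})
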