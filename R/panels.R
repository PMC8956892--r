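# Built-in panel definitions. Locus slot counts: Minimal 9, PowerPlexY12 12,
# Yfiler17 17, PPY23 23 (DYS385 occupies two slots each time).
.MINIMAL_LOCI <- c("DYS19", "DYS385", "DYS389I", "DYS389II", "DYS390",
                   "DYS391", "DYS392", "DYS393")
.PPY12_LOCI   <- c(.MINIMAL_LOCI, "DYS437", "DYS438", "DYS439")
.YFILER17_LOCI <- c(.PPY12_LOCI, "DYS448", "DYS456", "DYS458", "DYS635",
                    "YGATAH4")
.PPY23_LOCI   <- c(.YFILER17_LOCI, "DYS481", "DYS533", "DYS549", "DYS570",
                   "DYS576", "DYS643")

.PANELS <- list(
  Minimal      = .MINIMAL_LOCI,
  PowerPlexY12 = .PPY12_LOCI,
  Yfiler17     = .YFILER17_LOCI,
  PPY23        = .PPY23_LOCI
)

# fixed alias map -> canonical locus names (normalized keys: upper-case,
# alphanumerics only)
.LOCUS_ALIASES <- c(
  "YGATAH4" = "YGATAH4", "GATAH4" = "YGATAH4", "HIV" = "YGATAH4",
  "DYS385AB" = "DYS385", "DYS385" = "DYS385",
  "DYS385A" = "DYS385a", "DYS385B" = "DYS385b"
)

normalizeLocusName <- function(x) {
  if (!length(x)) return(character(0))
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  # DYS389 I/II roman numerals survive the strip (I, II are letters)
  out <- ifelse(key %in% names(.LOCUS_ALIASES), .LOCUS_ALIASES[key], key)
  # canonical names are upper-case except the a/b copy suffix
  unname(out)
}

#' Built-in Y-STR locus panels
#'
#' Returns one of the four standard forensic Y-STR panels as a
#' [LocusPanel-class]: the minimal haplotype (`"Minimal"`, 9 locus slots),
#' PowerPlex Y (`"PowerPlexY12"`, 12), Yfiler (`"Yfiler17"`, 17) and
#' PowerPlex Y23 (`"PPY23"`, 23). The panels are nested: Minimal is a subset
#' of PowerPlexY12, which is a subset of Yfiler17, which is a subset of PPY23.
#'
#' @param name panel name, one of `"Minimal"`, `"PowerPlexY12"`,
#'   `"Yfiler17"`, `"PPY23"`.
#' @return a [LocusPanel-class].
#' @examples
#' ystrPanel("PPY23")
#' @export
ystrPanel <- function(name = c("PPY23", "Yfiler17", "PowerPlexY12", "Minimal")) {
  name <- match.arg(name)
  new("LocusPanel", name = name, loci = .PANELS[[name]], multiCopy = "DYS385")
}

#' Define a custom locus panel
#'
#' For data typed on a non-standard marker set (the built-ins cover the four
#' common forensic panels, see [ystrPanel()]).
#'
#' @param name panel name.
#' @param loci ordered locus names (multi-copy loci listed once).
#' @param multiCopy loci carrying two calls per sample.
#' @return a [LocusPanel-class].
#' @export
locusPanel <- function(name, loci, multiCopy = character(0)) {
  new("LocusPanel", name = name, loci = normalizeLocusName(loci),
      multiCopy = normalizeLocusName(multiCopy))
}

#' Locus slots of a panel
#'
#' Expands multi-copy loci to their per-copy column names: DYS385 becomes
#' `DYS385a`, `DYS385b`. These are the column names of a
#' [YstrPopulation-class] call matrix; their count is the panel's slot count
#' (23 for PPY23).
#'
#' @param panel a [LocusPanel-class].
#' @return character vector of locus slot names.
#' @export
panelColumns <- function(panel) {
  unlist(lapply(panel@loci, function(l) {
    if (l %in% panel@multiCopy) paste0(l, c("a", "b")) else l
  }), use.names = FALSE)
}

# columns belonging to one locus
locusColumns <- function(panel, locus) {
  if (locus %in% panel@multiCopy) paste0(locus, c("a", "b")) else locus
}

#' @describeIn ystrPanel loci of a panel (multi-copy loci listed once).
#' @param object,panel a [LocusPanel-class] (or, for `loci`, a
#'   [YstrPopulation-class]).
#' @export
setGeneric("loci", function(object) standardGeneric("loci"))

#' @rdname ystrPanel
#' @export
setMethod("loci", "LocusPanel", function(object) object@loci)

setMethod("show", "LocusPanel", function(object) {
  cat(sprintf("LocusPanel '%s': %d loci (%d slots)\n", object@name,
              length(object@loci), length(panelColumns(object))))
  cat("  ", paste(object@loci, collapse = ", "), "\n", sep = "")
})
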