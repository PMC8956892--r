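#' @import methods
NULL

#' Y-STR locus panel
#'
#' An ordered set of Y-STR loci defining a typing panel. The four panels in
#' common forensic use are built in (see [ystrPanel()]): the minimal haplotype
#' (9 locus slots), PowerPlex Y12, Yfiler 17 and PowerPlex Y23. Multi-copy
#' loci (DYS385, typed as an a/b pair) occupy two slots but are listed once in
#' `loci` and flagged in `multiCopy`.
#'
#' @slot name panel name.
#' @slot loci ordered character vector of locus names (multi-copy loci once).
#' @slot multiCopy character vector of loci carrying two calls per sample.
#' @export
setClass("LocusPanel",
  representation(name = "character", loci = "character", multiCopy = "character")
)

setValidity("LocusPanel", function(object) {
  msgs <- character()
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
  if (anyDuplicated(object@loci)) msgs <- c(msgs, "duplicated locus names")
  if (!all(object@multiCopy %in% object@loci))
    msgs <- c(msgs, "multiCopy loci must be panel loci")
  if (length(msgs)) msgs else TRUE
})

#' A named collection of Y-STR haplotypes on a declared panel
#'
#' Holds one row per sampled male and one column per locus slot (DYS385
#' expands to two columns, `DYS385a`/`DYS385b`, stored sorted ascending).
#' Allele calls are kept as their exact text designation (`"15"`, `"24.1"`);
#' a failed or absent call is `NA`. The amelogenin Y-deletion status is
#' sample metadata only and never enters any statistic.
#'
#' @slot name dataset name.
#' @slot panel a [LocusPanel-class].
#' @slot calls character matrix, rows = samples (rownames = unique sample
#'   IDs), columns = panel locus slots.
#' @slot amelYDeleted logical vector, one flag per sample.
#' @export
setClass("YstrPopulation",
  representation(name = "character", panel = "LocusPanel",
                 calls = "matrix", amelYDeleted = "logical")
)

setValidity("YstrPopulation", function(object) {
  msgs <- character()
  cols <- panelColumns(object@panel)
  if (!identical(colnames(object@calls), cols))
    msgs <- c(msgs, "call matrix columns must match the panel locus slots")
  ids <- rownames(object@calls)
  if (nrow(object@calls) > 0L) {
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
      msgs <- c(msgs, "sample IDs must be unique non-empty rownames")
  }
  if (length(object@amelYDeleted) != nrow(object@calls))
    msgs <- c(msgs, "amelYDeleted must have one entry per sample")
  vals <- object@calls[!is.na(object@calls)]
  bad <- vals[!grepl("^[0-9]{1,2}(\\.[0-9])?$", vals)]
  if (length(bad))
    msgs <- c(msgs, paste0("invalid allele designation(s): ",
                           paste(unique(bad)[1:min(3, length(unique(bad)))], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Forensic summary of a Y-STR population
#'
#' Container returned by [forensicSummary()]: per-locus allele frequencies and
#' forensic parameters, plus the haplotype-level summary (haplotype diversity,
#' discrimination capacity, match probability, singleton count).
#'
#' @slot perLocus data.frame of per-locus parameters (one row per locus).
#' @slot freqs named list: locus -> named numeric vector of allele frequencies.
#' @slot n,h,singletons sample count, distinct haplotype count, singletons.
#' @slot haplotypeDiversity,discriminationCapacity,haplotypeMatchProbability
#'   haplotype-level parameters.
#' @slot meanGD,seGD mean per-locus gene diversity and its standard error
#'   across loci (`seGD` is `NA` for a single-locus panel).
#' @slot totalDistinctAlleles,meanAllelesPerLocus allele-count summaries.
#' @export
setClass("ForensicReport",
  representation(perLocus = "data.frame", freqs = "list",
                 n = "integer", h = "integer", singletons = "integer",
                 haplotypeDiversity = "numeric",
                 discriminationCapacity = "numeric",
                 haplotypeMatchProbability = "numeric",
                 meanGD = "numeric", seGD = "numeric",
                 totalDistinctAlleles = "integer",
                 meanAllelesPerLocus = "numeric")
)

setValidity("ForensicReport", function(object) {
  msgs <- character()
  if (object@h > object@n) msgs <- c(msgs, "h cannot exceed n")
  if (object@singletons > object@h) msgs <- c(msgs, "singletons cannot exceed h")
  if (length(msgs)) msgs else TRUE
})

#' Analysis of molecular variance (AMOVA) result
#'
#' Two-level AMOVA on squared repeat-count distances, partitioning molecular
#' variance among and within populations. `phiST` is the Rst analogue
#' sigma2Among / (sigma2Among + sigma2Within); the p-value comes from
#' permuting individual-to-population labels.
#'
#' @slot ssdAmong,ssdWithin sums of squared deviations.
#' @slot dfAmong,dfWithin degrees of freedom (K-1 and N-K).
#' @slot sigma2Among,sigma2Within variance components.
#' @slot phiST the Phi-st / Rst estimate.
#' @slot pValue permutation p-value, (b+1)/(m+1) convention.
#' @slot nPermutations,seed permutation count and RNG seed used.
#' @slot groupSizes named integer vector of population sizes.
#' @export
setClass("AmovaResult",
  representation(ssdAmong = "numeric", ssdWithin = "numeric",
                 dfAmong = "integer", dfWithin = "integer",
                 sigma2Among = "numeric", sigma2Within = "numeric",
                 phiST = "numeric", pValue = "numeric",
                 nPermutations = "integer", seed = "integer",
                 groupSizes = "integer")
)

#' Pairwise Rst distance matrix with permutation p-values
#'
#' @slot labels population names.
#' @slot rst symmetric matrix of pairwise Rst (negative estimates retained).
#' @slot pValues matrix of permutation p-values (diagonal `NA`).
#' @slot nPermutations,seed permutation settings.
#' @export
setClass("RstMatrix",
  representation(labels = "character", rst = "matrix", pValues = "matrix",
                 nPermutations = "integer", seed = "integer")
)

setValidity("RstMatrix", function(object) {
  msgs <- character()
  d <- object@rst
  if (nrow(d) != ncol(d) || nrow(d) != length(object@labels))
    msgs <- c(msgs, "rst must be square with one row per label")
  else {
    if (max(abs(d - t(d))) > 1e-12) msgs <- c(msgs, "rst must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) msgs <- c(msgs, "rst diagonal must be zero")
  }
  p <- object@pValues[!is.na(object@pValues)]
  if (any(p < 0 | p > 1)) msgs <- c(msgs, "p-values must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Per-haplogroup Y-STR allele frequency table
#'
#' The reference object for Bayesian haplogroup assignment: for each
#' haplogroup and locus, a discrete allele frequency distribution (summing to
#' one), plus prior haplogroup probabilities. See [readHaplogroupTable()] and
#' [makeHaplogroupFixture()].
#'
#' @slot haplogroups haplogroup names.
#' @slot loci loci covered by the table.
#' @slot freq nested list: haplogroup -> locus -> named numeric vector
#'   (names = allele designations, values = probabilities).
#' @slot priors named numeric vector of prior probabilities, summing to one.
#' @export
setClass("HaplogroupTable",
  representation(haplogroups = "character", loci = "character",
                 freq = "list", priors = "numeric")
)

setValidity("HaplogroupTable", function(object) {
  msgs <- character()
  if (!setequal(names(object@freq), object@haplogroups))
    msgs <- c(msgs, "freq must have one entry per haplogroup")
  if (abs(sum(object@priors) - 1) > 1e-9)
    msgs <- c(msgs, "priors must sum to 1")
  if (!setequal(names(object@priors), object@haplogroups))
    msgs <- c(msgs, "priors must be named by haplogroup")
  for (hg in object@haplogroups) {
    for (loc in names(object@freq[[hg]])) {
      s <- sum(object@freq[[hg]][[loc]])
      if (abs(s - 1) > 1e-9) {
        msgs <- c(msgs, sprintf("frequencies for %s/%s sum to %.6f, not 1", hg, loc, s))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})
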