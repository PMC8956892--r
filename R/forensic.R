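requireComplete <- function(object, what) {
  if (!all(isComplete(object)))
    stop(what, " requires a complete dataset; run filterComplete() first",
         call. = FALSE)
  invisible(object)
}

# haplotype identity string; DYS385 pair is stored sorted, so comparison is
# order-insensitive
haplotypeKey <- function(object) {
  apply(object@calls, 1L, paste, collapse = "|")
}

#' Per-locus allele frequencies
#'
#' Relative allele frequencies at every panel locus. Single-copy loci use
#' denominator n (one allele per male); the multi-copy DYS385 pools both
#' copies with denominator 2n.
#'
#' @param object a complete [YstrPopulation-class].
#' @return named list: locus -> named numeric vector of frequencies (names
#'   are allele designations, sorted by allele value; each vector sums to 1).
#' @export
alleleFrequencies <- function(object) {
  requireComplete(object, "alleleFrequencies()")
  if (nSamples(object) < 1L) stop("empty dataset", call. = FALSE)
  pn <- object@panel
  res <- lapply(pn@loci, function(l) {
    obs <- as.vector(object@calls[, locusColumns(pn, l)])
    tab <- table(obs)
    f <- as.numeric(tab) / length(obs)
    names(f) <- names(tab)
    f[match(sortAlleles(names(f)), names(f))]
  })
  names(res) <- pn@loci
  res
}

#' Gene diversity (unbiased heterozygosity analogue)
#'
#' Nei's unbiased estimator GD = n/(n-1) * (1 - sum p_i^2): the probability
#' that two alleles drawn without replacement differ, clipped to [0, 1].
#'
#' @param freqs numeric vector of allele frequencies (must sum to 1).
#' @param n number of sampled alleles at the locus (>= 2).
#' @return gene diversity in [0, 1].
#' @examples
#' geneDiversity(c(0.5, 0.5), 10)  # 10/9 * 0.5
#' @export
geneDiversity <- function(freqs, n) {
  if (n < 2) stop("gene diversity needs n >= 2", call. = FALSE)
  gd <- n / (n - 1) * (1 - sum(freqs^2))
  min(max(gd, 0), 1)
}

#' Polymorphic information content (Botstein)
#'
#' PIC = 1 - sum p_i^2 - (sum p_i^2)^2 + sum p_i^4, the classical marker
#' informativeness index.
#'
#' @param freqs numeric vector of allele frequencies.
#' @return PIC in [0, 1].
#' @export
picValue <- function(freqs) {
  s2 <- sum(freqs^2)
  1 - s2 - s2^2 + sum(freqs^4)
}

#' Match probability
#'
#' PM = sum p_i^2, the probability that two random draws match; the power of
#' discrimination is its complement PD = 1 - PM. At `level = "locus"` the
#' p_i are allele frequencies; at `level = "haplotype"` they are full-profile
#' haplotype frequencies.
#'
#' @param object a complete [YstrPopulation-class], or (for `level =
#'   "locus"`) a numeric frequency vector.
#' @param level `"haplotype"` (default) or `"locus"`.
#' @return PM in (0, 1].
#' @export
matchProbability <- function(object, level = c("haplotype", "locus")) {
  level <- match.arg(level)
  if (is.numeric(object)) return(sum(object^2))
  requireComplete(object, "matchProbability()")
  if (level == "haplotype") {
    p <- as.numeric(table(haplotypeKey(object))) / nSamples(object)
    sum(p^2)
  } else {
    vapply(alleleFrequencies(object), function(f) sum(f^2), numeric(1))
  }
}

#' Haplotype counts and frequency spectrum
#'
#' @param object a complete [YstrPopulation-class].
#' @return list with `h` (distinct haplotypes), `singletons` (haplotypes
#'   observed exactly once) and `spectrum` (table of haplotype multiplicity,
#'   e.g. how many haplotypes were seen once, twice, ...).
#' @export
haplotypeCounts <- function(object) {
  requireComplete(object, "haplotypeCounts()")
  counts <- table(haplotypeKey(object))
  list(h = length(counts),
       singletons = sum(counts == 1L),
       spectrum = table(as.integer(counts)))
}

#' Haplotype diversity
#'
#' HD = n (1 - sum p_i^2) / (n - 1) with p_i the relative frequency of the
#' i-th distinct haplotype: the probability that two haplotypes drawn without
#' replacement differ. Equals the fraction of differing unordered sample
#' pairs.
#'
#' @param object a complete [YstrPopulation-class] with n >= 2.
#' @return HD in [0, 1].
#' @export
haplotypeDiversity <- function(object) {
  requireComplete(object, "haplotypeDiversity()")
  n <- nSamples(object)
  if (n < 2L) stop("haplotype diversity needs n >= 2", call. = FALSE)
  p <- as.numeric(table(haplotypeKey(object))) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Discrimination capacity
#'
#' DC = h / n, the number of distinct haplotypes over the sample size.
#'
#' @param object a complete [YstrPopulation-class].
#' @return DC in (0, 1].
#' @export
discriminationCapacity <- function(object) {
  requireComplete(object, "discriminationCapacity()")
  haplotypeCounts(object)$h / nSamples(object)
}

#' Full forensic summary of a Y-STR dataset
#'
#' Assembles the per-locus parameters (distinct allele count, gene diversity,
#' PIC, PM, PD) and the haplotype-level parameters (HD, DC, haplotype match
#' probability, singleton count) into a [ForensicReport-class].
#'
#' The multi-copy DYS385 locus is summarised once from its pooled a/b allele
#' distribution (denominator 2n), while the mean-alleles-per-locus figure
#' divides by the panel's slot count (23 for PPY23), the customary way these
#' panels are reported.
#'
#' @param object a complete [YstrPopulation-class] with n >= 2.
#' @return a [ForensicReport-class].
#' @export
forensicSummary <- function(object) {
  requireComplete(object, "forensicSummary()")
  n <- nSamples(object)
  if (n < 2L) stop("forensic summary needs n >= 2", call. = FALSE)
  pn <- object@panel
  freqs <- alleleFrequencies(object)

  perLocus <- do.call(rbind, lapply(pn@loci, function(l) {
    f <- freqs[[l]]
    nAll <- length(locusColumns(pn, l)) * n    # sampled allele count
    pm <- sum(f^2)
    data.frame(locus = l,
               nAlleles = length(f),
               geneDiversity = geneDiversity(f, nAll),
               pic = picValue(f),
               matchProbability = pm,
               powerOfDiscrimination = 1 - pm,
               stringsAsFactors = FALSE)
  }))

  hc <- haplotypeCounts(object)
  nSlots <- length(panelColumns(pn))
  totalDistinct <- sum(perLocus$nAlleles)
  gd <- perLocus$geneDiversity
  seGD <- if (length(gd) > 1L) stats::sd(gd) / sqrt(length(gd)) else NA_real_

  new("ForensicReport",
      perLocus = perLocus, freqs = freqs,
      n = as.integer(n), h = as.integer(hc$h),
      singletons = as.integer(hc$singletons),
      haplotypeDiversity = haplotypeDiversity(object),
      discriminationCapacity = hc$h / n,
      haplotypeMatchProbability = matchProbability(object, "haplotype"),
      meanGD = mean(gd), seGD = seGD,
      totalDistinctAlleles = as.integer(totalDistinct),
      meanAllelesPerLocus = totalDistinct / nSlots)
}

setMethod("show", "ForensicReport", function(object) {
  cat("ForensicReport\n")
  cat(sprintf("  n = %d, distinct haplotypes h = %d, singletons = %d\n",
              object@n, object@h, object@singletons))
  cat(sprintf("  HD = %.4f, DC = %.4f, haplotype PM = %.5f\n",
              object@haplotypeDiversity, object@discriminationCapacity,
              object@haplotypeMatchProbability))
  cat(sprintf("  mean GD = %.3f +/- %.3f (SE over %d loci)\n",
              object@meanGD, object@seGD, nrow(object@perLocus)))
  cat(sprintf("  %d distinct alleles, %.3f per locus slot\n",
              object@totalDistinctAlleles, object@meanAllelesPerLocus))
})
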