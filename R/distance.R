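# Numeric repeat values for the single-copy locus slots used in distance
# computations. DYS385a/b is excluded by default (multi-copy loci are
# conventionally left out of Rst); DYS389II optionally has DYS389I
# subtracted (it is typed as a compound fragment containing DYS389I).
distanceValueMatrix <- function(object, includeDYS385 = FALSE,
                                subtractDYS389 = FALSE) {
  pn <- object@panel
  single <- setdiff(pn@loci, pn@multiCopy)
  V <- matrix(alleleValue(object@calls[, single, drop = FALSE]),
              nrow = nSamples(object),
              dimnames = list(sampleIds(object), single))
  if (subtractDYS389 && all(c("DYS389I", "DYS389II") %in% single))
    V[, "DYS389II"] <- V[, "DYS389II"] - V[, "DYS389I"]
  V
}

# squared repeat-distance matrix over all samples of a stacked call matrix
squaredDistanceMatrix <- function(object, includeDYS385 = FALSE,
                                  subtractDYS389 = FALSE) {
  V <- distanceValueMatrix(object, includeDYS385, subtractDYS389)
  D <- as.matrix(stats::dist(V))^2
  if (includeDYS385 && "DYS385" %in% object@panel@multiCopy) {
    lc <- locusColumns(object@panel, "DYS385")
    a <- alleleValue(object@calls[, lc[1]])
    b <- alleleValue(object@calls[, lc[2]])
    d1 <- outer(a, a, "-")^2 + outer(b, b, "-")^2   # aligned pairing
    d2 <- outer(a, b, "-")^2 + outer(b, a, "-")^2   # crossed pairing
    D <- D + pmin(d1, d2)
  }
  D
}

#' Squared repeat-count distance between two haplotypes
#'
#' The microsatellite distance underlying Rst: the sum over loci of the
#' squared difference in repeat number, with micro-variants valued as
#' repeats + variant/10. The unordered DYS385 pair (when included)
#' contributes the minimum over its two possible pairings.
#'
#' @param a,b named character vectors of allele designations (rows of a
#'   [YstrPopulation-class] call matrix), complete on `panel`.
#' @param panel the [LocusPanel-class] both haplotypes are typed on.
#' @param includeDYS385 include the multi-copy locus (default `FALSE`,
#'   mirroring usual Rst practice).
#' @param subtractDYS389 subtract DYS389I from DYS389II before differencing.
#' @return non-negative squared distance.
#' @export
haplotypeDistance <- function(a, b, panel = ystrPanel("PPY23"),
                              includeDYS385 = FALSE, subtractDYS389 = FALSE) {
  cols <- panelColumns(panel)
  if (anyNA(a[cols]) || anyNA(b[cols]))
    stop("both haplotypes must be complete on the panel", call. = FALSE)
  pop <- ystrPopulation(rbind(S1 = a[cols], S2 = b[cols]), panel = panel)
  squaredDistanceMatrix(pop, includeDYS385, subtractDYS389)[1, 2]
}

# stack populations into one call matrix + group labels; panels must agree
stackPopulations <- function(pops) {
  pn <- pops[[1]]@panel
  for (p in pops)
    if (!identical(p@panel@loci, pn@loci))
      stop("all populations must share one panel", call. = FALSE)
  calls <- do.call(rbind, lapply(seq_along(pops), function(k) {
    m <- pops[[k]]@calls
    rownames(m) <- paste0("g", k, ".", rownames(m))
    m
  }))
  stacked <- new("YstrPopulation", name = "stacked", panel = pn, calls = calls,
                 amelYDeleted = rep(FALSE, nrow(calls)))
  sizes <- vapply(pops, nSamples, integer(1))
  names(sizes) <- vapply(seq_along(pops), function(k) {
    nm <- pops[[k]]@name
    if (is.null(nm) || !nzchar(nm)) paste0("pop", k) else nm
  }, character(1))
  list(pop = stacked, group = rep(seq_along(pops), sizes), sizes = sizes)
}
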