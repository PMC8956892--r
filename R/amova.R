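# AMOVA sums of squares and variance components from a squared-distance
# matrix D and an integer group labelling. Excoffier's identity: the sum of
# squared deviations of a group equals the sum of its pairwise squared
# distances divided by group size.
amovaComponents <- function(D, group) {
  N <- nrow(D)
  K <- length(unique(group))
  sizes <- tabulate(group, nbins = max(group))
  sizes <- sizes[sizes > 0]
  ssdTotal <- sum(D) / (2 * N)
  ssdWithin <- 0
  for (k in unique(group)) {
    idx <- group == k
    ssdWithin <- ssdWithin + sum(D[idx, idx]) / (2 * sum(idx))
  }
  ssdAmong <- ssdTotal - ssdWithin
  dfAmong <- K - 1L
  dfWithin <- N - K
  sigma2W <- ssdWithin / dfWithin
  nBar <- (N - sum(sizes^2) / N) / (K - 1)
  sigma2A <- (ssdAmong / dfAmong - sigma2W) / nBar
  denom <- sigma2A + sigma2W
  phi <- if (denom > 0) sigma2A / denom else 0
  list(ssdTotal = ssdTotal, ssdAmong = ssdAmong, ssdWithin = ssdWithin,
       dfAmong = dfAmong, dfWithin = dfWithin,
       sigma2A = sigma2A, sigma2W = sigma2W, phi = phi)
}

# permutation phi only (shared ssdTotal precomputed by caller would not help
# much; D subsetting dominates)
permutedPhi <- function(D, group) {
  amovaComponents(D, sample(group))$phi
}

#' Analysis of molecular variance between Y-STR populations
#'
#' Two-level AMOVA on squared repeat-count distances (see
#' [haplotypeDistance()]): partitions the total sum of squared deviations
#' into among- and within-population components, estimates the variance
#' components by equating mean squares to their expectations, and reports
#' Phi-st (the Rst analogue) = sigma2_among / (sigma2_among + sigma2_within).
#' Significance comes from permuting individuals across populations; the
#' p-value is (b + 1) / (m + 1) with b the number of permutations whose
#' Phi-st is at least the observed one.
#'
#' @param groups list of >= 2 complete [YstrPopulation-class] objects on the
#'   same panel, each with >= 2 samples.
#' @param nPerm number of label permutations (>= 1; default 1000).
#' @param seed RNG seed, recorded in the result.
#' @param includeDYS385,subtractDYS389 distance options, see
#'   [haplotypeDistance()].
#' @return an [AmovaResult-class].
#' @export
amova <- function(groups, nPerm = 1000L, seed = 1L,
                  includeDYS385 = FALSE, subtractDYS389 = FALSE) {
  if (length(groups) < 2L) stop("amova needs >= 2 populations", call. = FALSE)
  sizes <- vapply(groups, nSamples, integer(1))
  if (any(sizes < 2L)) stop("every population needs >= 2 samples", call. = FALSE)
  if (nPerm < 1L) stop("nPerm must be >= 1", call. = FALSE)
  for (g in groups) requireComplete(g, "amova()")
  st <- stackPopulations(groups)
  D <- squaredDistanceMatrix(st$pop, includeDYS385, subtractDYS389)
  obs <- amovaComponents(D, st$group)
  set.seed(seed)
  b <- sum(vapply(seq_len(nPerm), function(i) permutedPhi(D, st$group),
                  numeric(1)) >= obs$phi)
  new("AmovaResult",
      ssdAmong = obs$ssdAmong, ssdWithin = obs$ssdWithin,
      dfAmong = as.integer(obs$dfAmong), dfWithin = as.integer(obs$dfWithin),
      sigma2Among = obs$sigma2A, sigma2Within = obs$sigma2W,
      phiST = obs$phi, pValue = (b + 1) / (nPerm + 1),
      nPermutations = as.integer(nPerm), seed = as.integer(seed),
      groupSizes = st$sizes)
}

#' Pairwise Rst matrix over populations
#'
#' Runs a two-population [amova()] for every pair and collects the Phi-st
#' estimates (negative values retained as computed) and permutation p-values.
#' Each pair gets its own deterministic seed derived from `seed`.
#'
#' @param pops named list of >= 2 complete [YstrPopulation-class] objects.
#' @param nPerm permutations per pair.
#' @param seed base RNG seed.
#' @param includeDYS385,subtractDYS389 distance options.
#' @return an [RstMatrix-class].
#' @export
pairwiseRst <- function(pops, nPerm = 1000L, seed = 1L,
                        includeDYS385 = FALSE, subtractDYS389 = FALSE) {
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)
  labels <- vapply(seq_along(pops), function(k) {
    nm <- pops[[k]]@name
    if (is.null(nm) || !nzchar(nm)) paste0("pop", k) else nm
  }, character(1))
  K <- length(pops)
  d <- matrix(0, K, K, dimnames = list(labels, labels))
  p <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  pair <- 0L
  for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
    pair <- pair + 1L
    res <- amova(pops[c(i, j)], nPerm = nPerm, seed = seed + pair,
                 includeDYS385 = includeDYS385, subtractDYS389 = subtractDYS389)
    d[i, j] <- d[j, i] <- res@phiST
    p[i, j] <- p[j, i] <- res@pValue
  }
  new("RstMatrix", labels = labels, rst = d, pValues = p,
      nPermutations = as.integer(nPerm), seed = as.integer(seed))
}

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (squared repeat-count distances)\n")
  cat(sprintf("  populations: %d (%s)\n", length(object@groupSizes),
              paste(object@groupSizes, collapse = "/")))
  cat(sprintf("  SSD among = %.4f (df %d), within = %.4f (df %d)\n",
              object@ssdAmong, object@dfAmong, object@ssdWithin, object@dfWithin))
  cat(sprintf("  sigma2 among = %.4f, within = %.4f\n",
              object@sigma2Among, object@sigma2Within))
  cat(sprintf("  Phi-st (Rst) = %.4f, p = %.4f (%d permutations, seed %d)\n",
              object@phiST, object@pValue, object@nPermutations, object@seed))
})

setMethod("show", "RstMatrix", function(object) {
  cat(sprintf("Pairwise Rst over %d populations (%d permutations)\n",
              length(object@labels), object@nPermutations))
  print(round(object@rst, 4))
})
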