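# small custom single-copy panel for compact fixtures
tinyPanel <- function(nLoci = 3L) {
  locusPanel(paste0("tiny", nLoci), paste0("DYS", 100 + seq_len(nLoci)))
}

# population from a character matrix/data.frame on a tiny panel
tinyPop <- function(calls, panel = NULL, name = "test") {
  if (is.null(panel)) panel <- tinyPanel(ncol(calls))
  if (is.null(rownames(calls))) rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  colnames(calls) <- panelColumns(panel)
  ystrPopulation(calls, panel = panel, name = name)
}

# one-locus population from a numeric repeat vector (for AMOVA oracles)
oneLocusPop <- function(values, name = "g") {
  tinyPop(matrix(as.character(values), ncol = 1), panel = tinyPanel(1),
          name = name)
}

# population of labelled haplotypes: each distinct label becomes a distinct
# two-locus haplotype (alleles kept inside the 5-45 sanity band), repeated
# per its multiplicity
labelledPop <- function(labels) {
  idx <- match(labels, unique(labels)) - 1L
  stopifnot(max(idx) < 20 * 20)
  tinyPop(cbind(as.character(10L + idx %/% 20L),
                as.character(10L + idx %% 20L)),
          panel = tinyPanel(2))
}

# ---- independent oracles ----------------------------------------------------

# HD oracle: fraction of unordered sample pairs with differing haplotypes
pairwiseMismatchHD <- function(pop) {
  key <- apply(alleleCalls(pop), 1, paste, collapse = "|")
  n <- length(key)
  diff <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (key[i] != key[j]) diff <- diff + 1L
  diff / choose(n, 2)
}

# brute-force one-locus AMOVA via explicit ANOVA decomposition (independent
# of the package's pairwise-distance route)
bruteAmova1Locus <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x); K <- length(groups)
  ssdTotal <- sum((x - mean(x))^2)
  ssdWithin <- 0
  for (k in seq_len(K)) ssdWithin <- ssdWithin + sum((groups[[k]] - mean(groups[[k]]))^2)
  ssdAmong <- ssdTotal - ssdWithin
  sizes <- lengths(groups)
  sigma2W <- ssdWithin / (N - K)
  nBar <- (N - sum(sizes^2) / N) / (K - 1)
  sigma2A <- (ssdAmong / (K - 1) - sigma2W) / nBar
  denom <- sigma2A + sigma2W
  list(ssdAmong = ssdAmong, ssdWithin = ssdWithin,
       sigma2A = sigma2A, sigma2W = sigma2W,
       phi = if (denom > 0) sigma2A / denom else 0)
}

# random small synthetic dataset with duplicated haplotypes (for HD identity)
randomTinyPop <- function(n = NULL, nLoci = 3L) {
  if (is.null(n)) n <- sample(4:25, 1)
  base <- matrix(as.character(sample(8:14, n * nLoci, replace = TRUE)),
                 nrow = n)
  # plant duplicates with 50% chance to exercise p_i > 1/n
  if (stats::runif(1) < 0.5 && n >= 4) {
    k <- sample(2:floor(n / 2), 1)
    base[seq_len(k), ] <- base[rep(1, k), ]
  }
  tinyPop(base, panel = tinyPanel(nLoci))
}

# write a PPY23 haplotype CSV (two-column DYS385 dialect) and return the path
writePpy23Csv <- function(pop, path = tempfile(fileext = ".csv")) {
  writeHaplotypes(pop, path)
  path
}
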