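test_that("allele frequencies sum to 1 and use the right denominators", {
  # DYS391-style single-copy symmetry
  pop <- oneLocusPop(c(10, 10, 11, 11))
  f <- alleleFrequencies(pop)[[1]]
  expect_equal(unname(f), c(0.5, 0.5))

  # one sample: every single-copy allele at frequency 1; the DYS385 pair
  # pools to 0.5/0.5 when its two copies differ
  one <- simulatePopulation(simulationConfig(nSamples = 1,
                                             partialProfileCount = 0,
                                             seed = 4))$population
  f1 <- alleleFrequencies(one)
  expect_true(all(unlist(f1[setdiff(names(f1), "DYS385")]) == 1))
  expect_equal(sum(f1$DYS385), 1)

  # multi-copy DYS385 pools both copies over 2n
  cols <- panelColumns(ystrPanel("PPY23"))
  calls <- matrix("12", 2, length(cols), dimnames = list(c("s1", "s2"), cols))
  calls[, "DYS385a"] <- c("13", "13")
  calls[, "DYS385b"] <- c("17", "13")
  pop385 <- ystrPopulation(calls)
  f385 <- alleleFrequencies(pop385)[["DYS385"]]
  expect_equal(f385[["13"]], 3 / 4)
  expect_equal(f385[["17"]], 1 / 4)

  # frequency vectors always sum to 1 on a large simulated dataset
  big <- filterComplete(simulatePopulation(simulationConfig(seed = 8))$population)$complete
  sums <- vapply(alleleFrequencies(big), sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("gene diversity matches its closed form and edge cases", {
  expect_equal(geneDiversity(c(0.5, 0.5), 10), (10 / 9) * 0.5, tolerance = 1e-12)
  expect_equal(geneDiversity(1, 5), 0)
  # all n alleles distinct -> exactly 1
  for (n in c(2, 7, 31))
    expect_equal(geneDiversity(rep(1 / n, n), n), 1, tolerance = 1e-12)
  expect_error(geneDiversity(c(0.5, 0.5), 1), "n >= 2")
})

test_that("PIC matches the Botstein form and is bounded by heterozygosity", {
  expect_equal(picValue(1), 0)
  expect_equal(picValue(c(0.5, 0.5)), 0.375, tolerance = 1e-12)
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- as.numeric(stats::rmultinom(1, 50, rep(1, k))) / 50
    p <- p[p > 0]
    expect_lte(picValue(p), 1 - sum(p^2) + 1e-12)
    expect_gte(picValue(p), 0)
  }
})

test_that("haplotype counting matches a brute-force pairwise oracle", {
  pop <- labelledPop(c("A", "A", "B", "C", "D"))
  hc <- haplotypeCounts(pop)
  expect_equal(hc$h, 4)
  expect_equal(hc$singletons, 3)

  same <- labelledPop(rep("A", 6))
  expect_equal(haplotypeCounts(same)$h, 1)
  expect_equal(haplotypeCounts(same)$singletons, 0)

  # planted duplicates: distinct count equals n minus duplicated pairs found
  # by O(n^2) scan
  set.seed(77)
  for (i in 1:20) {
    pop <- randomTinyPop()
    key <- apply(alleleCalls(pop), 1, paste, collapse = "|")
    bruteH <- length(unique(key))
    bruteSingle <- sum(table(key) == 1)
    hc <- haplotypeCounts(pop)
    expect_equal(hc$h, bruteH)
    expect_equal(hc$singletons, bruteSingle)
  }
})

test_that("DYS385 haplotype identity is order-insensitive", {
  cols <- panelColumns(ystrPanel("PPY23"))
  calls <- matrix("12", 2, length(cols), dimnames = list(c("s1", "s2"), cols))
  calls[1, c("DYS385a", "DYS385b")] <- c("13", "17")
  calls[2, c("DYS385a", "DYS385b")] <- c("17", "13")
  pop <- ystrPopulation(calls)
  expect_equal(haplotypeCounts(pop)$h, 1)
})

test_that("haplotype diversity equals the pairwise-mismatch oracle", {
  expect_equal(haplotypeDiversity(labelledPop(c("A", "A", "B", "C", "D"))),
               9 / 10, tolerance = 1e-12)
  expect_equal(haplotypeDiversity(labelledPop(letters[1:8])), 1, tolerance = 1e-12)
  expect_equal(haplotypeDiversity(labelledPop(rep("A", 5))), 0)

  set.seed(303)
  for (i in 1:25) {
    pop <- randomTinyPop()
    expect_equal(haplotypeDiversity(pop), pairwiseMismatchHD(pop),
                 tolerance = 1e-12)
  }
})

test_that("discrimination capacity is h/n with its boundary cases", {
  pop <- labelledPop(c(seq_len(94), 1))     # 95 samples, 94 distinct
  expect_equal(discriminationCapacity(pop), 94 / 95, tolerance = 1e-12)
  expect_equal(discriminationCapacity(labelledPop(letters[1:6])), 1)
  expect_equal(discriminationCapacity(labelledPop(rep("A", 100))), 0.01)
  # DC = 1 iff all haplotypes unique, HD = 1 iff all unique
  expect_lt(haplotypeDiversity(pop), 1)
  expect_lt(discriminationCapacity(pop), 1)
})

test_that("match probability at both levels", {
  allU <- labelledPop(seq_len(95))
  expect_equal(matchProbability(allU), 1 / 95, tolerance = 1e-12)
  expect_equal(matchProbability(labelledPop(rep("A", 4))), 1)
  expect_equal(matchProbability(c(0.5, 0.5)), 0.5)
  lp <- matchProbability(oneLocusPop(c(10, 10, 11, 11)), level = "locus")
  expect_equal(unname(lp), 0.5)
})

test_that("forensicSummary assembles consistent reports", {
  pop <- filterComplete(simulatePopulation(simulationConfig(
    nSamples = 60, seed = 12))$population)$complete
  rep_ <- forensicSummary(pop)

  # PM + PD = 1 exactly, per locus
  expect_equal(rep_@perLocus$matchProbability +
                 rep_@perLocus$powerOfDiscrimination,
               rep(1, nrow(rep_@perLocus)))
  expect_true(rep_@singletons <= rep_@h && rep_@h <= rep_@n)
  expect_equal(rep_@meanAllelesPerLocus, rep_@totalDistinctAlleles / 23)
  expect_equal(rep_@haplotypeMatchProbability +
                 0, matchProbability(pop), tolerance = 1e-12)
  # 0 <= PIC <= GD*(n-1)/n <= GD <= 1 per locus (single-copy loci: n draws)
  n <- nSamples(pop)
  single <- rep_@perLocus$locus != "DYS385"
  expect_true(all(rep_@perLocus$pic[single] <=
                    rep_@perLocus$geneDiversity[single] * (n - 1) / n + 1e-12))
  expect_true(all(rep_@perLocus$geneDiversity <= 1))
  expect_true(all(rep_@perLocus$pic >= 0))

  # merging two copies of a dataset leaves allele frequencies unchanged
  doubledCalls <- rbind(alleleCalls(pop), alleleCalls(pop))
  rownames(doubledCalls) <- paste0("d", seq_len(nrow(doubledCalls)))
  doubled <- ystrPopulation(doubledCalls, panel = panel(pop))
  expect_equal(alleleFrequencies(doubled), alleleFrequencies(pop),
               tolerance = 1e-12)
})

test_that("140 distinct alleles over a 23-slot panel average 6.087 per locus", {
  # construct a complete PPY23 dataset carrying exactly 140 distinct alleles
  target <- c(rep(7, 10), rep(6, 8), rep(6, 4))   # per-locus distinct counts
  # 22 loci rows (DYS385 pooled); 10*7 + 12*6 = 142 -> trim to 140
  target[1:2] <- 6
  expect_equal(sum(target), 140)
  pn <- ystrPanel("PPY23")
  n <- 40
  set.seed(5)
  calls <- matrix(NA_character_, n, 23, dimnames = list(sprintf("S%02d", 1:n),
                                                        panelColumns(pn)))
  for (j in seq_along(loci(pn))) {
    loc <- loci(pn)[j]
    k <- target[j]
    alleles <- as.character(9 + seq_len(k))
    lc <- if (loc == "DYS385") c("DYS385a", "DYS385b") else loc
    for (cc in lc)
      calls[, cc] <- c(alleles, sample(alleles, n - k, replace = TRUE))
  }
  pop <- ystrPopulation(calls, panel = pn)
  rep_ <- forensicSummary(pop)
  expect_equal(rep_@totalDistinctAlleles, 140L)
  expect_equal(rep_@meanAllelesPerLocus, 140 / 23, tolerance = 1e-12)
  expect_equal(round(rep_@meanAllelesPerLocus, 3), 6.087)
})

test_that("single-locus summary reports SE as absent", {
  pop <- oneLocusPop(c(10, 11, 12, 12))
  rep_ <- forensicSummary(pop)
  expect_true(is.na(rep_@seGD))
})
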