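test_that("built-in panels have the right slot counts and are nested", {
  sizes <- c(Minimal = 9L, PowerPlexY12 = 12L, Yfiler17 = 17L, PPY23 = 23L)
  for (nm in names(sizes))
    expect_length(panelColumns(ystrPanel(nm)), sizes[[nm]])
  chain <- lapply(names(sizes), ystrPanel)
  for (i in 1:3)
    expect_true(all(loci(chain[[i]]) %in% loci(chain[[i + 1]])))
})

test_that("haplotype tables round-trip through CSV, both DYS385 dialects", {
  sim <- simulatePopulation(simulationConfig(nSamples = 12,
                                             partialProfileCount = 2,
                                             seed = 42))
  pop <- sim$population
  path <- writePpy23Csv(pop)
  back <- readHaplotypes(path, name = pop@name)
  expect_identical(alleleCalls(back), alleleCalls(pop))

  # one-column combined dialect ("13-17"; a comma would need CSV quoting);
  # a half-typed pair has no combined representation, so use complete rows
  comp <- filterComplete(pop)$complete
  df <- data.frame(sample = sampleIds(comp), alleleCalls(comp),
                   check.names = FALSE)
  ab <- paste0(df$DYS385a, "-", df$DYS385b)
  df$DYS385a <- NULL; df$DYS385b <- NULL
  df$DYS385 <- ab
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE, quote = FALSE, na = "")
  back2 <- readHaplotypes(p2)
  expect_identical(alleleCalls(back2)[, "DYS385a"], alleleCalls(comp)[, "DYS385a"])
  expect_identical(alleleCalls(back2)[, "DYS385b"], alleleCalls(comp)[, "DYS385b"])
})

test_that("reader flags bad input precisely", {
  path <- tempfile(fileext = ".csv")
  pop <- simulatePopulation(simulationConfig(nSamples = 3,
                                             partialProfileCount = 0,
                                             seed = 1))$population
  df <- data.frame(sample = sampleIds(pop), alleleCalls(pop),
                   check.names = FALSE)

  bad <- df; bad$DYS19[2] <- "x"
  write.csv(bad, path, row.names = FALSE, quote = FALSE, na = "")
  expect_error(readHaplotypes(path), "'x' at row 'S002', column 'DYS19'")

  bad <- df; names(bad)[names(bad) == "DYS19"] <- "DYS999"
  write.csv(bad, path, row.names = FALSE, quote = FALSE, na = "")
  expect_error(readHaplotypes(path), "unknown locus column.*DYS999")

  bad <- df; bad$sample[2] <- bad$sample[1]
  write.csv(bad, path, row.names = FALSE, quote = FALSE, na = "")
  expect_error(readHaplotypes(path), "duplicate sample ID")

  # blank cell becomes a missing locus, never a silent zero
  blank <- df; blank$DYS391[1] <- ""
  write.csv(blank, path, row.names = FALSE, quote = FALSE, na = "")
  got <- readHaplotypes(path)
  expect_identical(missingLoci(got)[["S001"]], "DYS391")

  # alias headers resolve to canonical names
  ali <- df; names(ali)[names(ali) == "YGATAH4"] <- "Y-GATA-H4"
  write.csv(ali, path, row.names = FALSE, quote = FALSE, na = "")
  expect_identical(alleleCalls(readHaplotypes(path))[, "YGATAH4"],
                   alleleCalls(pop)[, "YGATAH4"])
})

test_that("allele sanity bounds: out-of-range treated as missing or error", {
  calls <- matrix(c("15", "50", "12", "13"), 2, 2,
                  dimnames = list(c("a", "b"), NULL))
  expect_warning(pop <- tinyPop(calls, panel = tinyPanel(2)), "sanity bounds")
  expect_identical(missingLoci(pop)[["b"]], "DYS101")
  expect_error(suppressWarnings(
    ystrPopulation(`colnames<-`(calls, panelColumns(tinyPanel(2))),
                   panel = tinyPanel(2), boundsAction = "error")),
    "sanity bounds")
})

test_that("filterComplete partitions the dataset", {
  sim <- simulatePopulation(simulationConfig(nSamples = 30,
                                             partialProfileCount = 5,
                                             seed = 9))
  f <- filterComplete(sim$population)
  expect_equal(nSamples(f$complete) + nSamples(f$excluded), 30)
  expect_true(all(isComplete(f$complete)))
  expect_false(any(isComplete(f$excluded)))
  expect_setequal(c(sampleIds(f$complete), sampleIds(f$excluded)),
                  sampleIds(sim$population))

  allComplete <- filterComplete(f$complete)
  expect_equal(nSamples(allComplete$excluded), 0)
})

test_that("panel subsetting behaves and commutes with completeness filtering", {
  sim <- simulatePopulation(simulationConfig(nSamples = 40,
                                             partialProfileCount = 6,
                                             seed = 5))
  pop <- sim$population
  minimal <- subsetPanel(pop, ystrPanel("Minimal"))
  expect_length(panelColumns(panel(minimal)), 9)

  same <- subsetPanel(pop, ystrPanel("PPY23"))
  expect_identical(alleleCalls(same), alleleCalls(pop))

  expect_error(subsetPanel(minimal, ystrPanel("PPY23")), "absent")

  # distinct haplotype count is non-increasing under subsetting
  comp <- filterComplete(pop)$complete
  h23 <- haplotypeCounts(comp)$h
  h9 <- haplotypeCounts(subsetPanel(comp, ystrPanel("Minimal")))$h
  expect_lte(h9, h23)

  # complete-on-PPY23 haplotypes stay complete on any sub-panel, so
  # subset-then-filter equals filter-then-subset for them
  a <- filterComplete(subsetPanel(pop, ystrPanel("Yfiler17")))$complete
  b <- subsetPanel(filterComplete(pop)$complete, ystrPanel("Yfiler17"))
  expect_true(all(sampleIds(b) %in% sampleIds(a)))
})

test_that("forensic report round-trips JSON at full precision, CSV at 4 dp", {
  pop <- simulatePopulation(simulationConfig(nSamples = 25,
                                             partialProfileCount = 0,
                                             seed = 2))$population
  rep_ <- forensicSummary(pop)
  jpath <- tempfile(fileext = ".json")
  writeReport(rep_, jpath, "json")
  back <- readReport(jpath)
  expect_equal(back$n, rep_@n)
  expect_equal(back$haplotype_diversity, rep_@haplotypeDiversity,
               tolerance = 1e-15)
  expect_equal(back$mean_gd, rep_@meanGD, tolerance = 1e-15)
  expect_equal(back$per_locus$geneDiversity, rep_@perLocus$geneDiversity,
               tolerance = 1e-15)

  cpath <- tempfile(fileext = ".csv")
  writeReport(rep_, cpath, "csv")
  lines <- readLines(cpath)
  dcLine <- grep("\\[haplotype\\] DC", lines, value = TRUE)
  expect_match(dcLine, displayTrunc(rep_@discriminationCapacity), fixed = TRUE)
})

test_that("displayed values truncate to 4 decimals (0.98947... shows 0.9894)", {
  expect_identical(displayTrunc(94 / 95), "0.9894")
  expect_identical(displayTrunc(0.5), "0.5000")
  expect_identical(displayTrunc(1), "1.0000")
  # a 95-sample dataset with one duplicated haplotype displays DC = 0.9894
  pop <- labelledPop(c(seq_len(94), 1))
  expect_identical(displayTrunc(discriminationCapacity(pop)), "0.9894")
})
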