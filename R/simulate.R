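# Modal PPY23 reference haplotype used as the ancestral state of the
# simulator (plausible repeat numbers; haplogroup founders are offsets from
# these).
.BASE_MODAL <- c(
  DYS19 = 15, DYS385a = 13, DYS385b = 17, DYS389I = 13, DYS389II = 30,
  DYS390 = 24, DYS391 = 10, DYS392 = 11, DYS393 = 12, DYS437 = 14,
  DYS438 = 11, DYS439 = 11, DYS448 = 19, DYS456 = 15, DYS458 = 16,
  DYS635 = 23, YGATAH4 = 12, DYS481 = 24, DYS533 = 11, DYS549 = 12,
  DYS570 = 18, DYS576 = 17, DYS643 = 10
)

# loci at which incomplete-repeat (micro-variant) alleles are allowed to
# arise in simulation
.MICROVARIANT_LOCI <- c("DYS481", "DYS576", "DYS390")

# default haplogroup mixture: R1a-dominated with substantial H and L, the
# structure typical of North-Indian caste populations
.DEFAULT_MIX <- c(R1a = 0.57, H = 0.15, L = 0.13, J2b = 0.05, Q = 0.03,
                  R1b = 0.03, E1b1b = 0.01, G2a = 0.01, I2a = 0.01, J1 = 0.01)

#' Simulation settings for the Y-STR population generator
#'
#' The generator follows a star genealogy: each sampled male descends
#' independently from his haplogroup's founder haplotype, accumulating
#' single-step (+/-1 repeat) mutations over `depthGenerations` generations at
#' `mutationRate` per locus per generation. Defaults emulate a ~100-male
#' PowerPlex Y23 sample with a singleton-dominated haplotype spectrum: a few
#' micro-variant alleles at the loci where they are commonly seen
#' (DYS481, DYS576, DYS390) and a handful of partial profiles.
#'
#' @param nSamples males to simulate (default 100).
#' @param panel a [LocusPanel-class] (default PPY23).
#' @param haplogroupMix named proportions summing to 1 (default an
#'   R1a-dominated ten-haplogroup mixture).
#' @param mutationRate per-locus per-generation single-step mutation
#'   probability (default 0.002, the typical Y-STR order of magnitude).
#' @param depthGenerations generations since the founders (default 600).
#' @param microvariantRate per-sample probability of a micro-variant allele
#'   at each eligible locus (default 0.03).
#' @param partialProfileCount samples to blank random loci in (default 4).
#' @param founders optional named list: haplogroup -> integer repeat vector
#'   over the panel slots; generated from the seed when `NULL`.
#' @param seed RNG seed; the full configuration (seed included) is carried in
#'   the simulator output so any dataset can be regenerated.
#' @return a `ystr_sim_config` list.
#' @export
simulationConfig <- function(nSamples = 100L, panel = ystrPanel("PPY23"),
                             haplogroupMix = .DEFAULT_MIX,
                             mutationRate = 0.002, depthGenerations = 600L,
                             microvariantRate = 0.03,
                             partialProfileCount = 4L,
                             founders = NULL, seed = 1L) {
  if (abs(sum(haplogroupMix) - 1) > 1e-9)
    stop("haplogroup proportions must sum to 1", call. = FALSE)
  if (mutationRate < 0 || mutationRate > 1 || microvariantRate < 0 ||
      microvariantRate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (partialProfileCount > nSamples)
    stop("more partial profiles requested than samples", call. = FALSE)
  structure(list(nSamples = as.integer(nSamples), panel = panel,
                 haplogroupMix = haplogroupMix, mutationRate = mutationRate,
                 depthGenerations = as.integer(depthGenerations),
                 microvariantRate = microvariantRate,
                 partialProfileCount = as.integer(partialProfileCount),
                 founders = founders, seed = as.integer(seed)),
            class = "ystr_sim_config")
}

# reflect repeat counts into the 5-45 sanity band
.reflectBounds <- function(x) {
  for (i in 1:4) {          # converges immediately for realistic step counts
    x <- ifelse(x > 45, 90 - x, x)
    x <- ifelse(x < 5, 10 - x, x)
  }
  x
}

# founder repeat vectors per haplogroup: offsets from the base modal
# haplotype, drawn once from the current RNG stream
.makeFounders <- function(cfg) {
  cols <- panelColumns(cfg$panel)
  base <- ifelse(cols %in% names(.BASE_MODAL), .BASE_MODAL[cols], 12)
  names(base) <- cols
  founders <- lapply(names(cfg$haplogroupMix), function(hg) {
    .reflectBounds(base + sample(-3:3, length(cols), replace = TRUE))
  })
  names(founders) <- names(cfg$haplogroupMix)
  founders
}

# apply t generations of stepwise mutation to an integer repeat vector;
# returns list(repeats, nMutations)
.mutate <- function(repeats, rate, t) {
  k <- stats::rpois(length(repeats), rate * t)
  net <- 2L * stats::rbinom(length(repeats), k, 0.5) - k
  list(repeats = .reflectBounds(repeats + net), nMutations = sum(k))
}

# core sampler: star genealogy from given founders, using the ambient RNG
.simulateFromFounders <- function(cfg, founders, prefix = "S") {
  cols <- panelColumns(cfg$panel)
  hgs <- sample(names(cfg$haplogroupMix), cfg$nSamples, replace = TRUE,
                prob = cfg$haplogroupMix)
  calls <- matrix(NA_character_, cfg$nSamples, length(cols),
                  dimnames = list(sprintf("%s%03d", prefix,
                                          seq_len(cfg$nSamples)), cols))
  nMut <- integer(cfg$nSamples)
  variants <- matrix(0L, cfg$nSamples, length(cols))
  mvCols <- intersect(.MICROVARIANT_LOCI, cols)
  for (i in seq_len(cfg$nSamples)) {
    m <- .mutate(founders[[hgs[i]]], cfg$mutationRate, cfg$depthGenerations)
    nMut[i] <- m$nMutations
    rep_i <- m$repeats
    var_i <- integer(length(cols))
    for (loc in mvCols) {
      if (stats::runif(1) < cfg$microvariantRate)
        var_i[match(loc, cols)] <- sample(c(1L, 2L, 3L), 1L,
                                          prob = c(0.6, 0.2, 0.2))
    }
    calls[i, ] <- formatAllele(rep_i, var_i)
  }
  # blank random loci in the designated partial profiles
  if (cfg$partialProfileCount > 0L) {
    partial <- sample(cfg$nSamples, cfg$partialProfileCount)
    for (i in partial) {
      nBlank <- sample(1:3, 1L)
      calls[i, sample(length(cols), nBlank)] <- NA_character_
    }
  }
  pop <- ystrPopulation(calls, panel = cfg$panel, name = paste0(prefix, "-sim"))
  truth <- data.frame(sample = sampleIds(pop), haplogroup = hgs,
                      nMutations = nMut, stringsAsFactors = FALSE)
  list(population = pop, truth = truth, config = cfg)
}

#' Simulate a Y-STR population under the stepwise mutation model
#'
#' Draws each sample's haplogroup from the configured mixture, then mutates
#' the haplogroup founder haplotype along an independent lineage of
#' `depthGenerations` generations (Poisson number of +/-1-repeat steps per
#' locus, fair step direction). Micro-variant alleles are injected at
#' DYS481/DYS576/DYS390 only; repeat counts are reflected back into the 5-45
#' band. The same seed always reproduces the identical dataset.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `population` (a [YstrPopulation-class], possibly with
#'   partial profiles), `truth` (data.frame: per-sample haplogroup and
#'   mutation count) and `config` (the settings used, seed included).
#' @export
simulatePopulation <- function(cfg = simulationConfig()) {
  set.seed(cfg$seed)
  founders <- if (is.null(cfg$founders)) .makeFounders(cfg) else cfg$founders
  .simulateFromFounders(cfg, founders)
}

#' Simulate a pair of populations with known divergence
#'
#' Both populations descend from the same founder haplotypes; each
#' population's founders first drift independently for `divergenceT`
#' generations of stepwise mutation, then samples radiate from them as in
#' [simulatePopulation()]. Rst between the pair grows with `divergenceT`,
#' which makes the AMOVA/Rst machinery testable against planted truth.
#'
#' @param cfg a [simulationConfig()] (applied to each population).
#' @param divergenceT generations of independent divergence (0 = none).
#' @return list of two elements as returned by [simulatePopulation()], with
#'   disjoint sample IDs (`A...`, `B...`).
#' @export
simulateDivergentPair <- function(cfg = simulationConfig(), divergenceT = 0L) {
  set.seed(cfg$seed)
  founders <- if (is.null(cfg$founders)) .makeFounders(cfg) else cfg$founders
  lapply(c("A", "B"), function(prefix) {
    drifted <- lapply(founders, function(f)
      .mutate(f, cfg$mutationRate, divergenceT)$repeats)
    out <- .simulateFromFounders(cfg, drifted, prefix = prefix)
    out$population@name <- paste0("pop", prefix)
    out
  })
}

#' Separable haplogroup-classifier fixture
#'
#' Builds a synthetic [HaplogroupTable-class] in which each haplogroup's
#' allele distribution at every locus is unimodal (probabilities 0.1/0.8/0.1
#' on the mode and its neighbours) with modes placed `separation` repeats
#' apart between neighbouring haplogroups, plus a sampler that draws
#' haplotypes with known truth labels. `separation = 0` collapses all
#' haplogroups onto one distribution (classifier accuracy at chance);
#' `separation >= 4` separates them essentially perfectly.
#'
#' @param nHaplogroups,nLoci fixture dimensions (defaults 10 and 15).
#' @param separation repeats between neighbouring haplogroup modes.
#' @param seed seed for the sampler's draws.
#' @return list with `table` (a [HaplogroupTable-class]), `panel` (the
#'   custom [LocusPanel-class] the fixture lives on) and `sampler`, a
#'   `function(n)` returning `list(population, truth)`.
#' @export
makeHaplogroupFixture <- function(nHaplogroups = 10L, nLoci = 15L,
                                  separation = 4L, seed = 1L) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  hgNames <- c("E1b1b", "G2a", "H", "I2a", "J1", "J2b", "L", "Q", "R1a",
               "R1b", paste0("HG", seq_len(max(0, nHaplogroups - 10))))
  hgNames <- hgNames[seq_len(nHaplogroups)]
  lociPool <- setdiff(.PPY23_LOCI, "DYS385")
  lociNames <- if (nLoci <= length(lociPool)) lociPool[seq_len(nLoci)] else
    c(lociPool, paste0("LOC", seq_len(nLoci - length(lociPool))))
  pn <- locusPanel("hgFixture", lociNames)
  freq <- lapply(seq_len(nHaplogroups), function(g) {
    perLocus <- lapply(seq_len(nLoci), function(j) {
      center <- 7L + (j %% 2L) + (g - 1L) * separation
      f <- c(0.1, 0.8, 0.1)
      names(f) <- as.character(center + (-1L:1L))
      f
    })
    names(perLocus) <- lociNames
    perLocus
  })
  names(freq) <- hgNames
  tab <- haplogroupTable(freq)
  sampler <- function(n) {
    hgs <- sample(hgNames, n, replace = TRUE)
    calls <- t(vapply(hgs, function(hg) {
      vapply(lociNames, function(loc) {
        f <- freq[[hg]][[loc]]
        sample(names(f), 1L, prob = f)
      }, character(1))
    }, character(nLoci)))
    rownames(calls) <- sprintf("F%04d", seq_len(n))
    list(population = ystrPopulation(calls, panel = pn, name = "hg-fixture"),
         truth = data.frame(sample = rownames(calls), haplogroup = hgs,
                            stringsAsFactors = FALSE))
  }
  set.seed(seed)
  list(table = tab, panel = pn, sampler = sampler)
}
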