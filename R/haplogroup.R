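#' Construct a haplogroup allele-frequency table
#'
#' @param freq nested list: haplogroup -> locus -> named numeric vector of
#'   allele probabilities, each summing to 1 (tolerance 1e-9).
#' @param priors optional named prior probabilities; default uniform over the
#'   haplogroups.
#' @return a [HaplogroupTable-class].
#' @export
haplogroupTable <- function(freq, priors = NULL) {
  hgs <- names(freq)
  if (is.null(priors)) {
    priors <- rep(1 / length(hgs), length(hgs))
    names(priors) <- hgs
  }
  lociSet <- unique(unlist(lapply(freq, names), use.names = FALSE))
  new("HaplogroupTable", haplogroups = hgs, loci = lociSet,
      freq = freq, priors = priors)
}

#' Read / write haplogroup allele-frequency tables
#'
#' The on-disk format is long delimited text with columns `haplogroup`,
#' `locus`, `allele`, `frequency`. Frequencies must sum to one within each
#' (haplogroup, locus) block to 1e-9; a block that does not normalize is
#' rejected. `writeHaplogroupTable()` round-trips exactly.
#'
#' @param path file path (CSV, or TSV if the header contains a tab).
#' @param priors optional named priors (default uniform).
#' @return a [HaplogroupTable-class].
#' @export
readHaplogroupTable <- function(path, priors = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("haplogroup", "locus", "allele", "frequency")
  if (!all(need %in% tolower(names(df))))
    stop("haplogroup table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  names(df) <- tolower(names(df))
  df$locus <- normalizeLocusName(df$locus)
  parseAllele(df$allele)   # validate designations
  df$frequency <- as.numeric(df$frequency)
  freq <- lapply(split(df, df$haplogroup), function(hd) {
    lapply(split(hd, hd$locus), function(ld) {
      f <- ld$frequency
      names(f) <- ld$allele
      if (abs(sum(f) - 1) > 1e-9)
        stop(sprintf("frequencies for %s/%s sum to %.6f, not 1",
                     ld$haplogroup[1], ld$locus[1], sum(f)), call. = FALSE)
      f
    })
  })
  haplogroupTable(freq, priors)
}

#' @rdname readHaplogroupTable
#' @param table a [HaplogroupTable-class].
#' @export
writeHaplogroupTable <- function(table, path) {
  rows <- do.call(rbind, lapply(table@haplogroups, function(hg) {
    do.call(rbind, lapply(names(table@freq[[hg]]), function(loc) {
      f <- table@freq[[hg]][[loc]]
      data.frame(haplogroup = hg, locus = loc, allele = names(f),
                 frequency = f, stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# log-likelihood of one haplotype under one haplogroup's frequency profile
.hgLogLik <- function(callsRow, pn, table, hg, eps) {
  fr <- table@freq[[hg]]
  ll <- 0
  for (loc in intersect(pn@loci, names(fr))) {
    f <- fr[[loc]]
    obs <- callsRow[locusColumns(pn, loc)]   # 1 value, or 2 for DYS385
    for (a in obs) {
      p <- if (a %in% names(f)) unname(f[a]) else eps
      if (p <= 0) return(-Inf)
      ll <- ll + log(p)
    }
  }
  ll
}

#' Bayesian haplogroup assignment from Y-STR alleles
#'
#' Assigns each haplotype the haplogroup maximising the posterior
#' `prior(g) * prod_locus f_g(allele)`, the Whit-Athey-style score, using a
#' per-haplogroup allele-frequency table. Alleles unseen in a haplogroup's
#' table receive a floor frequency `eps` (an unseen allele should penalize a
#' haplogroup, not eliminate it); with `eps = 0` a haplotype whose likelihood
#' vanishes under every haplogroup is reported as unclassifiable rather than
#' raising an error. The two DYS385 calls are scored as exchangeable
#' observations against a single per-locus distribution. Loci present in the
#' dataset but absent from the table are skipped with a warning.
#'
#' @param object a complete [YstrPopulation-class].
#' @param table a [HaplogroupTable-class].
#' @param eps floor frequency for unseen alleles (default 1e-3).
#' @return data.frame with one row per sample: `sample`, `haplogroup` (`NA`
#'   if unclassifiable), `posterior`, `logLik`, `runnerUp`,
#'   `runnerUpPosterior`. Posteriors are normalized over all haplogroups.
#' @export
assignHaplogroup <- function(object, table, eps = 1e-3) {
  requireComplete(object, "assignHaplogroup()")
  pn <- object@panel
  skipped <- setdiff(pn@loci, table@loci)
  if (length(skipped))
    warning("loci absent from the frequency table skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  hgs <- table@haplogroups
  logPrior <- log(table@priors[hgs])
  out <- lapply(seq_len(nSamples(object)), function(i) {
    row <- object@calls[i, ]
    ll <- vapply(hgs, function(hg) .hgLogLik(row, pn, table, hg, eps),
                 numeric(1))
    score <- logPrior + ll
    if (all(!is.finite(score))) {
      return(data.frame(sample = sampleIds(object)[i], haplogroup = NA_character_,
                        posterior = NA_real_, logLik = NA_real_,
                        runnerUp = NA_character_, runnerUpPosterior = NA_real_,
                        stringsAsFactors = FALSE))
    }
    post <- exp(score - max(score[is.finite(score)]))
    post[!is.finite(post)] <- 0
    post <- post / sum(post)
    ord <- order(post, decreasing = TRUE)
    data.frame(sample = sampleIds(object)[i],
               haplogroup = hgs[ord[1]], posterior = post[ord[1]],
               logLik = ll[ord[1]],
               runnerUp = if (length(hgs) > 1L) hgs[ord[2]] else NA_character_,
               runnerUpPosterior = if (length(hgs) > 1L) post[ord[2]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Population haplogroup spectrum
#'
#' Assigns every sample with [assignHaplogroup()] and tabulates the
#' percentage of classified samples per haplogroup (summing to 100);
#' unclassifiable samples are counted separately.
#'
#' @inheritParams assignHaplogroup
#' @return list with `percent` (named numeric, percentages over classified
#'   samples), `counts` (named integer) and `nUnclassified`.
#' @export
haplogroupSpectrum <- function(object, table, eps = 1e-3) {
  calls <- assignHaplogroup(object, table, eps)
  ok <- !is.na(calls$haplogroup)
  counts <- base::table(factor(calls$haplogroup[ok], levels = table@haplogroups))
  counts <- counts[counts > 0]
  pct <- 100 * as.numeric(counts) / sum(counts)
  names(pct) <- names(counts)
  list(percent = pct,
       counts = stats::setNames(as.integer(counts), names(counts)),
       nUnclassified = sum(!ok))
}

setMethod("show", "HaplogroupTable", function(object) {
  cat(sprintf("HaplogroupTable: %d haplogroups x %d loci\n",
              length(object@haplogroups), length(object@loci)))
  cat("  ", paste(object@haplogroups, collapse = ", "), "\n", sep = "")
})
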