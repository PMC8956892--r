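#' Run the full Y-STR analysis pipeline
#'
#' Executes the standard workflow over one or more haplotype tables: load,
#' exclude partial profiles, compute the forensic summary per population,
#' then — when at least two populations are given — pairwise Rst, an overall
#' AMOVA and a classical MDS embedding, and — when a haplogroup frequency
#' table is given — per-sample haplogroup calls and the population spectrum.
#' All outputs land in `outputDir` as CSV/JSON next to a machine-readable
#' `manifest.json` recording package version, seeds and per-population
#' input/excluded/complete counts. A failing stage aborts with an error
#' naming the stage; outputs of earlier stages are kept alongside a
#' `FAILED` marker file.
#'
#' @param config named list (or path to a YAML/JSON file with the same
#'   fields): `populations` — named character vector/list of haplotype-table
#'   paths, or a list of [YstrPopulation-class] objects; `panel` — panel
#'   name (default `"PPY23"`); `outputDir`; `nPerm` (default 1000); `seed`
#'   (default 1); `smoothingEps` (default 1e-3); `includeDYS385`,
#'   `subtractDYS389` (default `FALSE`); `mdsDims` (default 2);
#'   `haplogroupTable` — optional path or [HaplogroupTable-class].
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(panel = "PPY23", nPerm = 1000L, seed = 1L, smoothingEps = 1e-3,
         includeDYS385 = FALSE, subtractDYS389 = FALSE, mdsDims = 2L,
         haplogroupTable = NULL),
    config)
  if (is.null(cfg$outputDir)) stop("config needs an outputDir", call. = FALSE)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name, "\n", conditionMessage(e)),
                 file.path(cfg$outputDir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log_ <- function(...) message(sprintf(...))

  pn <- ystrPanel(cfg$panel)
  pops <- stage("load", {
    raw <- cfg$populations
    if (is.null(raw) || length(raw) < 1L)
      stop("config needs at least one population")
    if (is.character(raw)) raw <- as.list(raw)
    for (p in raw)
      if (is.character(p) && !file.exists(p)) stop("no such file: ", p)
    out <- lapply(seq_along(raw), function(k) {
      p <- raw[[k]]
      if (is(p, "YstrPopulation")) return(p)
      nm <- names(raw)[k]
      readHaplotypes(p, panel = pn,
                     name = if (!is.null(nm) && nzchar(nm)) nm else basename(p))
    })
    names(out) <- vapply(out, function(p) p@name, character(1))
    out
  })

  filtered <- stage("filter", lapply(pops, filterComplete))
  manifest <- list(
    package = "ystrkit",
    version = as.character(utils::packageVersion("ystrkit")),
    seed = cfg$seed, nPerm = cfg$nPerm, panel = cfg$panel,
    populations = lapply(filtered, function(f) {
      list(n_input = nSamples(f$complete) + nSamples(f$excluded),
           n_excluded = nSamples(f$excluded),
           n_complete = nSamples(f$complete))
    })
  )
  for (nm in names(filtered))
    log_("stage filter: %s %d in / %d excluded / %d complete", nm,
         manifest$populations[[nm]]$n_input,
         manifest$populations[[nm]]$n_excluded,
         manifest$populations[[nm]]$n_complete)

  complete <- lapply(filtered, `[[`, "complete")
  reports <- stage("forensic", {
    lapply(names(complete), function(nm) {
      rep_ <- forensicSummary(complete[[nm]])
      writeReport(rep_, file.path(cfg$outputDir, paste0(nm, "_report.json")),
                  "json")
      writeReport(rep_, file.path(cfg$outputDir, paste0(nm, "_report.csv")),
                  "csv")
      rep_
    })
  })
  names(reports) <- names(complete)
  log_("stage forensic: %d report(s) written", length(reports))

  rst <- NULL; mds <- NULL; amv <- NULL
  if (length(complete) >= 2L) {
    rst <- stage("rst", pairwiseRst(complete, nPerm = cfg$nPerm,
                                    seed = cfg$seed,
                                    includeDYS385 = cfg$includeDYS385,
                                    subtractDYS389 = cfg$subtractDYS389))
    utils::write.csv(rst@rst, file.path(cfg$outputDir, "rst_matrix.csv"))
    utils::write.csv(rst@pValues, file.path(cfg$outputDir, "rst_pvalues.csv"))
    amv <- stage("amova", amova(complete, nPerm = cfg$nPerm, seed = cfg$seed,
                                includeDYS385 = cfg$includeDYS385,
                                subtractDYS389 = cfg$subtractDYS389))
    jsonlite::write_json(
      list(ssd_among = amv@ssdAmong, ssd_within = amv@ssdWithin,
           df_among = amv@dfAmong, df_within = amv@dfWithin,
           sigma2_among = amv@sigma2Among, sigma2_within = amv@sigma2Within,
           phi_st = amv@phiST, p_value = amv@pValue,
           n_permutations = amv@nPermutations, seed = amv@seed),
      file.path(cfg$outputDir, "amova.json"), auto_unbox = TRUE, digits = NA)
    mds <- stage("mds", classicalMDS(rst, dims = cfg$mdsDims))
    utils::write.csv(mds$coords, file.path(cfg$outputDir,
                                           "mds_coordinates.csv"))
    log_("stage compare: %d x %d Rst matrix, %d-D MDS",
         length(rst@labels), length(rst@labels), mds$dimsReturned)
  }

  hg <- NULL
  if (!is.null(cfg$haplogroupTable)) {
    hg <- stage("haplogroup", {
      tab <- if (is(cfg$haplogroupTable, "HaplogroupTable")) cfg$haplogroupTable
             else readHaplogroupTable(cfg$haplogroupTable)
      calls <- assignHaplogroup(complete[[1L]], tab, eps = cfg$smoothingEps)
      utils::write.csv(calls, file.path(cfg$outputDir, "haplogroup_calls.csv"),
                       row.names = FALSE)
      spec_ <- haplogroupSpectrum(complete[[1L]], tab, eps = cfg$smoothingEps)
      jsonlite::write_json(
        list(percent = as.list(spec_$percent),
             counts = as.list(spec_$counts),
             n_unclassified = spec_$nUnclassified),
        file.path(cfg$outputDir, "haplogroup_spectrum.json"),
        auto_unbox = TRUE, digits = NA)
      list(calls = calls, spectrum = spec_)
    })
    log_("stage haplogroup: %d sample(s) called", nrow(hg$calls))
  }

  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(populations = complete, excluded = lapply(filtered, `[[`,
                                                           "excluded"),
                 reports = reports, rst = rst, amova = amv, mds = mds,
                 haplogroup = hg, manifest = manifest))
}
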