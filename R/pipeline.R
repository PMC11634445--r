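#' Configuration for an end-to-end run
#'
#' A run either ingests measured data (`plates`, `mixing`, optionally
#' `ig_plates` CSV paths plus a `library` manifest) or, when no plate files
#' are given, simulates a cohort with [generate_cohort()] under `seed`.
#'
#' @param out_dir Output directory; created (recursively) at run time.
#' @param seed Integer seed for any simulation in the run.
#' @param plates Character vector of peptide-plate CSV paths, or `NULL` to
#'   simulate.
#' @param mixing Mixing-study CSV path, or `NULL`.
#' @param ig_plates Immunoglobulin plate CSV path(s), or `NULL`.
#' @param library Peptide-library manifest TSV, or `NULL` for the packaged
#'   ADAMTS13 proximal-domain library.
#' @param regions Regions/domains TSV, or `NULL` for the packaged fixture.
#' @param k Positivity cut-off multiplier (default 3).
#' @param shared_threshold Cohort shared-region threshold (default 0.5).
#' @param core_mode `"max_coverage"` or `"intersection"`.
#' @param n_patients Cohort size when simulating (default 53).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, plates = NULL, mixing = NULL,
                       ig_plates = NULL, library = NULL, regions = NULL,
                       k = 3, shared_threshold = 0.5,
                       core_mode = c("max_coverage", "intersection"),
                       n_patients = 53L) {
  core_mode <- match.arg(core_mode)
  for (f in c(plates, mixing, ig_plates, library, regions)) {
    if (!file.exists(f))
      pep_stop(paste("input file not found:", f), "missing_input")
  }
  structure(list(out_dir = out_dir, seed = assert_scalar_int(seed, "seed"),
                 plates = plates, mixing = mixing, ig_plates = ig_plates,
                 library = library, regions = regions, k = k,
                 shared_threshold = shared_threshold, core_mode = core_mode,
                 n_patients = n_patients),
            class = "run_config")
}

#' Run the full epitope-mapping pipeline
#'
#' Orchestrates design -> simulate/ingest -> plate calling -> epitope
#' deconvolution -> Bethesda titration -> report. Writes to
#' `config$out_dir`: the peptide library (`library.fasta`, `library.tsv`),
#' `calls.tsv`, the report tables (`regions.tsv`,
#' `domain_reactivity.tsv`, ...), `bethesda.tsv`, optionally
#' `ig_quantification.tsv` and `recovery.txt` (simulated runs), and a
#' machine-readable `manifest.json` recording parameters and the package
#' version. Deterministic under a fixed seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory `library`, `calls`, `map`,
#'   `bu`, `ig`, `recovery` objects.
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"), seed = 7, n_patients = 6)
#' res <- run_all(cfg, quiet = TRUE)
#' summary(res$map)
#' }
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pep_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "stage_error")
    })
  }

  say("designing peptide library")
  regions <- stage("design", if (is.null(config$regions)) adamts13_regions()
                   else read_regions_tsv(config$regions))
  lib <- stage("design", if (is.null(config$library)) {
    design_library(adamts13_proximal(), regions)
  } else read_peptide_library(config$library))
  write_peptide_library(lib, fasta = file.path(config$out_dir, "library.fasta"),
                        tsv = file.path(config$out_dir, "library.tsv"))

  cohort <- NULL
  if (is.null(config$plates)) {
    say("simulating cohort of ", config$n_patients, " patients (seed ",
        config$seed, ")")
    cohort <- stage("simulate", generate_cohort(
      synthetic_config(n_patients = config$n_patients, seed = config$seed),
      library = lib, dir = file.path(config$out_dir, "simulated")))
    wells <- cohort$wells; mixing <- cohort$mixing; ig_wells <- cohort$ig_wells
  } else {
    say("reading plate measurements")
    wells <- stage("ingest", read_plates_csv(config$plates))
    mixing <- if (!is.null(config$mixing))
      stage("ingest", read_mixing_csv(config$mixing)) else NULL
    ig_wells <- if (!is.null(config$ig_plates))
      stage("ingest", read_plates_csv(config$ig_plates)) else NULL
  }

  say("calling peptide positivity (k = ", config$k, ")")
  calls <- stage("call", call_plates(wells, library = lib, k = config$k))
  utils::write.table(as.data.frame(calls),
                     file.path(config$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("deconvolving epitope regions")
  map <- stage("map", epitope_map(calls, regions,
                                  shared_threshold = config$shared_threshold,
                                  core_mode = config$core_mode))
  write_report_tables(map, config$out_dir, library = lib)

  bu <- NULL
  if (!is.null(mixing)) {
    say("Bethesda titration")
    bu <- stage("bethesda", bethesda_all(mixing))
    utils::write.table(bu, file.path(config$out_dir, "bethesda.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ig <- NULL
  if (!is.null(ig_wells)) {
    say("immunoglobulin quantification")
    ig <- stage("ig", rbind(quantify_ig(ig_wells, "IgM"),
                            quantify_ig(ig_wells, "IgA")))
    utils::write.table(ig, file.path(config$out_dir, "ig_quantification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  recovery <- NULL
  if (!is.null(cohort)) {
    recovery <- stage("score", score_recovery(cohort, map, bu = bu, ig = ig))
    utils::capture.output(print(recovery),
                          file = file.path(config$out_dir, "recovery.txt"))
  }

  manifest <- list(
    package = "pepscanr",
    version = as.character(utils::packageVersion("pepscanr")),
    seed = config$seed, k = config$k,
    shared_threshold = config$shared_threshold, core_mode = config$core_mode,
    simulated = is.null(config$plates), n_patients = config$n_patients,
    n_peptides = nrow(lib), n_calls = nrow(calls),
    outputs = list.files(config$out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", config$out_dir)
  invisible(list(library = lib, calls = calls, map = map, bu = bu, ig = ig,
                 recovery = recovery, cohort = cohort))
}
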