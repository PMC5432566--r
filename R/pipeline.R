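config_manifest <- function(config, extra = list()) {
  c(list(package = "surfannot",
         version = as.character(utils::packageVersion("surfannot")),
         seed = config$seed,
         tolerances = list(step_tol = config$step_tol,
                           anchor_tol = config$anchor_tol,
                           comp_tol = config$comp_tol,
                           template_tol = config$template_tol,
                           loss_tol = config$loss_tol,
                           adduct_tol = config$adduct_tol,
                           ms1_tol = config$ms1_tol),
         nominal = config$nominal,
         spacing = config$spacing,
         min_series_length = config$min_series_length,
         residue_table_md5 = unname(tools::md5sum(
           system.file("extdata", "residue_masses.txt",
                       package = "surfannot"))),
         templates = names(config$templates)),
    extra)
}

write_manifest <- function(config, out_dir, extra = list()) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(config_manifest(config, extra), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the annotation pipeline on a peak-list file
#'
#' Reads an MGF file (or takes a [spectrum_set()]), runs homolog-series
#' detection and sodium-adduct pairing on every MS1 spectrum and
#' [annotate_spectrum()] on every MS2 spectrum, and writes to `out_dir`:
#' `series.tsv`, `annotations.tsv` (one row per precursor),
#' `annotations.json` (full ladders and per-step errors) and
#' `manifest.json` (config hash material sufficient to reproduce the run).
#'
#' @param input Path to an MGF file, or a [spectrum_set()].
#' @param config An [annotation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `series`, `adduct_pairs`, `annotations`
#'   and the written file paths.
#' @export
pipeline_annotate <- function(input, config = annotation_config(),
                              out_dir = ".") {
  set <- if (inherits(input, "spectrum_set")) input else read_mgf(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lv <- vapply(set$spectra, function(s) s$ms_level, 1L)
  series <- list(); pairs <- list()
  for (s in set$spectra[lv == 1L]) {
    found <- detect_homolog_series(s, config$spacing, config$ms1_tol,
                                   config$min_series_length)
    series <- c(series, found)
    for (sr in found) {
      pairs[[length(pairs) + 1L]] <-
        pair_sodium_adducts(sr, s, config$adduct_tol, config$adducts)
    }
  }
  annotations <- lapply(set$spectra[lv == 2L], annotate_spectrum, config)
  series_tab <- if (length(series) > 0) {
    do.call(rbind, lapply(seq_along(series), function(i) {
      data.frame(series = i,
                 members = paste(sprintf("%.4f", series[[i]]$member_mzs),
                                 collapse = ","),
                 length = length(series[[i]]$member_mzs),
                 fitted_spacing = series[[i]]$fitted_spacing)
    }))
  } else {
    data.frame(series = integer(), members = character(),
               length = integer(), fitted_spacing = numeric())
  }
  p_series <- file.path(out_dir, "series.tsv")
  utils::write.table(series_tab, p_series, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_tab <- file.path(out_dir, "annotations.tsv")
  write_annotation_report(annotations, p_tab, "tsv")
  p_json <- file.path(out_dir, "annotations.json")
  write_annotation_report(annotations, p_json, "json")
  p_manifest <- write_manifest(config, out_dir,
                               list(n_spectra = length(set$spectra)))
  fams <- vapply(annotations, function(a) a$family, "")
  message(sprintf(
    "annotated %d MS2 spectra (%d assigned, %d unassigned); %d homolog series",
    length(annotations), sum(fams != "unassigned"),
    sum(fams == "unassigned"), length(series)))
  if (length(annotations) == 0) warning("no MS2 spectra found in input")
  invisible(list(series = series, adduct_pairs = pairs,
                 annotations = annotations,
                 paths = c(series = p_series, table = p_tab, json = p_json,
                           manifest = p_manifest)))
}

#' Simulate a run and write it to disk
#'
#' Writes the generated MGF plus a truth sidecar (`truth.json`: template,
#' true sequence, chain lengths, precursors and per-peak provenance) and a
#' run manifest. Outputs are byte-identical for a fixed seed.
#'
#' @param sim_config A [sim_spectra_config()].
#' @param out_dir Output directory.
#' @param config An [annotation_config()] (recorded in the manifest).
#' @return Invisibly, the written paths and the generated [spectrum_set()].
#' @export
pipeline_simulate <- function(sim_config = sim_spectra_config(),
                              out_dir = ".",
                              config = annotation_config(seed =
                                                           sim_config$seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- generate_lcms_run(sim_config)
  p_mgf <- file.path(out_dir, "run.mgf")
  write_mgf(run, p_mgf)
  p_truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(attr(run, "truth"), p_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  p_manifest <- write_manifest(config, out_dir,
                               list(simulator = unclass(
                                 sim_config[setdiff(names(sim_config),
                                                    "template")])))
  message(sprintf("wrote %d spectra to %s", length(run$spectra), p_mgf))
  invisible(list(set = run,
                 paths = c(mgf = p_mgf, truth = p_truth,
                           manifest = p_manifest)))
}

#' Run the bioassay statistics and write reports
#'
#' @param stability Path to a delimited table (columns `condition`, `time`,
#'   `dac_mm`, optionally `replicate`) or a data.frame.
#' @param control_condition Control label for [summarize_stability()].
#' @param dilution Optional [dilution_series()] for a MIC call.
#' @param thresholds Zone grading cut-offs, mm.
#' @param out_dir Output directory.
#' @param config An [annotation_config()] (for the manifest).
#' @return Invisibly, the summary, grades, MIC result and written paths.
#' @export
pipeline_bioassay <- function(stability, control_condition = "control",
                              dilution = NULL, thresholds = c(10, 20, 30),
                              out_dir = ".",
                              config = annotation_config()) {
  tab <- if (is.character(stability)) {
    utils::read.table(stability, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else stability
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_stability(tab, control_condition)
  p_sum <- file.path(out_dir, "stability_summary.tsv")
  utils::write.table(summ, p_sum, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grades <- data.frame(condition = tab$condition, time = tab$time,
                       dac_mm = tab$dac_mm,
                       grade = as.character(grade_dac(tab$dac_mm,
                                                      thresholds)))
  p_grades <- file.path(out_dir, "grades.tsv")
  utils::write.table(grades, p_grades, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mic <- NULL
  paths <- c(summary = p_sum, grades = p_grades)
  if (!is.null(dilution)) {
    mic <- mic_from_dilution(dilution)
    p_mic <- file.path(out_dir, "mic.json")
    jsonlite::write_json(list(mic_ug_ml = if (mic$reached) mic$mic else NULL,
                              reached = mic$reached,
                              monotone = mic$monotone),
                         p_mic, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, mic = p_mic)
  }
  paths <- c(paths, manifest = write_manifest(config, out_dir))
  invisible(list(summary = summ, grades = grades, mic = mic, paths = paths))
}
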