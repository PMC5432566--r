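#' Read a Mascot generic format (MGF) peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks into a [spectrum_set()]. Only the
#' headers `PEPMASS`, `RTINSECONDS`, `TITLE` and the non-standard `MSLEVEL`
#' are interpreted; any other `KEY=value` header is preserved verbatim in the
#' spectrum metadata. Peak lines are `mz [intensity]` pairs (a missing
#' intensity defaults to 1). A block without `MSLEVEL=1` must carry a
#' `PEPMASS` and is treated as MS2.
#'
#' @param path Path to an MGF text file.
#' @return A [spectrum_set()].
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- 0L
  hdr <- list(); mz <- numeric(); int <- numeric()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("MGF parse error at line ", i,
                         ": BEGIN IONS inside an open block")
      in_block <- TRUE; block_start <- i
      hdr <- list(); mz <- numeric(); int <- numeric()
    } else if (ln == "END IONS") {
      if (!in_block) stop("MGF parse error at line ", i,
                          ": END IONS without BEGIN IONS")
      spectra[[length(spectra) + 1L]] <-
        mgf_block_to_spectrum(hdr, mz, int, block_start)
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      hdr[[key]] <- val
    } else if (in_block) {
      tok <- strsplit(ln, "[ \t]+")[[1]]
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v[seq_len(min(2, length(v)))]) || length(v) < 1) {
        stop("MGF parse error at line ", i, ": non-numeric peak line '",
             ln, "'")
      }
      mz <- c(mz, v[1])
      int <- c(int, if (length(v) >= 2) v[2] else 1)
    }
    # content outside blocks is ignored
  }
  if (in_block) stop("MGF parse error: block starting at line ", block_start,
                     " missing END IONS")
  spectrum_set(spectra)
}

mgf_block_to_spectrum <- function(hdr, mz, int, block_start) {
  ms_level <- if (!is.null(hdr$MSLEVEL)) as.integer(hdr$MSLEVEL) else 2L
  precursor <- NULL
  if (!is.null(hdr$PEPMASS)) {
    precursor <- as.numeric(strsplit(trimws(hdr$PEPMASS), "[ \t]+")[[1]][1])
  }
  if (ms_level == 2L && is.null(precursor)) {
    stop("MGF parse error: MS2 block starting at line ", block_start,
         " has no PEPMASS")
  }
  rt <- if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) / 60
        else NULL
  id <- if (!is.null(hdr$TITLE)) hdr$TITLE else ""
  extra <- hdr[setdiff(names(hdr), c("MSLEVEL", "PEPMASS", "RTINSECONDS",
                                     "TITLE"))]
  ms_spectrum(mz, int, ms_level = ms_level, precursor_mz = precursor,
              rt = rt, id = id, metadata = extra)
}

#' Write spectra to a Mascot generic format file
#'
#' @param x A [spectrum_set()] or a single [ms_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  if (inherits(x, "mass_spectrum")) x <- spectrum_set(list(x))
  stopifnot(inherits(x, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in x$spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(paste0("MSLEVEL=", s$ms_level), con)
    if (!is.null(s$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    }
    if (!is.null(s$rt)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$rt * 60), con)
    }
    for (k in names(s$metadata)) {
      writeLines(paste0(k, "=", s$metadata[[k]]), con)
    }
    if (n_peaks(s) > 0) {
      writeLines(sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a delimited peak table as a single spectrum
#'
#' @param path Path to a delimited text file with a header row.
#' @param delimiter Field delimiter (default tab).
#' @param columns Named character vector mapping the roles `mz` and
#'   (optionally) `intensity` to column names in the file.
#' @param ms_level,precursor_mz,rt,id Spectrum attributes supplied by the
#'   caller (a flat table carries none).
#' @return A [ms_spectrum()]. A header-only file yields an empty spectrum
#'   with a warning.
#' @export
read_peak_table <- function(path, delimiter = "\t",
                            columns = c(mz = "mz", intensity = "intensity"),
                            ms_level = 1L, precursor_mz = NULL, rt = NULL,
                            id = "") {
  if (!file.exists(path)) stop("peak table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE)
  if (!"mz" %in% names(columns)) stop("columns mapping must name 'mz'")
  if (!columns[["mz"]] %in% names(tab)) {
    stop("peak table is missing mandated column '", columns[["mz"]], "'")
  }
  if (nrow(tab) == 0) {
    warning("peak table '", path, "' has a header but no rows")
    return(structure(list(peaks = data.frame(mz = numeric(),
                                             intensity = numeric()),
                          ms_level = as.integer(ms_level),
                          precursor_mz = precursor_mz, rt = rt,
                          id = as.character(id), metadata = list()),
                     class = "mass_spectrum"))
  }
  mz <- as.numeric(tab[[columns[["mz"]]]])
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("peak table '", path, "' contains non-positive or non-numeric m/z")
  }
  int <- if ("intensity" %in% names(columns) &&
             columns[["intensity"]] %in% names(tab)) {
    as.numeric(tab[[columns[["intensity"]]]])
  } else 1
  ms_spectrum(mz, int, ms_level = ms_level, precursor_mz = precursor_mz,
              rt = rt, id = id)
}

#' Write an annotation report
#'
#' Tabular reports give one row per annotated precursor; structured (JSON)
#' reports serialise the complete ladders, per-step candidate sets and mass
#' errors so that a report round-trips losslessly.
#'
#' @param annotations A list of `lipopeptide_annotation` objects (or one).
#' @param path Output path.
#' @param format `"tsv"` for the one-row-per-precursor table, `"json"` for
#'   the full structured report.
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(annotations, path,
                                    format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(annotations, "lipopeptide_annotation")) {
    annotations <- list(annotations)
  }
  stopifnot(all(vapply(annotations, inherits, TRUE,
                       "lipopeptide_annotation")))
  if (format == "tsv") {
    tab <- annotation_table(annotations)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- lapply(annotations, annotation_to_list)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Summarise annotations as a one-row-per-precursor table
#'
#' @param annotations List of `lipopeptide_annotation` objects.
#' @return A data.frame with columns `precursor_mz`, `rt`, `family`,
#'   `chain_length`, `sequence`, `score`, `mass_error`.
#' @export
annotation_table <- function(annotations) {
  if (inherits(annotations, "lipopeptide_annotation")) {
    annotations <- list(annotations)
  }
  do.call(rbind, c(list(data.frame(precursor_mz = numeric(), rt = numeric(),
                                   family = character(),
                                   chain_length = integer(),
                                   sequence = character(), score = numeric(),
                                   mass_error = numeric())),
    lapply(annotations, function(a) {
      data.frame(precursor_mz = a$precursor_mz,
                 rt = if (is.null(a$rt)) NA_real_ else a$rt,
                 family = a$family,
                 chain_length = if (is.na(a$chain_length)) NA_integer_
                                else a$chain_length,
                 sequence = sequence_string(a$sequence),
                 score = a$score,
                 mass_error = if (is.na(a$lipid_error)) NA_real_
                              else a$lipid_error)
    })))
}

annotation_to_list <- function(a) {
  list(precursor_mz = a$precursor_mz,
       rt = a$rt,
       family = a$family,
       chain_length = if (is.na(a$chain_length)) NULL else a$chain_length,
       lipid_error = if (is.na(a$lipid_error)) NULL else a$lipid_error,
       score = a$score,
       sequence = lapply(a$sequence, function(p)
         list(candidates = p$symbol, errors = p$error, source =
                attr(p, "source"))),
       b_ladder = ladder_to_list(a$b_ladder),
       y_ladder = ladder_to_list(a$y_ladder),
       terminal = list(delta = a$terminal$delta,
                       candidates = a$terminal$candidates$symbol,
                       errors = a$terminal$candidates$error),
       complements = a$complements,
       water_loss = a$water_loss)
}

ladder_to_list <- function(l) {
  if (is.null(l) || length(l$rungs) == 0) return(NULL)
  list(ion_type = l$ion_type,
       rungs = l$rungs,
       deltas = l$deltas,
       total_intensity = l$total_intensity,
       steps = lapply(l$steps, function(s)
         list(candidates = s$symbol, errors = s$error)))
}

#' Read back a structured (JSON) annotation report
#'
#' @param path Path written by [write_annotation_report()] with
#'   `format = "json"`.
#' @return The parsed report as a list.
#' @export
read_annotation_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}
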