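#' Construct a centroided mass spectrum
#'
#' The basic container of the pipeline: a peak list (m/z, intensity) with an
#' MS level, an optional precursor and retention time. Peaks are stored
#' sorted strictly ascending in m/z; duplicate m/z values are merged by
#' summing their intensities (downstream graph algorithms assume strict
#' ordering).
#'
#' @param mz Numeric vector of peak m/z values (Da, positive).
#' @param intensity Numeric vector of intensities (non-negative); recycled.
#' @param ms_level 1 or 2.
#' @param precursor_mz Precursor m/z; required when `ms_level = 2`.
#' @param rt Retention time in minutes (optional).
#' @param id Free-text spectrum identifier.
#' @param metadata Named list of extra run metadata.
#' @return An object of class `mass_spectrum`.
#' @examples
#' ms_spectrum(c(994, 1008, 1022, 1036))
#' @export
ms_spectrum <- function(mz, intensity = 1, ms_level = 1L,
                        precursor_mz = NULL, rt = NULL, id = "",
                        metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- rep_len(as.numeric(intensity), length(mz))
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("peak m/z must be positive")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("peak intensity must be non-negative")
  }
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (ms_level == 2L && is.null(precursor_mz)) {
    stop("an MS2 spectrum requires precursor_mz")
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    n_dup <- sum(duplicated(mz))
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)),
                                   sum))
    mz <- unique(mz)
    message("merged ", n_dup, " duplicate m/z peak(s) by intensity sum")
  }
  structure(
    list(peaks = data.frame(mz = mz, intensity = intensity),
         ms_level = ms_level,
         precursor_mz = if (is.null(precursor_mz)) NULL
                        else as.numeric(precursor_mz),
         rt = if (is.null(rt)) NULL else as.numeric(rt),
         id = as.character(id),
         metadata = metadata),
    class = "mass_spectrum")
}

#' Bundle spectra into a set
#'
#' @param spectra List of [ms_spectrum()] objects. Spectra with empty ids are
#'   assigned sequential ids; ids must be unique within the set.
#' @param run_metadata Named list describing the run (instrument, gradient,
#'   ...).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, run_metadata = list()) {
  stopifnot(is.list(spectra),
            all(vapply(spectra, inherits, TRUE, "mass_spectrum")))
  ids <- vapply(spectra, function(s) s$id, "")
  blank <- !nzchar(ids)
  ids[blank] <- sprintf("spectrum_%03d", which(blank))
  if (anyDuplicated(ids)) stop("spectrum ids must be unique within a set")
  for (i in seq_along(spectra)) spectra[[i]]$id <- ids[i]
  structure(list(spectra = spectra, run_metadata = run_metadata),
            class = "spectrum_set")
}

n_peaks <- function(x) nrow(x$peaks)

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("MS%d spectrum%s: %d peaks", x$ms_level,
              if (nzchar(x$id)) paste0(" '", x$id, "'") else "",
              n_peaks(x)))
  if (!is.null(x$precursor_mz)) {
    cat(sprintf(", precursor m/z %.4f", x$precursor_mz))
  }
  if (!is.null(x$rt)) cat(sprintf(", Rt %.2f min", x$rt))
  cat("\n")
  if (n_peaks(x) > 0) {
    cat(sprintf("  m/z range %.4f - %.4f\n",
                min(x$peaks$mz), max(x$peaks$mz)))
  }
  invisible(x)
}

#' @export
print.spectrum_set <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$ms_level, 1L)
  cat(sprintf("Spectrum set: %d spectra (%d MS1, %d MS2)\n",
              length(x$spectra), sum(lv == 1), sum(lv == 2)))
  invisible(x)
}

#' @export
summary.spectrum_set <- function(object, ...) {
  d <- data.frame(
    id = vapply(object$spectra, function(s) s$id, ""),
    ms_level = vapply(object$spectra, function(s) s$ms_level, 1L),
    n_peaks = vapply(object$spectra, n_peaks, 1L),
    precursor_mz = vapply(object$spectra, function(s)
      if (is.null(s$precursor_mz)) NA_real_ else s$precursor_mz, 1),
    rt = vapply(object$spectra, function(s)
      if (is.null(s$rt)) NA_real_ else s$rt, 1))
  rownames(d) <- NULL
  d
}

#' Stick plot of a spectrum
#'
#' @param x A `mass_spectrum`.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mass_spectrum <- function(x, y, ...) {
  if (n_peaks(x) == 0) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "m/z", ylab = "intensity", ...)
    return(invisible(x))
  }
  graphics::plot(x$peaks$mz, x$peaks$intensity, type = "h",
                 xlab = "m/z", ylab = "intensity",
                 main = if (nzchar(x$id)) x$id else NULL, ...)
  invisible(x)
}
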