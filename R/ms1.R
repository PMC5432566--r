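#' Detect CH2-spaced homolog series in a peak list
#'
#' Lipopeptide homologs differ by repeated CH2 units in the fatty-acyl chain,
#' so their protonated precursors form chains of peaks with a common spacing
#' of ~14.016 Da. This function returns every maximal chain of peaks whose
#' consecutive gaps each lie within `tol` of `spacing`. A reported series is
#' never a contiguous sub-chain of another reported series; a peak may sit in
#' several chains only when the tolerance genuinely admits it.
#'
#' @param x A [ms_spectrum()] or a numeric vector of peak m/z values.
#' @param spacing Target spacing in Da (default: one CH2).
#' @param tol Allowed deviation of each gap from `spacing`, in Da. Use
#'   ~0.1 for high-precision peak lists and ~0.6 in "nominal" mode where
#'   precursors are printed as unit-resolution integers.
#' @param min_length Minimum number of members for a reported series.
#' @return A list of `homolog_series` objects, each with components
#'   `member_mzs`, `gaps`, `per_step_errors` (signed deviations from
#'   `spacing`), `spacing` (the target) and `fitted_spacing` (mean observed
#'   gap).
#' @examples
#' s <- detect_homolog_series(c(994, 1008, 1022, 1036), tol = 0.6)
#' s[[1]]$fitted_spacing
#' @export
detect_homolog_series <- function(x, spacing = 14.01565007, tol = 0.1,
                                  min_length = 3L) {
  stopifnot(spacing > 0, tol > 0, min_length >= 2)
  mz <- sort(unique(peak_mz(x)))
  n <- length(mz)
  if (n == 0) return(list())
  # adjacency: j follows i when the gap matches the spacing within tol
  succ <- lapply(seq_len(n), function(i) {
    which(abs(mz - mz[i] - spacing) <= tol & mz > mz[i])
  })
  has_pred <- rep(FALSE, n)
  for (i in seq_len(n)) has_pred[succ[[i]]] <- TRUE
  chains <- list()
  grow <- function(path) {
    nxt <- succ[[path[length(path)]]]
    if (length(nxt) == 0) {
      chains[[length(chains) + 1L]] <<- path
    } else {
      for (j in nxt) grow(c(path, j))
    }
  }
  for (i in which(!has_pred)) grow(i)
  chains <- Filter(function(p) length(p) >= min_length, chains)
  lapply(chains, function(p) {
    m <- mz[p]
    gaps <- diff(m)
    structure(list(member_mzs = m,
                   gaps = gaps,
                   per_step_errors = gaps - spacing,
                   spacing = spacing,
                   fitted_spacing = mean(gaps),
                   tol = tol),
              class = "homolog_series")
  })
}

peak_mz <- function(x) {
  if (inherits(x, "mass_spectrum")) x$peaks$mz else as.numeric(x)
}

#' @export
print.homolog_series <- function(x, ...) {
  cat(sprintf("Homolog series: %d members, fitted spacing %.4f Da (target %.4f)\n",
              length(x$member_mzs), x$fitted_spacing, x$spacing))
  cat("  m/z:", paste(sprintf("%.4f", x$member_mzs), collapse = " -> "), "\n")
  invisible(x)
}

#' Pair homolog series members with sodium adducts
#'
#' For each series member m (assumed \eqn{[M+H]^+}), searches the spectrum
#' for an \eqn{[M+Na]^+} partner at `m + (Na - H)` within `tol`.
#'
#' @param series A `homolog_series` (or numeric vector of member m/z).
#' @param spectrum A [ms_spectrum()] or numeric peak vector to search.
#' @param tol Matching tolerance in Da.
#' @param adducts Mass constants, see [adduct_constants()].
#' @return A data.frame with one row per found pair: `protonated_mz`,
#'   `sodiated_mz`, `error` (signed deviation from the Na-H offset).
#'   Members without a partner yield no row.
#' @examples
#' pair_sodium_adducts(c(994, 1008), c(994, 1008, 1016, 1030), tol = 0.1)
#' @export
pair_sodium_adducts <- function(series, spectrum, tol = 0.1,
                                adducts = adduct_constants()) {
  stopifnot(tol > 0)
  members <- if (inherits(series, "homolog_series")) series$member_mzs
             else as.numeric(series)
  mz <- peak_mz(spectrum)
  out <- data.frame(protonated_mz = numeric(), sodiated_mz = numeric(),
                    error = numeric())
  for (m in members) {
    target <- m + adducts$sodium_minus_hydrogen
    d <- mz - target
    i <- which.min(abs(d))
    if (length(i) == 1 && abs(d[i]) <= tol && mz[i] > m) {
      out <- rbind(out, data.frame(protonated_mz = m, sodiated_mz = mz[i],
                                   error = d[i]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Search for a neutral-loss partner peak
#'
#' Finds the peak closest to `reference_mz - loss` (e.g. the dehydration ion
#' \eqn{[M-H_2O]^+} of a precursor) if it lies within `tol`.
#'
#' @param spectrum A [ms_spectrum()] or numeric peak vector.
#' @param reference_mz Reference m/z in Da.
#' @param loss Neutral-loss mass in Da (default: water).
#' @param tol Matching tolerance in Da.
#' @return A list with `mz` (matched peak, NA when none), `error` (signed,
#'   observed minus expected) and `matched` (logical).
#' @examples
#' find_neutral_loss(c(976.53, 994), 994)
#' @export
find_neutral_loss <- function(spectrum, reference_mz,
                              loss = adduct_constants()$water, tol = 0.75) {
  stopifnot(loss > 0, tol > 0, reference_mz > 0)
  mz <- peak_mz(spectrum)
  if (length(mz) == 0) return(list(mz = NA_real_, error = NA_real_,
                                   matched = FALSE))
  target <- reference_mz - loss
  d <- mz - target
  i <- which.min(abs(d))
  if (abs(d[i]) <= tol) {
    list(mz = mz[i], error = d[i], matched = TRUE)
  } else {
    list(mz = NA_real_, error = NA_real_, matched = FALSE)
  }
}
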