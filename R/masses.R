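#' Monoisotopic residue mass table
#'
#' Builds the table of monoisotopic amino-acid residue masses (the mass of a
#' residue as incorporated in a peptide chain, i.e. the free amino acid minus
#' water) used throughout the annotation pipeline, together with the ambiguity
#' groups that low-resolution CID data cannot resolve: Leu/Ile are exactly
#' isobaric and are merged into the single reporting symbol `"Leu/Ile"`;
#' Gln/Lys differ by only 0.036 Da and are co-reported whenever either
#' matches.
#'
#' @param path Optional path to a plain-text table overriding the built-in
#'   masses. The file must have two whitespace-separated columns,
#'   `symbol` and `mass` (Da); lines starting with `#` are ignored. The
#'   default table ships with the package
#'   (`system.file("extdata", "residue_masses.txt", package = "surfannot")`).
#' @return An object of class `residue_table` with components
#'   \describe{
#'     \item{masses}{named numeric vector of residue masses per 3-letter
#'       symbol (Leu and Ile listed separately, with equal mass)}
#'     \item{reporting}{named numeric vector with isobaric Leu/Ile merged
#'       into one `"Leu/Ile"` entry, used for candidate matching}
#'     \item{ambiguity_groups}{list of symbol sets treated as
#'       indistinguishable at the working mass accuracy}
#'   }
#' @examples
#' tbl <- residue_mass_table()
#' residue_mass("Val", tbl)
#' @export
residue_mass_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_masses.txt", package = "surfannot")
  }
  if (!file.exists(path)) stop("residue mass file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("symbol", "mass") %in% names(tab))) {
    stop("residue mass file needs columns 'symbol' and 'mass': ", path)
  }
  masses <- stats::setNames(as.numeric(tab$mass), tab$symbol)
  if (any(masses <= 0)) stop("residue masses must be strictly positive")
  if (!all(c("Leu", "Ile") %in% names(masses))) {
    stop("residue table must contain both Leu and Ile")
  }
  if (masses[["Leu"]] != masses[["Ile"]]) {
    stop("Leu and Ile must be exactly isobaric in the table")
  }
  reporting <- masses[setdiff(names(masses), c("Leu", "Ile"))]
  reporting <- c(reporting, "Leu/Ile" = unname(masses[["Leu"]]))
  reporting <- reporting[order(reporting)]
  structure(
    list(masses = masses,
         reporting = reporting,
         ambiguity_groups = list(leu_ile = c("Leu", "Ile"),
                                 gln_lys = c("Gln", "Lys"))),
    class = "residue_table")
}

#' Look up a residue mass
#'
#' @param symbol A 3-letter residue code, or the merged code `"Leu/Ile"`.
#' @param table A [residue_mass_table()] object.
#' @return Monoisotopic residue mass in Da.
#' @examples
#' residue_mass("Leu/Ile")
#' @export
residue_mass <- function(symbol, table = residue_mass_table()) {
  stopifnot(inherits(table, "residue_table"))
  vapply(symbol, function(s) {
    if (s %in% names(table$reporting)) return(unname(table$reporting[[s]]))
    if (s %in% names(table$masses)) return(unname(table$masses[[s]]))
    stop("unknown residue symbol: '", s, "'", call. = FALSE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Match a mass difference against the residue table
#'
#' Finds every residue whose monoisotopic mass lies within `tol` of an
#' observed mass difference, ranked by absolute deviation. Leu/Ile appear as
#' a single merged candidate. Because Gln and Lys differ by only 0.036 Da,
#' whenever one of them matches the other is appended as a co-reported
#' candidate even if its own deviation slightly exceeds `tol`
#' (flagged in the `co_reported` column).
#'
#' @param delta Observed mass difference in Da (positive).
#' @param tol Matching tolerance in Da. The default 0.8 Da reflects the
#'   accuracy of unit-resolution CID peak lists, whose printed fragment
#'   arithmetic deviates from monoisotopic theory by up to ~0.75 Da.
#' @param table A [residue_mass_table()].
#' @return A data.frame with columns `symbol`, `mass`, `error`
#'   (signed, `delta - mass`), `abs_error` and `co_reported`, sorted by
#'   `abs_error`. Zero rows when nothing matches.
#' @examples
#' match_residue(112.34)           # the Leu/Ile fragment difference
#' match_residue(113.83)           # ambiguous: Asn or Leu/Ile
#' @export
match_residue <- function(delta, tol = 0.8, table = residue_mass_table()) {
  stopifnot(length(delta) == 1, delta > 0, tol > 0)
  rep_tab <- table$reporting
  err <- delta - rep_tab
  hit <- abs(err) <= tol
  out <- data.frame(symbol = names(rep_tab)[hit],
                    mass = unname(rep_tab[hit]),
                    error = unname(err[hit]),
                    abs_error = abs(unname(err[hit])),
                    co_reported = rep(FALSE, sum(hit)),
                    stringsAsFactors = FALSE)
  # Gln/Lys are indistinguishable at this accuracy: co-report the partner.
  gl <- table$ambiguity_groups$gln_lys
  present <- gl %in% out$symbol
  if (xor(present[1], present[2])) {
    miss <- gl[!present]
    if (miss %in% names(rep_tab)) {
      m <- rep_tab[[miss]]
      out <- rbind(out, data.frame(symbol = miss, mass = m,
                                   error = delta - m,
                                   abs_error = abs(delta - m),
                                   co_reported = TRUE,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$abs_error, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Beta-hydroxy fatty-acyl homolog mass series
#'
#' The lipid moiety of a surfactin-type lipopeptide is a beta-hydroxy fatty
#' acid of n carbons closed into the lactone ring. Its mass contribution
#' follows the linear law `L(n) = delta_ch2 * n + offset`. The default
#' calibration treats the acyl moiety inside the closed lactone as
#' CnH(2n-2)O2, so that `proton + L(n) + sum(residue masses)` reproduces the
#' protonated precursor of a Cn homolog.
#'
#' @param delta_ch2 Mass of one CH2 unit in Da.
#' @param offset Constant term of the mass law in Da.
#' @param n_min,n_max Admissible carbon counts.
#' @return An object of class `lipid_series`.
#' @examples
#' lipid_mass(12)                       # C12 acyl moiety
#' lipid_mass(13) - lipid_mass(12)      # exactly one CH2
#' @export
lipid_series <- function(delta_ch2 = 14.01565007,
                         offset = 29.97417918,
                         n_min = 8L, n_max = 20L) {
  stopifnot(delta_ch2 > 0, n_min <= n_max)
  structure(list(delta_ch2 = delta_ch2, offset = offset,
                 n_min = as.integer(n_min), n_max = as.integer(n_max)),
            class = "lipid_series")
}

#' @rdname lipid_series
#' @param n Carbon count (may be a vector).
#' @param series A [lipid_series()] object.
#' @export
lipid_mass <- function(n, series = lipid_series()) {
  stopifnot(inherits(series, "lipid_series"))
  if (any(n < series$n_min | n > series$n_max)) {
    stop("carbon count out of range [", series$n_min, ", ", series$n_max, "]")
  }
  series$delta_ch2 * n + series$offset
}

#' Infer the acyl chain length from a residual mass
#'
#' Inverts the lipid mass law: finds the integer carbon count whose series
#' mass is closest to an observed residual mass (typically the first b-type
#' ladder rung minus the proton and the leading residue masses).
#'
#' @param residual Observed residual mass in Da (positive).
#' @param tol Absolute anchor tolerance in Da; deviations beyond it yield a
#'   no-match. The default 1.2 Da is deliberately wider than the residue
#'   step tolerance because the anchor accumulates the error of several
#'   summed masses.
#' @param series A [lipid_series()].
#' @return A list of class `chain_match` with components `n` (integer, NA on
#'   no-match), `error` (signed, `residual - lipid_mass(n)`) and `matched`
#'   (logical). A no-match is a valid result, not an error.
#' @examples
#' chain_length_from_mass(197.52)   # C12, error -0.642
#' @export
chain_length_from_mass <- function(residual, tol = 1.2,
                                   series = lipid_series()) {
  stopifnot(length(residual) == 1, residual > 0, tol > 0)
  n_all <- seq(series$n_min, series$n_max)
  err <- residual - lipid_mass(n_all, series)
  i <- which.min(abs(err))
  if (abs(err[i]) > tol) {
    out <- list(n = NA_integer_, error = NA_real_, matched = FALSE)
  } else {
    out <- list(n = n_all[i], error = err[i], matched = TRUE)
  }
  structure(out, class = "chain_match")
}

#' Adduct and neutral-loss mass constants
#'
#' @return A list with `proton` (mass of a proton, Da), `sodium_minus_hydrogen`
#'   (offset from an \eqn{[M+H]^+} to an \eqn{[M+Na]^+} peak) and `water`
#'   (the neutral loss of a dehydration ion).
#' @examples
#' adduct_constants()$sodium_minus_hydrogen   # ~21.982
#' @export
adduct_constants <- function() {
  list(proton = 1.00727646688,
       sodium_minus_hydrogen = 21.98194425,
       water = 18.01056468)
}

#' @export
print.residue_table <- function(x, ...) {
  cat("Residue mass table:", length(x$reporting),
      "distinct monoisotopic masses\n")
  cat("  ambiguity groups:",
      paste(vapply(x$ambiguity_groups, paste, "", collapse = "/"),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lipid_series <- function(x, ...) {
  cat(sprintf("Lipid homolog series: L(n) = %.5f n + %.5f Da, n in [%d, %d]\n",
              x$delta_ch2, x$offset, x$n_min, x$n_max))
  invisible(x)
}

#' @export
print.chain_match <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("Acyl chain length C%d (error %+.3f Da)\n", x$n, x$error))
  } else {
    cat("No acyl chain length within tolerance\n")
  }
  invisible(x)
}
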