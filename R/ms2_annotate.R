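#' Lipopeptide family templates
#'
#' A family template encodes the structural rules used to classify a
#' reconstructed sequence: fixed residues at conserved positions, wildcard
#' positions (with the residues typically seen there), the admissible
#' fatty-acyl chain-length range, and whether the peptide is cyclised. The
#' shipped registry contains a complete surfactin template — a 7-residue
#' lactone-closed peptide with Glu at position 1, Leu at positions 3 and 6,
#' Asp at position 5, and variable positions 2, 4 and 7 (generally Val, Leu
#' or Ile) — plus iturin and fengycin stubs that users may complete.
#' Position numbering follows the convention in which the acyl chain counts
#' as position 1 of the molecule; see the package vignette for the mapping
#' to conventional proteomics b/y indices.
#'
#' @param path Optional YAML registry overriding the shipped one
#'   (`system.file("extdata", "templates.yml", package = "surfannot")`).
#' @return For `family_templates()`, a named list of `family_template`
#'   objects; for `surfactin_template()`, the single complete surfactin
#'   entry.
#' @examples
#' surfactin_template()
#' @export
family_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "templates.yml", package = "surfannot")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(t) {
    complete <- !is.null(t$positions)
    if (complete && !any(unlist(t$positions) != "*")) {
      stop("template '", t$name, "' must fix at least one position")
    }
    structure(list(name = t$name,
                   positions = if (complete) as.character(unlist(t$positions))
                               else NULL,
                   length = if (complete) length(t$positions) else NA_integer_,
                   lipid_range = as.integer(unlist(t$lipid_range)),
                   cyclic = isTRUE(t$cyclic),
                   variable_domain = if (!is.null(t$variable_domain))
                     as.character(unlist(t$variable_domain))
                   else c("Leu/Ile", "Val"),
                   canonical = if (!is.null(t$canonical))
                     as.character(unlist(t$canonical)) else NULL,
                   complete = complete),
              class = "family_template")
  })
  stats::setNames(out, vapply(out, function(t) t$name, ""))
}

#' @rdname family_templates
#' @export
surfactin_template <- function() family_templates()[["Surfactin"]]

#' @export
print.family_template <- function(x, ...) {
  cat("Family template:", x$name,
      if (!x$complete) "(incomplete stub)" else "", "\n")
  if (x$complete) {
    cat("  positions:", paste(x$positions, collapse = "-"), "\n")
  }
  cat(sprintf("  lipid range C%d-C%d, %s\n", x$lipid_range[1],
              x$lipid_range[2], if (x$cyclic) "cyclic" else "linear"))
  invisible(x)
}

#' Pipeline configuration
#'
#' Gathers every tolerance, mass table and template registry used by the
#' annotation pipeline. Defaults are calibrated for unit-resolution CID peak
#' lists: residue steps within 0.8 Da, absolute anchors (lipid residual,
#' b/y complements, template fixed-position re-checks) within 1.2 Da,
#' water-loss search within 0.75 Da.
#'
#' @param step_tol Residue-step (graph edge) tolerance, Da.
#' @param anchor_tol Lipid-anchor tolerance, Da.
#' @param comp_tol b/y complement-sum tolerance, Da.
#' @param template_tol Tolerance for re-checking fixed template positions
#'   against raw mass gaps, Da.
#' @param loss_tol Neutral-loss matching tolerance, Da.
#' @param adduct_tol Sodium-adduct matching tolerance, Da.
#' @param ms1_tol MS1 homolog-spacing tolerance, Da (ignored when
#'   `nominal = TRUE`).
#' @param nominal Set `TRUE` when MS1 precursors are nominal (integer)
#'   masses; widens the MS1 spacing tolerance to `nominal_ms1_tol`.
#' @param nominal_ms1_tol MS1 spacing tolerance used in nominal mode, Da.
#' @param spacing Homolog spacing target, Da (one CH2).
#' @param min_series_length Minimum homolog-series length.
#' @param max_prefix Maximum number of leading residues folded into the
#'   lipid anchor when interpreting a ladder.
#' @param residues,lipids,adducts,templates Component tables; see
#'   [residue_mass_table()], [lipid_series()], [adduct_constants()],
#'   [family_templates()].
#' @param seed Seed recorded in run manifests and used by the simulators.
#' @return An object of class `annotation_config`.
#' @export
annotation_config <- function(step_tol = 0.8, anchor_tol = 1.2,
                              comp_tol = 1.2, template_tol = 1.2,
                              loss_tol = 0.75, adduct_tol = 0.1,
                              ms1_tol = 0.1, nominal = FALSE,
                              nominal_ms1_tol = 0.6,
                              spacing = 14.01565007,
                              min_series_length = 3L,
                              max_prefix = 3L,
                              residues = residue_mass_table(),
                              lipids = lipid_series(),
                              adducts = adduct_constants(),
                              templates = family_templates(),
                              seed = 1L) {
  tols <- c(step_tol, anchor_tol, comp_tol, template_tol, loss_tol,
            adduct_tol, ms1_tol, nominal_ms1_tol)
  if (any(tols <= 0)) stop("all tolerances must be positive")
  structure(list(step_tol = step_tol, anchor_tol = anchor_tol,
                 comp_tol = comp_tol, template_tol = template_tol,
                 loss_tol = loss_tol, adduct_tol = adduct_tol,
                 ms1_tol = if (nominal) nominal_ms1_tol else ms1_tol,
                 nominal = nominal, spacing = spacing,
                 min_series_length = as.integer(min_series_length),
                 max_prefix = as.integer(max_prefix),
                 residues = residues, lipids = lipids, adducts = adducts,
                 templates = templates, seed = as.integer(seed)),
            class = "annotation_config")
}

#' Assign the terminal residue from the precursor gap
#'
#' The residue closing the ladder is read off the gap between the precursor
#' m/z and the highest ladder rung (e.g. 994 - 881.66 = 112.34, the Leu/Ile
#' fragment mass).
#'
#' @param precursor_mz Precursor m/z, Da.
#' @param ladder A non-empty `ion_ladder` (or a numeric vector of rungs).
#' @param tol Residue matching tolerance, Da.
#' @param table A [residue_mass_table()].
#' @return A list with `delta` (the gap) and `candidates` (a
#'   [match_residue()] data.frame, possibly empty — an unassigned terminus
#'   is a valid outcome).
#' @export
assign_terminal_residue <- function(precursor_mz, ladder, tol = 0.8,
                                    table = residue_mass_table()) {
  rungs <- if (inherits(ladder, "ion_ladder")) ladder$rungs
           else as.numeric(ladder)
  if (length(rungs) == 0) stop("cannot assign a terminal residue: empty ladder")
  delta <- precursor_mz - max(rungs)
  cands <- if (delta > 0) match_residue(delta, tol, table)
           else match_residue(1e-6, tol, table)[0, ]
  list(delta = delta, candidates = cands)
}

#' Infer the fatty-acyl chain length from a ladder's lipid anchor
#'
#' The first rung of a b-type ladder carries the proton, the acyl chain and
#' the leading residues not resolved by the ladder. Subtracting the proton
#' and those prefix residues leaves the lipid residual, which is matched
#' against the homolog mass law.
#'
#' @param ladder A non-empty `ion_ladder`, or the first rung m/z directly.
#' @param prefix Character vector of residues spanned between the acyl
#'   anchor and the first rung (may be empty).
#' @param anchor_tol Anchor tolerance, Da.
#' @param series A [lipid_series()].
#' @param table A [residue_mass_table()].
#' @param adducts Mass constants.
#' @return A `chain_match` (see [chain_length_from_mass()]) with an extra
#'   `residual` component.
#' @examples
#' infer_lipid_anchor(441.05, c("Glu", "Leu/Ile"))   # C12
#' @export
infer_lipid_anchor <- function(ladder, prefix = character(),
                               anchor_tol = 1.2, series = lipid_series(),
                               table = residue_mass_table(),
                               adducts = adduct_constants()) {
  first <- if (inherits(ladder, "ion_ladder")) {
    if (length(ladder$rungs) == 0) stop("empty ladder has no lipid anchor")
    ladder$rungs[1]
  } else as.numeric(ladder)[1]
  residual <- first - adducts$proton -
    sum(if (length(prefix)) residue_mass(prefix, table) else 0)
  if (residual <= 0) {
    stop("inconsistent lipid anchor: non-positive residual mass (",
         format(residual), " Da)")
  }
  out <- chain_length_from_mass(residual, anchor_tol, series)
  out$residual <- residual
  out
}

#' Reconcile b/y complement pairs
#'
#' For a linear fragment pair covering the whole molecule, the b and y
#' masses sum (approximately) to the precursor mass. Each y rung is paired
#' with the b rung, if any, whose sum deviates least from the precursor
#' within `comp_tol`. Complement pairs are a confidence feature: they never
#' veto an annotation.
#'
#' @param precursor_mz Precursor m/z, Da.
#' @param b_ladder,y_ladder `ion_ladder`s (or numeric rung vectors).
#' @param comp_tol Tolerance on `b + y - precursor`, Da.
#' @return A data.frame with one row per matched pair: `y_mz`, `b_mz`,
#'   `sum_error` (signed) and `complement_mz` (`precursor - y`, the implied
#'   b-side mass).
#' @examples
#' reconcile_complements(994, 441.05, 553.99)
#' @export
reconcile_complements <- function(precursor_mz, b_ladder, y_ladder,
                                  comp_tol = 1.2) {
  stopifnot(comp_tol > 0)
  b <- if (inherits(b_ladder, "ion_ladder")) b_ladder$rungs
       else as.numeric(b_ladder)
  y <- if (inherits(y_ladder, "ion_ladder")) y_ladder$rungs
       else as.numeric(y_ladder)
  out <- data.frame(y_mz = numeric(), b_mz = numeric(),
                    sum_error = numeric(), complement_mz = numeric())
  if (length(b) == 0 || length(y) == 0) return(out)
  for (ym in y) {
    err <- b + ym - precursor_mz
    i <- which.min(abs(err))
    if (abs(err[i]) <= comp_tol) {
      out <- rbind(out, data.frame(y_mz = ym, b_mz = b[i],
                                   sum_error = err[i],
                                   complement_mz = precursor_mz - ym))
    }
  }
  rownames(out) <- NULL
  out
}

# --- template matching helpers -------------------------------------------

# "Leu/Ile" matches Leu, Ile or itself.
symbols_match <- function(a, b) {
  expand <- function(s) if (s %in% c("Leu", "Ile", "Leu/Ile"))
    c("Leu", "Ile", "Leu/Ile") else s
  any(vapply(a, function(s) b %in% expand(s) || s %in% expand(b), TRUE))
}

# A fixed template position is satisfied when the required residue is in the
# step's candidate set (step tolerance), or when the raw mass gap re-checked
# at the wider template tolerance admits it.
check_fixed_position <- function(cand_df, delta, residue, template_tol,
                                 table) {
  if (!is.null(cand_df) && nrow(cand_df) > 0 &&
      symbols_match(cand_df$symbol, residue)) return(TRUE)
  if (!is.null(delta) && !is.na(delta)) {
    return(abs(delta - residue_mass(residue, table)) <= template_tol)
  }
  FALSE
}

as_candidate_df <- function(symbols, table, source = "fixed") {
  d <- data.frame(symbol = as.character(symbols),
                  mass = residue_mass(as.character(symbols), table),
                  error = NA_real_, abs_error = NA_real_,
                  co_reported = FALSE, stringsAsFactors = FALSE)
  attr(d, "source") <- source
  d
}

#' Classify a reconstructed sequence against family templates
#'
#' A template matches when the chain length lies within its lipid range and
#' every fixed position is compatible with the corresponding candidate set
#' (or, when the raw mass gap is supplied, lies within `template_tol` of the
#' required residue mass). Among matching templates, the one whose fixed
#' positions are most often the exact best candidate wins.
#'
#' @param sequence A list of per-position candidate data.frames (as produced
#'   by [match_residue()]), or a list/vector of residue symbols. Optional
#'   `delta` attributes on the positions carry the raw observed mass gaps.
#' @param chain_length Inferred acyl carbon count.
#' @param templates Template registry, see [family_templates()]. Incomplete
#'   stub templates are skipped.
#' @param template_tol Fixed-position re-check tolerance, Da.
#' @param table A [residue_mass_table()].
#' @return A list with `family` (label, or `"unassigned"`), and `report`
#'   (a data.frame of per-template, per-position checks, with the failing
#'   constraints identifiable as `ok = FALSE`).
#' @export
classify_family <- function(sequence, chain_length,
                            templates = family_templates(),
                            template_tol = 1.2,
                            table = residue_mass_table()) {
  sequence <- lapply(sequence, function(p) {
    if (is.character(p)) as_candidate_df(p, table) else p
  })
  report <- data.frame(template = character(), position = integer(),
                       required = character(), ok = logical(),
                       exact_best = logical())
  best_name <- "unassigned"; best_exact <- -1L
  for (t in templates) {
    if (!t$complete) next
    if (length(sequence) != t$length) next
    if (is.na(chain_length) ||
        chain_length < t$lipid_range[1] || chain_length > t$lipid_range[2]) {
      next
    }
    all_ok <- TRUE; exact <- 0L
    for (i in seq_len(t$length)) {
      if (t$positions[i] == "*") next
      p <- sequence[[i]]
      ok <- check_fixed_position(p, attr(p, "delta"), t$positions[i],
                                 template_tol, table)
      is_exact <- !is.null(p) && nrow(p) > 0 &&
        symbols_match(p$symbol[1], t$positions[i])
      report <- rbind(report, data.frame(template = t$name, position = i,
                                         required = t$positions[i],
                                         ok = ok, exact_best = is_exact))
      if (!ok) all_ok <- FALSE
      if (ok && is_exact) exact <- exact + 1L
    }
    if (all_ok && exact > best_exact) {
      best_name <- t$name; best_exact <- exact
    }
  }
  list(family = best_name, report = report)
}

sequence_string <- function(sequence) {
  if (length(sequence) == 0) return("")
  paste(vapply(sequence, function(p) {
    if (is.null(p) || nrow(p) == 0) return("?")
    if (nrow(p) == 1) p$symbol else paste0("[", paste(p$symbol,
                                                      collapse = "|"), "]")
  }, ""), collapse = "-")
}

# --- end-to-end annotation ------------------------------------------------

# Enumerate template-consistent prefix residue combinations for the first
# p positions (fixed positions contribute their residue, wildcards the
# template's variable domain).
prefix_combos <- function(template, p) {
  if (p == 0) return(list(character()))
  choices <- lapply(seq_len(p), function(i) {
    if (template$positions[i] == "*") template$variable_domain
    else template$positions[i]
  })
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(r) as.character(grid[r, ]))
}

# Best (combo, n) anchor for a ladder first rung under one template.
# Isobaric prefix alternatives (e.g. Leu vs Val+CH2) give numerically equal
# anchor errors; ties go to the smaller chain length, i.e. mass is assigned
# to the peptide before the lipid.
best_prefix_anchor <- function(first_rung, template, p, config) {
  best <- NULL
  for (combo in prefix_combos(template, p)) {
    residual <- first_rung - config$adducts$proton -
      sum(if (length(combo)) residue_mass(combo, config$residues) else 0)
    if (residual <= 0) next
    cm <- chain_length_from_mass(residual, config$anchor_tol, config$lipids)
    if (!cm$matched) next
    if (cm$n < template$lipid_range[1] || cm$n > template$lipid_range[2]) next
    # anchor errors equal to within 1e-4 Da are ties (isobaric prefix
    # alternatives differ only by rounding of the mass constants)
    if (is.null(best) ||
        abs(cm$error) < abs(best$error) - 1e-4 ||
        (abs(abs(cm$error) - abs(best$error)) <= 1e-4 && cm$n < best$n)) {
      best <- list(prefix = combo, n = cm$n, error = cm$error,
                   residual = residual)
    }
  }
  best
}

# Score one (ladder, template) interpretation; NULL when it is not
# template-consistent.
interpret_ladder <- function(ladder, template, precursor_mz, config) {
  r <- length(ladder$rungs)
  p <- template$length - r
  if (p < 0 || p > config$max_prefix) return(NULL)
  anchor <- best_prefix_anchor(ladder$rungs[1], template, p, config)
  if (is.null(anchor)) return(NULL)
  terminal <- assign_terminal_residue(precursor_mz, ladder, config$step_tol,
                                      config$residues)
  # assemble per-position candidate sets
  sequence <- vector("list", template$length)
  for (i in seq_len(p)) {
    sequence[[i]] <- as_candidate_df(anchor$prefix[i], config$residues,
                                     source = "anchor")
  }
  for (k in seq_len(r - 1)) {
    s <- ladder$steps[[k]]
    attr(s, "delta") <- ladder$deltas[k]
    attr(s, "source") <- "step"
    sequence[[p + k]] <- s
  }
  tc <- terminal$candidates
  attr(tc, "delta") <- terminal$delta
  attr(tc, "source") <- "terminal"
  sequence[[template$length]] <- tc
  # fixed-position checks beyond the prefix
  for (i in seq(p + 1, template$length)) {
    if (template$positions[i] == "*") next
    ok <- check_fixed_position(sequence[[i]], attr(sequence[[i]], "delta"),
                               template$positions[i], config$template_tol,
                               config$residues)
    if (!ok) return(NULL)
  }
  step_errs <- vapply(ladder$steps, function(s)
    if (nrow(s) > 0) s$abs_error[1] else 0, 1)
  term_err <- if (nrow(tc) > 0) tc$abs_error[1] else 0
  assigned <- p + sum(vapply(ladder$steps, nrow, 1L) > 0) + (nrow(tc) > 0)
  total_err <- abs(anchor$error) + sum(step_errs) + term_err
  list(template = template$name, ladder = ladder, prefix = anchor$prefix,
       n = anchor$n, anchor_error = anchor$error, terminal = terminal,
       sequence = sequence, assigned = assigned,
       score = assigned - total_err)
}

#' Annotate one MS2 spectrum end to end
#'
#' Orchestrates the whole reconstruction: builds the spectrum graph over the
#' fragment region (peaks at or above the precursor minus the smallest
#' residue are excluded — they are molecular-ion satellites, not backbone
#' fragments), takes every contiguous window of the maximal ladder paths as
#' a candidate (a single coincidental residue-spaced edge from a suffix ion
#' onto the b-ladder head would otherwise hide the true ladder inside a
#' longer chimeric path), interprets each against the complete family
#' templates (lipid anchor with template-consistent prefix, residue steps,
#' terminal residue, fixed-position checks), and keeps the
#' interpretation with the highest score. The score is the number of
#' assigned positions minus the total absolute mass discrepancy in Da
#' (anchor + steps + terminal): interpretations whose entire mass arithmetic
#' is most self-consistent win; remaining ties go to the ladder with more
#' rungs, then to the lower starting m/z. The y-type suffix ladder is then
#' extracted from the peaks not consumed by the b ladder, complements are
#' reconciled, and the precursor's water-loss satellite is located. A
#' spectrum matching no template returns a valid annotation with family
#' `"unassigned"` built from the plain longest path.
#'
#' @param spectrum An MS2 [ms_spectrum()] with a precursor.
#' @param config An [annotation_config()].
#' @return An object of class `lipopeptide_annotation`.
#' @examples
#' sp <- generate_theoretical_spectrum(n = 13)$ms2
#' annotate_spectrum(sp)
#' @export
annotate_spectrum <- function(spectrum, config = annotation_config()) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (spectrum$ms_level != 2L || is.null(spectrum$precursor_mz)) {
    stop("annotate_spectrum needs an MS2 spectrum with a precursor m/z")
  }
  prec <- spectrum$precursor_mz
  mz_max <- prec - min(config$residues$reporting) + config$step_tol
  graph <- build_spectrum_graph(spectrum, config$step_tol, config$residues,
                                mz_max = mz_max)
  ladders <- lapply(candidate_subpaths(graph), function(p)
    new_ion_ladder(graph, p))
  candidates <- list()
  for (lad in ladders) {
    for (t in config$templates) {
      if (!t$complete) next
      ci <- interpret_ladder(lad, t, prec, config)
      if (!is.null(ci)) candidates[[length(candidates) + 1L]] <- ci
    }
  }
  if (length(candidates) > 0) {
    ord <- order(-round(vapply(candidates, function(c) c$score, 1), 6),
                 -vapply(candidates, function(c) length(c$ladder$rungs), 1),
                 vapply(candidates, function(c) c$ladder$rungs[1], 1))
    win <- candidates[[ord[1]]]
    b_ladder <- win$ladder; b_ladder$ion_type <- "b"
    family <- win$template
    chain <- win$n; lipid_error <- win$anchor_error
    sequence <- win$sequence; terminal <- win$terminal; score <- win$score
  } else {
    b_ladder <- extract_ladder(graph, "longest")
    b_ladder$ion_type <- if (length(b_ladder$rungs)) "b" else NA_character_
    family <- "unassigned"
    chain <- NA_integer_; lipid_error <- NA_real_
    terminal <- if (length(b_ladder$rungs) > 0) {
      assign_terminal_residue(prec, b_ladder, config$step_tol,
                              config$residues)
    } else list(delta = NA_real_,
                candidates = match_residue(1, config$step_tol,
                                           config$residues)[0, ])
    sequence <- b_ladder$steps
    if (length(b_ladder$rungs) > 0) {
      sequence <- c(sequence, list(terminal$candidates))
    }
    err <- sum(vapply(b_ladder$steps, function(s)
      if (nrow(s) > 0) s$abs_error[1] else 0, 1))
    score <- sum(vapply(sequence, function(s) nrow(s) > 0, TRUE)) - err
  }
  # y-type suffix ladder on the residual peak set
  used <- graph$peaks$mz %in% b_ladder$rungs
  y_ladder <- if (any(!used)) {
    yg <- build_spectrum_graph(
      ms_spectrum(graph$peaks$mz[!used], graph$peaks$intensity[!used]),
      config$step_tol, config$residues)
    extract_ladder(yg, "longest")
  } else new_ion_ladder(graph, integer())
  y_ladder$ion_type <- if (length(y_ladder$rungs)) "y" else NA_character_
  complements <- reconcile_complements(prec, b_ladder, y_ladder,
                                       config$comp_tol)
  water <- find_neutral_loss(spectrum, prec, config$adducts$water,
                             config$loss_tol)
  structure(list(precursor_mz = prec,
                 rt = spectrum$rt,
                 id = spectrum$id,
                 family = family,
                 chain_length = chain,
                 lipid_error = lipid_error,
                 sequence = sequence,
                 terminal = terminal,
                 b_ladder = b_ladder,
                 y_ladder = y_ladder,
                 complements = complements,
                 water_loss = water,
                 score = score),
            class = "lipopeptide_annotation")
}

#' @export
print.lipopeptide_annotation <- function(x, ...) {
  cat(sprintf("Lipopeptide annotation (precursor m/z %.4f%s)\n",
              x$precursor_mz,
              if (!is.null(x$rt)) sprintf(", Rt %.2f min", x$rt) else ""))
  cat(sprintf("  family: %s%s\n", x$family,
              if (!is.na(x$chain_length))
                sprintf(", acyl chain C%d (anchor error %+.3f Da)",
                        x$chain_length, x$lipid_error) else ""))
  cat("  sequence:", sequence_string(x$sequence), "\n")
  cat(sprintf("  b ladder: %d rungs; y ladder: %d rungs; %d complement pair(s)\n",
              length(x$b_ladder$rungs), length(x$y_ladder$rungs),
              nrow(x$complements)))
  if (isTRUE(x$water_loss$matched)) {
    cat(sprintf("  water loss [M-H2O]+ at %.2f (error %+.3f Da)\n",
                x$water_loss$mz, x$water_loss$error))
  }
  cat(sprintf("  score: %.3f\n", x$score))
  invisible(x)
}

#' @export
summary.lipopeptide_annotation <- function(object, ...) {
  annotation_table(list(object))
}
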