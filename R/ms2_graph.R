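#' Build the spectrum graph of an MS2 peak list
#'
#' Formalises manual fragment-ladder differencing: nodes are peaks, and a
#' directed edge u -> v (low to high m/z) exists whenever `v - u` matches
#' some residue mass within `tol`. The graph is acyclic by construction;
#' fragment-ion ladders are paths in it.
#'
#' @param spectrum A [ms_spectrum()] (any peak list is accepted).
#' @param tol Residue-step matching tolerance in Da.
#' @param table A [residue_mass_table()].
#' @param mz_max Optional upper m/z cut; peaks above it (e.g. the precursor
#'   ion and its dehydration satellite, which are not backbone fragments)
#'   are excluded from the graph.
#' @return An object of class `spectrum_graph`: peaks, an edge table
#'   (`from`, `to`, `delta`) and the per-edge residue candidate sets.
#' @examples
#' g <- build_spectrum_graph(ms_spectrum(c(441.05, 554.07), ms_level = 2,
#'                                       precursor_mz = 994))
#' g$edges
#' @export
build_spectrum_graph <- function(spectrum, tol = 0.8,
                                 table = residue_mass_table(),
                                 mz_max = NULL) {
  stopifnot(tol > 0)
  peaks <- if (inherits(spectrum, "mass_spectrum")) spectrum$peaks
           else data.frame(mz = sort(as.numeric(spectrum)), intensity = 1)
  if (!is.null(mz_max)) peaks <- peaks[peaks$mz <= mz_max, , drop = FALSE]
  rownames(peaks) <- NULL
  n <- nrow(peaks)
  from <- integer(); to <- integer(); delta <- numeric()
  candidates <- list()
  if (n >= 2) {
    rng <- range(table$reporting)
    for (i in seq_len(n - 1)) {
      d <- peaks$mz - peaks$mz[i]
      js <- which(d >= rng[1] - tol & d <= rng[2] + tol)
      for (j in js) {
        cand <- match_residue(d[j], tol, table)
        if (nrow(cand) > 0) {
          from <- c(from, i); to <- c(to, j); delta <- c(delta, d[j])
          candidates[[length(candidates) + 1L]] <- cand
        }
      }
    }
  }
  structure(list(peaks = peaks,
                 edges = data.frame(from = from, to = to, delta = delta),
                 candidates = candidates,
                 tol = tol,
                 precursor_mz = if (inherits(spectrum, "mass_spectrum"))
                   spectrum$precursor_mz else NULL),
            class = "spectrum_graph")
}

#' @export
print.spectrum_graph <- function(x, ...) {
  cat(sprintf("Spectrum graph: %d peaks, %d residue-labelled edges (tol %.2f Da)\n",
              nrow(x$peaks), nrow(x$edges), x$tol))
  invisible(x)
}

new_ion_ladder <- function(graph, path, ion_type = NA_character_) {
  if (length(path) < 2) {
    return(structure(list(ion_type = ion_type, rungs = numeric(),
                          intensities = numeric(), deltas = numeric(),
                          steps = list(), total_intensity = 0),
                     class = "ion_ladder"))
  }
  rungs <- graph$peaks$mz[path]
  steps <- vector("list", length(path) - 1L)
  for (k in seq_len(length(path) - 1L)) {
    e <- which(graph$edges$from == path[k] & graph$edges$to == path[k + 1L])
    steps[[k]] <- graph$candidates[[e[1]]]
  }
  structure(list(ion_type = ion_type,
                 rungs = rungs,
                 intensities = graph$peaks$intensity[path],
                 deltas = diff(rungs),
                 steps = steps,
                 total_intensity = sum(graph$peaks$intensity[path])),
            class = "ion_ladder")
}

#' @export
print.ion_ladder <- function(x, ...) {
  if (length(x$rungs) == 0) {
    cat("Empty ion ladder\n")
    return(invisible(x))
  }
  cat(sprintf("%s ladder, %d rungs:\n",
              if (is.na(x$ion_type)) "Ion" else paste0(x$ion_type, "-type"),
              length(x$rungs)))
  cat(" ", paste(sprintf("%.2f", x$rungs), collapse = " -> "), "\n")
  best <- vapply(x$steps, function(s) s$symbol[1], "")
  cat("  steps:", paste(best, collapse = ", "), "\n")
  invisible(x)
}

# Deterministic path comparison: longer wins, then larger summed intensity,
# then lower starting m/z, then lexicographically smaller m/z sequence.
path_better <- function(a, b, peaks) {
  if (is.null(b)) return(TRUE)
  if (length(a) != length(b)) return(length(a) > length(b))
  ia <- sum(peaks$intensity[a]); ib <- sum(peaks$intensity[b])
  if (ia != ib) return(ia > ib)
  ma <- peaks$mz[a]; mb <- peaks$mz[b]
  if (ma[1] != mb[1]) return(ma[1] < mb[1])
  d <- which(ma != mb)
  if (length(d) == 0) return(FALSE)
  ma[d[1]] < mb[d[1]]
}

#' Extract fragment-ion ladders from a spectrum graph
#'
#' With `strategy = "longest"` returns the single best path: longest by rung
#' count, ties broken by greater total intensity, then by lower starting
#' m/z (fully deterministic). With `strategy = "maximal"` returns every
#' maximal path (one that can be neither prepended nor extended), which is
#' the candidate set [annotate_spectrum()] scores against family templates.
#'
#' @param graph A [build_spectrum_graph()] result.
#' @param strategy `"longest"` or `"maximal"`.
#' @param max_paths Safety cap on the number of enumerated maximal paths.
#' @return An `ion_ladder` (possibly empty) for `"longest"`; a list of
#'   `ion_ladder`s for `"maximal"`.
#' @export
extract_ladder <- function(graph, strategy = c("longest", "maximal"),
                           max_paths = 10000L) {
  strategy <- match.arg(strategy)
  n <- nrow(graph$peaks)
  if (n == 0 || nrow(graph$edges) == 0) {
    return(if (strategy == "longest") new_ion_ladder(graph, integer())
           else list())
  }
  preds <- lapply(seq_len(n), function(v) graph$edges$from[graph$edges$to == v])
  succs <- lapply(seq_len(n), function(v) graph$edges$to[graph$edges$from == v])
  if (strategy == "longest") {
    best <- vector("list", n)
    for (v in seq_len(n)) {      # peaks are in ascending m/z order
      bv <- v
      for (u in preds[[v]]) {
        cand <- c(best[[u]], v)
        if (path_better(cand, bv, graph$peaks)) bv <- cand
      }
      best[[v]] <- bv
    }
    overall <- NULL
    for (v in seq_len(n)) {
      if (path_better(best[[v]], overall, graph$peaks)) overall <- best[[v]]
    }
    if (length(overall) < 2) return(new_ion_ladder(graph, integer()))
    return(new_ion_ladder(graph, overall))
  }
  paths <- maximal_paths(graph, max_paths)
  lapply(paths, function(p) new_ion_ladder(graph, p))
}

# All maximal paths (node index vectors, length >= 2) of a spectrum graph.
maximal_paths <- function(graph, max_paths = 10000L) {
  n <- nrow(graph$peaks)
  if (n == 0 || nrow(graph$edges) == 0) return(list())
  preds <- lapply(seq_len(n), function(v) graph$edges$from[graph$edges$to == v])
  succs <- lapply(seq_len(n), function(v) graph$edges$to[graph$edges$from == v])
  paths <- list()
  grow <- function(path) {
    if (length(paths) >= max_paths) return()
    nxt <- succs[[path[length(path)]]]
    if (length(nxt) == 0) {
      if (length(path) >= 2) paths[[length(paths) + 1L]] <<- path
    } else {
      for (j in nxt) grow(c(path, j))
    }
  }
  for (v in which(lengths(preds) == 0)) grow(v)
  if (length(paths) >= max_paths) {
    warning("maximal-path enumeration hit the cap of ", max_paths, " paths")
  }
  paths
}

# Every contiguous subpath (length >= 2) of the maximal paths, deduplicated.
# Spurious one-off extensions of a true fragment ladder (a suffix-ion peak
# sitting one residue mass away from its head, say) make the true ladder
# non-maximal; windowing the maximal paths restores it as a candidate.
candidate_subpaths <- function(graph, max_paths = 10000L) {
  out <- list(); seen <- character()
  for (p in maximal_paths(graph, max_paths)) {
    r <- length(p)
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        sub <- p[i:j]
        key <- paste(sub, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- sub
        }
      }
    }
  }
  out
}
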