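# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations, kept separate from the implementation
# paths they check.

# Scan the full reporting table directly (no Gln/Lys co-reporting).
oracle_match_residue <- function(delta, tol, table = residue_mass_table()) {
  rep_tab <- table$reporting
  hits <- names(rep_tab)[abs(delta - rep_tab) <= tol]
  hits[order(abs(delta - rep_tab[hits]), hits)]
}

# Is `small` a contiguous subsequence of `big`?
is_contiguous_sub <- function(small, big) {
  ns <- length(small); nb <- length(big)
  if (ns > nb) return(FALSE)
  for (s in seq_len(nb - ns + 1)) {
    if (all(big[s:(s + ns - 1)] == small)) return(TRUE)
  }
  FALSE
}

# All maximal spacing-chains by exhaustive enumeration over all starts and
# all extensions, discarding chains contained in a longer chain.
oracle_chains <- function(mz, spacing, tol, min_length) {
  mz <- sort(unique(mz))
  n <- length(mz)
  all_chains <- list()
  extend <- function(chain) {
    nxt <- which(abs(mz - mz[chain[length(chain)]] - spacing) <= tol &
                   mz > mz[chain[length(chain)]])
    if (length(nxt) == 0) {
      all_chains[[length(all_chains) + 1L]] <<- chain
    } else {
      for (j in nxt) extend(c(chain, j))
    }
  }
  for (i in seq_len(n)) extend(i)
  keep <- vapply(seq_along(all_chains), function(i) {
    !any(vapply(seq_along(all_chains), function(j) {
      j != i && length(all_chains[[j]]) > length(all_chains[[i]]) &&
        is_contiguous_sub(all_chains[[i]], all_chains[[j]])
    }, TRUE))
  }, TRUE)
  chains <- all_chains[keep]
  chains <- Filter(function(c) length(c) >= min_length, chains)
  # unique member-mz vectors, canonically ordered
  out <- unique(lapply(chains, function(c) mz[c]))
  out[order(vapply(out, function(m) m[1], 1),
            vapply(out, length, 1L))]
}

# Exhaustive longest-path search over a spectrum graph: enumerate every
# path (any start), then apply the documented tie rules.
oracle_longest_path <- function(graph) {
  n <- nrow(graph$peaks)
  edges <- graph$edges
  paths <- list()
  extend <- function(path) {
    nxt <- edges$to[edges$from == path[length(path)]]
    paths[[length(paths) + 1L]] <<- path
    for (j in nxt) extend(c(path, j))
  }
  for (v in seq_len(n)) extend(v)
  paths <- Filter(function(p) length(p) >= 2, paths)
  if (length(paths) == 0) return(integer())
  best <- NULL
  for (p in paths) {
    if (is.null(best)) { best <- p; next }
    lp <- length(p); lb <- length(best)
    if (lp != lb) { if (lp > lb) best <- p; next }
    ip <- sum(graph$peaks$intensity[p]); ib <- sum(graph$peaks$intensity[best])
    if (ip != ib) { if (ip > ib) best <- p; next }
    mp <- graph$peaks$mz[p]; mb <- graph$peaks$mz[best]
    if (mp[1] != mb[1]) { if (mp[1] < mb[1]) best <- p; next }
    d <- which(mp != mb)
    if (length(d) > 0 && mp[d[1]] < mb[d[1]]) best <- p
  }
  best
}

# Brute-force MIC call: lowest no-growth concentration, flag growth above.
oracle_mic <- function(conc, growth) {
  ng <- conc[!growth]
  if (length(ng) == 0) return(list(mic = NA_real_, reached = FALSE,
                                   monotone = TRUE))
  mic <- min(ng)
  list(mic = mic, reached = TRUE, monotone = !any(growth[conc > mic]))
}

# A random spectrum with some residue-spaced structure plus uniform noise.
random_ladder_spectrum <- function(n_peaks, table = residue_mass_table()) {
  res <- unname(table$reporting)
  start <- stats::runif(1, 150, 400)
  chain <- start
  for (k in seq_len(sample(0:5, 1))) {
    chain <- c(chain, chain[length(chain)] + sample(res, 1) +
                 stats::rnorm(1, 0, 0.2))
  }
  extra <- stats::runif(max(0, n_peaks - length(chain)), 100, 1200)
  mz <- sort(unique(c(chain, extra)))[seq_len(min(n_peaks,
                                                  length(chain) +
                                                    length(extra)))]
  ms_spectrum(mz, stats::runif(length(mz), 1, 100))
}

printed_994_peaks <- function() {
  c(341.13, 440.16, 553.99,             # y-type suffix ladder
    441.05, 554.07, 653.36, 768.42, 881.66,  # b-type ladder
    976.53)                             # dehydration ion
}

printed_1008_peaks <- function() {
  c(341.03, 454.05, 567.06, 667.64, 781.59, 894.17,  # b-type ladder
    876.17,                             # dehydration of 894.17
    1007.65)                            # molecular ion
}
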