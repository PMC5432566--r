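# Evaluate code under a temporary RNG state so generators are reproducible
# from an explicit seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Spectrum simulation configuration
#'
#' @param template A complete [family_templates()] entry with a `canonical`
#'   residue sequence.
#' @param chain_lengths Acyl carbon counts to simulate.
#' @param include_na_adducts Add \eqn{[M+Na]^+} partners to the MS1 view.
#' @param include_water_loss Add the \eqn{[M-H_2O]^+} satellite to MS2.
#' @param mz_jitter_sd Gaussian m/z jitter applied to true MS2 fragment
#'   peaks, Da. The default 0.2 Da emulates unit-resolution CID accuracy
#'   (observed deviations of up to ~0.75 Da are then ~3.75 sd).
#' @param ms1_jitter_sd Gaussian m/z jitter applied to the MS1 survey peaks,
#'   Da. Survey centroids are far more accurate than CID fragment
#'   arithmetic; the 0.02 Da default is consistent with the 0.1 Da
#'   homolog-spacing tolerance.
#' @param n_decoys Number of decoy noise peaks per MS2 spectrum.
#' @param decoy_mz_range m/z interval decoys are drawn from, Da.
#' @param decoy_exclusion Minimum distance (Da) of a decoy from any existing
#'   peak and from any residue relation with an existing peak, so that
#'   default-configuration decoys cannot join a ladder. Must exceed the
#'   residue step tolerance (0.8 Da by default).
#' @param adversarial_decoys Place decoys exactly at residue offsets from
#'   true peaks instead, to stress tie-breaking (the exclusion rule is then
#'   ignored).
#' @param intensity_model `"constant"` (all 1) or `"lognormal"`.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_spectra_config`.
#' @export
sim_spectra_config <- function(template = surfactin_template(),
                               chain_lengths = 12:15,
                               include_na_adducts = TRUE,
                               include_water_loss = TRUE,
                               mz_jitter_sd = 0.2,
                               ms1_jitter_sd = 0.02,
                               n_decoys = 20L,
                               decoy_mz_range = c(200, 1000),
                               decoy_exclusion = 2.0,
                               adversarial_decoys = FALSE,
                               intensity_model = c("lognormal", "constant"),
                               intensity_meanlog = log(1e4),
                               intensity_sdlog = 1,
                               seed = 1L) {
  stopifnot(mz_jitter_sd >= 0, ms1_jitter_sd >= 0, n_decoys >= 0,
            length(decoy_mz_range) == 2, diff(decoy_mz_range) > 0,
            isTRUE(template$complete), !is.null(template$canonical))
  if (!adversarial_decoys && decoy_exclusion <= 0.8) {
    stop("decoy_exclusion must exceed the residue step tolerance (0.8 Da)")
  }
  structure(list(template = template,
                 chain_lengths = as.integer(chain_lengths),
                 include_na_adducts = include_na_adducts,
                 include_water_loss = include_water_loss,
                 mz_jitter_sd = mz_jitter_sd,
                 ms1_jitter_sd = ms1_jitter_sd,
                 n_decoys = as.integer(n_decoys),
                 decoy_mz_range = as.numeric(decoy_mz_range),
                 decoy_exclusion = decoy_exclusion,
                 adversarial_decoys = adversarial_decoys,
                 intensity_model = match.arg(intensity_model),
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 seed = as.integer(seed)),
            class = "sim_spectra_config")
}

#' Theoretical spectrum of one lipopeptide homolog
#'
#' Computes the noiseless fragment pattern of a Cn homolog of a family
#' template: the protonated precursor `proton + L(n) + sum(residues)`,
#' b-type rungs `proton + L(n) + prefix sums` (prefix lengths 2..6 by
#' default, mirroring the observable CID prefix ions), and y-type rungs as
#' plain suffix residue sums (lengths 3..5 by default), plus optionally the
#' precursor's water-loss satellite.
#'
#' @param template A complete family template with `canonical` residues.
#' @param n Acyl carbon count (within the template's lipid range).
#' @param prefix_lengths,suffix_lengths Which b/y rungs are produced.
#' @param include_water_loss Add the \eqn{[M-H_2O]^+} peak.
#' @param include_precursor Include the molecular-ion peak in the MS2 list.
#' @param series,table,adducts Mass model components.
#' @return A list with `precursor_mz`, `ms1_peak` (same value), `ms2`
#'   (an [ms_spectrum()]) and `provenance` (a data.frame tagging each peak
#'   as b / y / water_loss / precursor).
#' @examples
#' generate_theoretical_spectrum(n = 12)$precursor_mz   # 994.64
#' @export
generate_theoretical_spectrum <- function(template = surfactin_template(),
                                          n,
                                          prefix_lengths = 2:6,
                                          suffix_lengths = 3:5,
                                          include_water_loss = TRUE,
                                          include_precursor = TRUE,
                                          series = lipid_series(),
                                          table = residue_mass_table(),
                                          adducts = adduct_constants()) {
  stopifnot(isTRUE(template$complete), !is.null(template$canonical))
  if (n < template$lipid_range[1] || n > template$lipid_range[2]) {
    stop("chain length C", n, " outside the template's lipid range")
  }
  res <- residue_mass(template$canonical, table)
  L <- length(res)
  stopifnot(max(prefix_lengths) < L, max(suffix_lengths) < L)
  base <- adducts$proton + lipid_mass(n, series)
  precursor <- base + sum(res)
  b <- base + cumsum(res)[prefix_lengths]
  y <- vapply(suffix_lengths, function(k) sum(res[(L - k + 1):L]), 1)
  mz <- c(b, y)
  kind <- c(rep("b", length(b)), rep("y", length(y)))
  if (include_water_loss) {
    mz <- c(mz, precursor - adducts$water)
    kind <- c(kind, "water_loss")
  }
  if (include_precursor) {
    mz <- c(mz, precursor)
    kind <- c(kind, "precursor")
  }
  o <- order(mz)
  ms2 <- ms_spectrum(mz[o], 1, ms_level = 2L, precursor_mz = precursor,
                     rt = synthetic_rt(n),
                     id = sprintf("%s_C%d", template$name, n))
  list(precursor_mz = precursor,
       ms1_peak = precursor,
       ms2 = ms2,
       provenance = data.frame(mz = mz[o], kind = kind[o]))
}

# Retention times increase with chain length (more hydrophobic homologs
# elute later on reversed phase); anchored to C12 ~ 6.5 min.
synthetic_rt <- function(n) 6.53 + 1.08 * (n - 12)

#' Add measurement noise and decoy peaks to a spectrum
#'
#' Applies Gaussian m/z jitter to the true peaks, inserts uniformly drawn
#' decoy peaks that respect the exclusion distance from every existing peak
#' and from every residue relation (so that, by construction, default-mode
#' decoys cannot take part in a ladder), and assigns intensities under the
#' configured model. Fully reproducible from the seed.
#'
#' @param spectrum A [ms_spectrum()].
#' @param config A [sim_spectra_config()].
#' @param seed Seed for this call (defaults to `config$seed`).
#' @param table Residue table used for the exclusion rule.
#' @return The noisy [ms_spectrum()], with a `provenance` attribute marking
#'   decoys.
#' @export
add_noise <- function(spectrum, config = sim_spectra_config(),
                      seed = config$seed, table = residue_mass_table()) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  res <- unname(table$reporting)
  with_seed(seed, {
    true_mz <- spectrum$peaks$mz
    mz <- true_mz + stats::rnorm(length(true_mz), 0, config$mz_jitter_sd)
    decoys <- numeric(0)
    if (config$n_decoys > 0) {
      if (config$adversarial_decoys) {
        for (i in seq_len(config$n_decoys)) {
          p <- sample(c(true_mz, decoys), 1)
          r <- sample(res, 1) * sample(c(-1, 1), 1)
          decoys <- c(decoys, p + r)
        }
      } else {
        for (i in seq_len(config$n_decoys)) {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            d <- stats::runif(1, config$decoy_mz_range[1],
                              config$decoy_mz_range[2])
            gaps <- abs(d - c(true_mz, decoys))
            ok <- all(gaps >= config$decoy_exclusion) &&
              all(vapply(gaps, function(g)
                all(abs(g - res) >= config$decoy_exclusion), TRUE))
            if (ok) { decoys <- c(decoys, d); placed <- TRUE; break }
          }
          if (!placed) {
            stop("could not place decoy ", i,
                 " after 1000 tries; relax decoy_exclusion or widen the range")
          }
        }
      }
    }
    all_mz <- c(mz, decoys)
    all_mz[all_mz <= 0] <- 1e-3
    intensity <- switch(config$intensity_model,
      # constant: true peaks keep their intensities, decoys sit at the median
      constant = c(spectrum$peaks$intensity,
                   rep(stats::median(spectrum$peaks$intensity),
                       length(decoys))),
      lognormal = stats::rlnorm(length(all_mz), config$intensity_meanlog,
                                config$intensity_sdlog))
    out <- ms_spectrum(all_mz, intensity, ms_level = spectrum$ms_level,
                       precursor_mz = spectrum$precursor_mz,
                       rt = spectrum$rt, id = spectrum$id,
                       metadata = spectrum$metadata)
    prov <- data.frame(mz = all_mz,
                       kind = c(rep("true", length(mz)),
                                rep("decoy", length(decoys))))
    attr(out, "provenance") <- prov[order(prov$mz), ]
    out
  })
}

#' Simulate a full LC-MS run of a homolog family
#'
#' Produces one MS1 spectrum holding every protonated precursor (plus
#' sodiated partners when enabled) and one MS2 spectrum per precursor, with
#' retention times increasing with chain length, jitter, decoys and
#' intensities per the configuration.
#'
#' @param config A [sim_spectra_config()].
#' @return A [spectrum_set()]; the `truth` attribute records the template,
#'   the true sequences and precursors, and per-spectrum peak provenance,
#'   enabling recovery scoring.
#' @examples
#' run <- generate_lcms_run(sim_spectra_config(seed = 7))
#' summary(run)
#' @export
generate_lcms_run <- function(config = sim_spectra_config()) {
  stopifnot(length(config$chain_lengths) > 0)
  theo <- lapply(config$chain_lengths, function(n)
    generate_theoretical_spectrum(config$template, n,
                                  include_water_loss =
                                    config$include_water_loss))
  precs <- vapply(theo, function(t) t$precursor_mz, 1)
  ms1_mz <- precs
  ms1_kind <- rep("protonated", length(precs))
  if (config$include_na_adducts) {
    ms1_mz <- c(ms1_mz, precs + adduct_constants()$sodium_minus_hydrogen)
    ms1_kind <- c(ms1_kind, rep("sodiated", length(precs)))
  }
  o <- order(ms1_mz)
  ms1 <- ms_spectrum(ms1_mz[o], 1, ms_level = 1L, id = "ms1_survey")
  ms1_noisy <- with_seed(config$seed, {
    jit <- ms1$peaks$mz + stats::rnorm(n_peaks(ms1), 0, config$ms1_jitter_sd)
    ms_spectrum(jit, 1, ms_level = 1L, id = "ms1_survey")
  })
  ms2 <- vector("list", length(theo))
  prov <- vector("list", length(theo))
  for (i in seq_along(theo)) {
    noisy <- add_noise(theo[[i]]$ms2, config, seed = config$seed + i)
    ms2[[i]] <- noisy
    prov[[i]] <- list(id = noisy$id,
                      chain_length = config$chain_lengths[i],
                      true_peaks = theo[[i]]$provenance,
                      observed = attr(noisy, "provenance"))
  }
  set <- spectrum_set(c(list(ms1_noisy), ms2),
                      run_metadata = list(generator = "surfannot simulator",
                                          seed = config$seed))
  attr(set, "truth") <- list(
    template = config$template$name,
    sequence = config$template$canonical,
    chain_lengths = config$chain_lengths,
    precursors = precs,
    ms1 = data.frame(mz = ms1_mz[o], kind = ms1_kind[o]),
    ms2 = prov)
  set
}

#' Bioassay simulation configuration
#'
#' @param true_curve Data frame with columns `condition`, `time` (days) and
#'   `rate` (true residual rate, percent) describing the stability
#'   trajectories to emulate. The default follows a thermal-stability
#'   design: 40-80 degC held for 10 days, with activity retention ~96-85%
#'   graded by temperature.
#' @param dac_control Inhibition-zone diameter of the fresh control, mm.
#' @param noise_sd Gaussian measurement noise on zone diameters, mm.
#' @param n_replicates Replicate plates per condition and time.
#' @param control_label Condition label used for the control rows.
#' @param seed Integer seed.
#' @return An object of class `sim_bioassay_config`.
#' @export
sim_bioassay_config <- function(true_curve = default_stability_curve(),
                                dac_control = 32,
                                noise_sd = 0.5,
                                n_replicates = 3L,
                                control_label = "control",
                                seed = 1L) {
  stopifnot(dac_control > 0, noise_sd >= 0, n_replicates >= 1,
            all(c("condition", "time", "rate") %in% names(true_curve)))
  structure(list(true_curve = true_curve, dac_control = dac_control,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 control_label = control_label, seed = as.integer(seed)),
            class = "sim_bioassay_config")
}

#' @rdname sim_bioassay_config
#' @export
default_stability_curve <- function() {
  temps <- c("40C", "50C", "60C", "70C", "80C")
  final <- c(96, 95, 93, 91, 85)
  times <- c(0, 2, 4, 6, 8, 10)
  do.call(rbind, lapply(seq_along(temps), function(i) {
    data.frame(condition = temps[i], time = times,
               rate = 100 + (final[i] - 100) * times / max(times))
  }))
}

#' Simulate a bioassay zone-diameter table
#'
#' Draws `DAC(condition, t) = dac_control * rate(condition, t) / 100 +
#' noise` per replicate (negative draws truncated to zero), plus control
#' rows at the true control diameter, matching the input layout expected by
#' [summarize_stability()].
#'
#' @param config A [sim_bioassay_config()].
#' @return A data.frame with columns `condition`, `time`, `replicate`,
#'   `dac_mm`.
#' @examples
#' head(generate_bioassay_table(sim_bioassay_config(seed = 3)))
#' @export
generate_bioassay_table <- function(config = sim_bioassay_config()) {
  with_seed(config$seed, {
    curve <- config$true_curve
    rows <- do.call(rbind, lapply(seq_len(nrow(curve)), function(i) {
      dac <- config$dac_control * curve$rate[i] / 100 +
        stats::rnorm(config$n_replicates, 0, config$noise_sd)
      data.frame(condition = curve$condition[i], time = curve$time[i],
                 replicate = seq_len(config$n_replicates),
                 dac_mm = pmax(dac, 0))
    }))
    ctrl <- do.call(rbind, lapply(unique(curve$time), function(t) {
      dac <- config$dac_control +
        stats::rnorm(config$n_replicates, 0, config$noise_sd)
      data.frame(condition = config$control_label, time = t,
                 replicate = seq_len(config$n_replicates),
                 dac_mm = pmax(dac, 0))
    }))
    out <- rbind(rows, ctrl)
    rownames(out) <- NULL
    out
  })
}
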