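test_that("theoretical precursors match independent residue-sum arithmetic", {
  # oracle: proton + CnH(2n-2)O2 + seven independently summed residue masses
  H <- 1.00782503207; O <- 15.9949146221
  res_sum <- 129.04259 + 113.08406 + 113.08406 + 99.06841 + 115.02694 +
    113.08406 + 113.08406
  oracle <- function(n) 1.00727646688 + (12 + 2 * H) * n + 2 * O - 2 * H +
    res_sum
  expect_equal(generate_theoretical_spectrum(n = 12)$precursor_mz,
               oracle(12), tolerance = 1e-9)
  expect_equal(generate_theoretical_spectrum(n = 12)$precursor_mz, 994.64,
               tolerance = 1e-2)
  expect_equal(generate_theoretical_spectrum(n = 15)$precursor_mz, 1036.69,
               tolerance = 1e-2)
  expect_equal(generate_theoretical_spectrum(n = 15)$precursor_mz -
                 generate_theoretical_spectrum(n = 14)$precursor_mz,
               14.01565007, tolerance = 1e-8)
  expect_error(generate_theoretical_spectrum(n = 25), "lipid range")
})

test_that("noiseless synthetic spectra carry the declared peak structure", {
  th <- generate_theoretical_spectrum(n = 14)
  expect_equal(sum(th$provenance$kind == "b"), 5)    # prefix lengths 2..6
  expect_equal(sum(th$provenance$kind == "y"), 3)    # suffix lengths 3..5
  expect_true("water_loss" %in% th$provenance$kind)
  expect_true("precursor" %in% th$provenance$kind)
  expect_equal(th$ms2$precursor_mz, th$precursor_mz)
})

test_that("add_noise is deterministic and the null config is the identity", {
  th <- generate_theoretical_spectrum(n = 13)$ms2
  cfg0 <- sim_spectra_config(mz_jitter_sd = 0, n_decoys = 0,
                             intensity_model = "constant")
  expect_equal(add_noise(th, cfg0)$peaks, th$peaks)
  cfg <- sim_spectra_config(seed = 99)
  a <- add_noise(th, cfg, seed = 99)
  b <- add_noise(th, cfg, seed = 99)
  expect_identical(a$peaks, b$peaks)
  c2 <- add_noise(th, cfg, seed = 100)
  expect_false(identical(a$peaks, c2$peaks))
})

test_that("decoys respect the exclusion distance from residue relations", {
  th <- generate_theoretical_spectrum(n = 12)$ms2
  cfg <- sim_spectra_config(mz_jitter_sd = 0, n_decoys = 20,
                            decoy_exclusion = 2, seed = 4)
  noisy <- add_noise(th, cfg, seed = 4)
  prov <- attr(noisy, "provenance")
  dec <- prov$mz[prov$kind == "decoy"]
  res <- unname(residue_mass_table()$reporting)
  for (d in dec) {
    gaps <- abs(d - th$peaks$mz)
    expect_true(all(gaps >= 2))
    expect_true(all(vapply(gaps, function(g) all(abs(g - res) >= 2), TRUE)))
  }
})

test_that("a default simulated run has the constructed MS1/MS2 structure", {
  run <- generate_lcms_run(sim_spectra_config(seed = 21))
  lv <- vapply(run$spectra, function(s) s$ms_level, 1L)
  ms1 <- run$spectra[[which(lv == 1)]]
  expect_equal(sum(lv == 2), 4)
  expect_equal(nrow(ms1$peaks), 8)      # 4 protonated + 4 sodiated
  found <- detect_homolog_series(ms1, tol = 0.1, min_length = 3)
  truth <- attr(run, "truth")
  prot <- found[vapply(found, function(s)
    all(abs(s$member_mzs - truth$precursors) < 0.2), TRUE)]
  expect_length(prot, 1)
  pairs <- pair_sodium_adducts(prot[[1]], ms1, tol = 0.1)
  expect_equal(nrow(pairs), 4)
  # retention times increase with chain length
  rts <- vapply(run$spectra[lv == 2], function(s) s$rt, 1)
  expect_true(all(diff(rts) > 0))
})

test_that("a single homolog yields no series at the default minimum length", {
  run <- generate_lcms_run(sim_spectra_config(chain_lengths = 14,
                                              include_na_adducts = FALSE,
                                              seed = 2))
  ms1 <- run$spectra[[1]]
  expect_length(detect_homolog_series(ms1, tol = 0.1, min_length = 3), 0)
})

test_that("MS1 precursor spacing is exactly CH2 before jitter", {
  truth <- attr(generate_lcms_run(sim_spectra_config(seed = 1)), "truth")
  expect_equal(diff(truth$precursors), rep(14.01565007, 3), tolerance = 1e-9)
})

test_that("bioassay tables are reproducible and unbiased when noiseless", {
  flat <- data.frame(condition = "40C", time = c(0, 5, 10), rate = 100)
  cfg0 <- sim_bioassay_config(true_curve = flat, dac_control = 20,
                              noise_sd = 0, seed = 1)
  tab <- generate_bioassay_table(cfg0)
  expect_true(all(tab$dac_mm == 20))

  cfg <- sim_bioassay_config(seed = 8)
  expect_identical(generate_bioassay_table(cfg), generate_bioassay_table(cfg))
})

test_that("estimated residual rates recover the true curve (Monte Carlo)", {
  cfg <- sim_bioassay_config(noise_sd = 0.5, n_replicates = 6, seed = 13)
  tab <- generate_bioassay_table(cfg)
  summ <- summarize_stability(tab, "control")
  curve <- cfg$true_curve
  for (i in seq_len(nrow(summ))) {
    truth <- curve$rate[curve$condition == summ$condition[i] &
                          curve$time == summ$time[i]]
    # propagated sd of the mean rate: noise on both numerator and control
    se <- 100 / cfg$dac_control *
      cfg$noise_sd * sqrt(2 / cfg$n_replicates)
    expect_lt(abs(summ$mean_rate[i] - truth), 3 * se + 1e-9)
  }
})
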