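test_that("terminal residues are read off the precursor gap", {
  t1 <- assign_terminal_residue(994, 881.66)
  expect_equal(t1$delta, 112.34)
  expect_equal(t1$candidates$symbol[1], "Leu/Ile")

  t2 <- assign_terminal_residue(1007.65, 894.17)
  expect_equal(t2$delta, 113.48)
  expect_equal(t2$candidates$symbol[1], "Leu/Ile")

  t3 <- assign_terminal_residue(994, 990)
  expect_equal(t3$delta, 4)
  expect_equal(nrow(t3$candidates), 0)

  expect_error(assign_terminal_residue(994, numeric(0)), "empty ladder")
})

test_that("the lipid anchor recovers the printed chain lengths", {
  a <- infer_lipid_anchor(441.05, c("Glu", "Leu/Ile"))
  expect_equal(a$n, 12L)
  expect_equal(a$error, -0.246, tolerance = 1e-3)

  a <- infer_lipid_anchor(341.03, "Glu")
  expect_equal(a$n, 13L)
  expect_lte(abs(a$error), 1.2)

  expect_error(infer_lipid_anchor(120, "Glu"), "residual")
})

test_that("b/y complements reconcile against the precursor", {
  p <- reconcile_complements(994, 441.05, 553.99)
  expect_equal(nrow(p), 1)
  expect_equal(p$sum_error, 1.04, tolerance = 1e-6)
  expect_equal(p$complement_mz, 440.01, tolerance = 1e-6)

  p <- reconcile_complements(994, 653.36, 341.13)
  expect_equal(p$sum_error, 0.49, tolerance = 1e-6)

  expect_equal(nrow(reconcile_complements(994, 600, 341.13)), 0)
})

test_that("family classification applies the surfactin structural rules", {
  seq_994 <- list("Glu", "Leu/Ile", "Leu/Ile", "Val", "Asp", "Leu/Ile",
                  "Leu/Ile")
  expect_equal(classify_family(seq_994, 12)$family, "Surfactin")

  seq_bad <- seq_994
  seq_bad[[5]] <- "Val"
  res <- classify_family(seq_bad, 12)
  expect_equal(res$family, "unassigned")
  fail <- res$report[!res$report$ok, ]
  expect_equal(fail$position, 5)
  expect_equal(fail$required, "Asp")

  seq_amb <- seq_994
  seq_amb[[6]] <- c("Asn", "Leu/Ile")
  expect_equal(classify_family(seq_amb, 12)$family, "Surfactin")

  # chain length outside the family's lipid range cannot match
  expect_equal(classify_family(seq_994, 20)$family, "unassigned")
})

test_that("the printed C12 spectrum annotates to the published structure", {
  sp <- ms_spectrum(printed_994_peaks(), ms_level = 2, precursor_mz = 994)
  a <- annotate_spectrum(sp)
  expect_equal(a$family, "Surfactin")
  expect_equal(a$chain_length, 12L)
  expect_equal(a$b_ladder$rungs, c(441.05, 554.07, 653.36, 768.42, 881.66))
  expect_equal(a$y_ladder$rungs, c(341.13, 440.16, 553.99))
  expect_equal(a$terminal$delta, 112.34)
  expect_equal(a$terminal$candidates$symbol[1], "Leu/Ile")
  expect_length(a$sequence, 7)
  expect_true(a$water_loss$matched)
  expect_equal(a$water_loss$mz, 976.53)
  # complement 440.01 = 994 - 553.99 reported with its +1.04 sum error
  expect_true(any(abs(a$complements$complement_mz - 440.01) < 1e-6))
})

test_that("the printed C13 spectrum annotates to Surfactin C13", {
  sp <- ms_spectrum(printed_1008_peaks(), ms_level = 2,
                    precursor_mz = 1007.65)
  a <- annotate_spectrum(sp)
  expect_equal(a$family, "Surfactin")
  expect_equal(a$chain_length, 13L)
  expect_equal(max(a$b_ladder$rungs), 894.17)
  expect_equal(length(a$b_ladder$rungs), 6)
  expect_equal(a$terminal$delta, 113.48)
  expect_equal(a$terminal$candidates$symbol[1], "Leu/Ile")
})

test_that("pure noise yields a valid unassigned annotation", {
  set.seed(5)
  sp <- ms_spectrum(sort(runif(15, 1000, 2000)) / 2.3, ms_level = 2,
                    precursor_mz = 994)
  a <- annotate_spectrum(sp)
  expect_equal(a$family, "unassigned")
  expect_true(is.na(a$chain_length))
})

test_that("decoys that join no residue relation never change an annotation", {
  base <- annotate_spectrum(ms_spectrum(printed_994_peaks(), ms_level = 2,
                                        precursor_mz = 994))
  for (seed in 1:5) {
    cfg <- sim_spectra_config(mz_jitter_sd = 0, n_decoys = 20, seed = seed)
    sp <- add_noise(ms_spectrum(printed_994_peaks(), ms_level = 2,
                                precursor_mz = 994), cfg, seed = seed)
    a <- annotate_spectrum(sp)
    expect_equal(a$family, base$family)
    expect_equal(a$chain_length, base$chain_length)
    expect_equal(a$b_ladder$rungs, base$b_ladder$rungs)
    expect_equal(a$y_ladder$rungs, base$y_ladder$rungs)
  }
})

test_that("reported complement pairs satisfy the tolerance on output", {
  cfg <- annotation_config()
  for (n in c(12, 14)) {
    a <- annotate_spectrum(generate_theoretical_spectrum(n = n)$ms2, cfg)
    if (nrow(a$complements) > 0) {
      expect_true(all(abs(a$complements$sum_error) <= cfg$comp_tol))
    }
  }
})

test_that("annotation requires an MS2 spectrum with precursor", {
  expect_error(annotate_spectrum(ms_spectrum(c(100, 200))), "MS2")
})
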