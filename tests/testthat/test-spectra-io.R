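test_that("spectra enforce peak invariants", {
  s <- ms_spectrum(c(300, 100, 200), c(1, 2, 3))
  expect_equal(s$peaks$mz, c(100, 200, 300))
  expect_message(s <- ms_spectrum(c(100, 100, 200), c(1, 2, 3)),
                 "duplicate")
  expect_equal(s$peaks$mz, c(100, 200))
  expect_equal(s$peaks$intensity, c(3, 3))
  expect_error(ms_spectrum(c(-1, 100)), "positive")
  expect_error(ms_spectrum(100, ms_level = 2), "precursor")
})

test_that("MGF files round-trip losslessly", {
  set <- spectrum_set(list(
    ms_spectrum(c(994.1234567, 1008.25, 1022.5), c(10, 20, 30),
                ms_level = 1, id = "survey",
                metadata = list(INSTRUMENT = "QTOF")),
    ms_spectrum(printed_994_peaks(), ms_level = 2, precursor_mz = 994,
                rt = 6.53, id = "C12")))
  p <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(set, p)
  back <- read_mgf(p)
  expect_length(back$spectra, 2)
  for (i in 1:2) {
    expect_equal(back$spectra[[i]]$peaks$mz, set$spectra[[i]]$peaks$mz,
                 tolerance = 1e-6)
    expect_equal(back$spectra[[i]]$ms_level, set$spectra[[i]]$ms_level)
    expect_equal(back$spectra[[i]]$id, set$spectra[[i]]$id)
  }
  expect_equal(back$spectra[[2]]$precursor_mz, 994)
  expect_equal(back$spectra[[2]]$rt, 6.53, tolerance = 1e-6)
  expect_equal(back$spectra[[1]]$metadata$INSTRUMENT, "QTOF")
})

test_that("malformed MGF input fails with located errors", {
  p <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=994", "100 1"), p)
  expect_error(read_mgf(p), "END IONS")
  writeLines(c("BEGIN IONS", "PEPMASS=994", "abc def", "END IONS"), p)
  expect_error(read_mgf(p), "line 3")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), p)
  expect_error(read_mgf(p), "PEPMASS")
  # an MS1 block needs no PEPMASS
  writeLines(c("BEGIN IONS", "MSLEVEL=1", "100 1", "END IONS"), p)
  expect_equal(read_mgf(p)$spectra[[1]]$ms_level, 1L)
})

test_that("peak tables are read with dialect mapping", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mass,height", "100,1", "200,2", "300,3", "400,4", "500,5"), p)
  s <- read_peak_table(p, delimiter = ",",
                       columns = c(mz = "mass", intensity = "height"))
  expect_equal(nrow(s$peaks), 5)
  expect_equal(s$peaks$intensity, 1:5)

  expect_error(read_peak_table(p, delimiter = ",",
                               columns = c(mz = "mz")), "mandated column")

  writeLines("mass,height", p)
  expect_warning(s <- read_peak_table(p, delimiter = ",",
                                      columns = c(mz = "mass")), "no rows")
  expect_equal(nrow(s$peaks), 0)

  writeLines(c("mass,height", "-5,1"), p)
  expect_error(read_peak_table(p, delimiter = ",",
                               columns = c(mz = "mass")), "non-positive")
})

test_that("annotation reports round-trip with per-step errors", {
  anns <- lapply(12:15, function(n)
    annotate_spectrum(generate_theoretical_spectrum(n = n)$ms2))
  p_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_report(anns, p_tsv, "tsv")
  tab <- read.delim(p_tsv)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$chain_length, 12:15)

  p_json <- withr::local_tempfile(fileext = ".json")
  write_annotation_report(anns, p_json, "json")
  back <- read_annotation_report(p_json)
  expect_length(back, 4)
  for (i in seq_along(anns)) {
    expect_equal(back[[i]]$precursor_mz, anns[[i]]$precursor_mz,
                 tolerance = 1e-9)
    expect_equal(back[[i]]$b_ladder$rungs, anns[[i]]$b_ladder$rungs,
                 tolerance = 1e-9)
    got_err <- unlist(lapply(back[[i]]$b_ladder$steps,
                             function(s) s$errors))
    want_err <- unlist(lapply(anns[[i]]$b_ladder$steps,
                              function(s) s$error))
    expect_equal(got_err, want_err, tolerance = 1e-9, ignore_attr = TRUE)
  }

  write_annotation_report(list(), p_tsv, "tsv")
  expect_equal(nrow(read.delim(p_tsv)), 0)
})
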