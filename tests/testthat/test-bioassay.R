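test_that("residual rate follows the DAC ratio formula", {
  expect_equal(residual_rate(18, 20), 90)
  expect_equal(residual_rate(20, 20), 100)
  expect_equal(residual_rate(0, 20), 0)
  expect_equal(residual_rate(25, 20), 125)   # may exceed 100
  expect_error(residual_rate(10, 0), "positive")
  expect_error(residual_rate(-1, 20), "non-negative")
})

test_that("residual rate is scale invariant", {
  set.seed(3)
  for (i in 1:50) {
    e <- runif(1, 0, 40); c <- runif(1, 1, 40); k <- runif(1, 0.1, 10)
    expect_equal(residual_rate(e, c), residual_rate(k * e, k * c))
  }
})

test_that("MIC calls match the dilution-series definition", {
  conc <- c(32, 16, 8, 4, 2, 1, 0.5, 0.25, 0.125, 0.0625)
  m <- mic_from_dilution(dilution_series(conc, c(F, F, T, T, T, T, T, T, T, T)))
  expect_equal(m$mic, 16)
  expect_true(m$monotone)

  m <- mic_from_dilution(dilution_series(conc, rep(TRUE, 10)))
  expect_false(m$reached)

  m <- mic_from_dilution(dilution_series(conc, c(F, T, F, T, T, T, T, T, T, T)))
  expect_equal(m$mic, 8)
  expect_false(m$monotone)
})

test_that("MIC control quality gates reject bad plates", {
  s <- dilution_series(c(32, 16), c(FALSE, TRUE),
                       controls = c(blank = FALSE, negative = FALSE,
                                    positive = FALSE))
  expect_error(mic_from_dilution(s), "positive control")
  s <- dilution_series(c(32, 16), c(FALSE, TRUE),
                       controls = c(blank = FALSE, negative = TRUE,
                                    positive = TRUE))
  expect_error(mic_from_dilution(s), "negative control")
})

test_that("MIC equals a brute-force scan on random series, any row order", {
  set.seed(17)
  for (i in 1:200) {
    k <- sample(3:10, 1)
    conc <- sort(2^sample(-4:6, k), decreasing = TRUE)
    growth <- runif(k) < 0.5
    perm <- sample(k)
    m <- mic_from_dilution(dilution_series(conc[perm], growth[perm]))
    want <- oracle_mic(conc, growth)
    expect_equal(m$mic, want$mic)
    expect_equal(m$reached, want$reached)
    expect_equal(m$monotone, want$monotone)
  }
})

test_that("zone grading uses left-closed bins anchored at 3 cm", {
  expect_equal(as.character(grade_dac(31)), "+++")
  expect_equal(as.character(grade_dac(5)), "-")
  expect_equal(as.character(grade_dac(20)), "++")
  expect_equal(as.character(grade_dac(c(9.99, 10, 20, 30))),
               c("-", "+", "++", "+++"))
  expect_error(grade_dac(-1), "non-negative")
  expect_error(grade_dac(10, thresholds = c(20, 10, 30)), "ascending")
})

test_that("zone grading is monotone non-decreasing", {
  d <- sort(runif(100, 0, 50))
  g <- grade_dac(d)
  expect_true(all(diff(as.integer(g)) >= 0))
})

test_that("stability summaries of a flat table are exactly 100%", {
  tab <- expand.grid(condition = c("control", "40C", "80C"),
                     time = c(0, 5, 10), replicate = 1:3)
  tab$dac_mm <- 20
  s <- summarize_stability(tab, "control")
  expect_true(all(s$mean_rate == 100))
  expect_true(all(s$sd_rate == 0))
  expect_true(all(s$n == 3))
  expect_false("control" %in% s$condition)
})

test_that("a missing time-matched control is an alignment error", {
  tab <- data.frame(condition = c("control", "40C", "40C"),
                    time = c(0, 0, 10), dac_mm = 20)
  expect_error(summarize_stability(tab, "control"), "alignment.*10")
})
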