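#' Residual activity rate from inhibition-zone diameters
#'
#' Residual rate (%) = DAC(experimental) / DAC(control) x 100, where DAC is
#' the diameter of the antibiotic circle (inhibition zone) in a plate
#' diffusion assay. Values above 100% are possible and preserved.
#'
#' @param dac_experimental Zone diameter(s) of the treated preparation, mm.
#' @param dac_control Zone diameter(s) of the fresh control, mm (> 0).
#' @return Residual rate(s) in percent.
#' @examples
#' residual_rate(18, 20)   # 90
#' @export
residual_rate <- function(dac_experimental, dac_control) {
  if (any(dac_control <= 0)) stop("control DAC must be positive")
  if (any(dac_experimental < 0)) stop("experimental DAC must be non-negative")
  100 * dac_experimental / dac_control
}

#' Construct a broth-dilution series
#'
#' @param concentration Concentrations in ug/mL (any order; stored strictly
#'   descending).
#' @param growth Logical growth calls, parallel to `concentration`.
#' @param controls Named logical list/vector with growth calls for the
#'   `blank`, `negative` and `positive` controls.
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(concentration, growth,
                            controls = c(blank = FALSE, negative = FALSE,
                                         positive = TRUE)) {
  stopifnot(length(concentration) == length(growth),
            all(concentration > 0), !anyDuplicated(concentration))
  o <- order(concentration, decreasing = TRUE)
  structure(list(rows = data.frame(concentration = concentration[o],
                                   growth = as.logical(growth)[o]),
                 controls = as.list(controls)),
            class = "dilution_series")
}

#' Minimum inhibitory concentration from a dilution series
#'
#' Quality gate: the positive control (inoculated, no compound) must show
#' growth and the negative control (sterile medium) must not; otherwise the
#' plate is rejected. The MIC is the lowest concentration showing no
#' visible growth. If growth reappears at a concentration above the MIC the
#' pattern is non-monotone and the call is flagged; if even the highest
#' concentration shows growth the MIC is not reached.
#'
#' @param series A [dilution_series()].
#' @return A list of class `mic_result` with `mic` (ug/mL, `NA` when not
#'   reached), `reached` and `monotone` logicals.
#' @examples
#' s <- dilution_series(c(32, 16, 8, 4), c(FALSE, FALSE, TRUE, TRUE))
#' mic_from_dilution(s)   # 16
#' @export
mic_from_dilution <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  ctl <- series$controls
  if (!isTRUE(as.logical(ctl$positive))) {
    stop("quality error: positive control shows no growth")
  }
  if (isTRUE(as.logical(ctl$negative))) {
    stop("quality error: negative control shows growth")
  }
  rows <- series$rows       # descending concentration
  no_growth <- which(!rows$growth)
  if (length(no_growth) == 0) {
    out <- list(mic = NA_real_, reached = FALSE, monotone = TRUE)
  } else {
    mic <- min(rows$concentration[no_growth])
    monotone <- !any(rows$growth[rows$concentration > mic])
    out <- list(mic = mic, reached = TRUE, monotone = monotone)
  }
  structure(out, class = "mic_result")
}

#' @export
print.mic_result <- function(x, ...) {
  if (!x$reached) {
    cat("MIC not reached (growth at every tested concentration)\n")
  } else {
    cat(sprintf("MIC = %g ug/mL%s\n", x$mic,
                if (!x$monotone)
                  " [non-monotone growth pattern: interpret with caution]"
                else ""))
  }
  invisible(x)
}

#' Grade an inhibition zone diameter
#'
#' Maps zone diameters onto the semi-quantitative activity scale
#' (-, +, ++, +++) by interval membership with left-closed bins. With the
#' default cut-offs (10, 20, 30 mm) a zone over 3 cm scores "+++".
#'
#' @param dac_mm Zone diameter(s), mm (non-negative).
#' @param thresholds Three strictly ascending cut-offs, mm.
#' @return A factor with ordered levels `-`, `+`, `++`, `+++`.
#' @examples
#' grade_dac(c(5, 15, 20, 31))
#' @export
grade_dac <- function(dac_mm, thresholds = c(10, 20, 30)) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be three strictly ascending cut-offs")
  }
  if (any(dac_mm < 0)) stop("zone diameter must be non-negative")
  cut(dac_mm, breaks = c(-Inf, thresholds, Inf),
      labels = c("-", "+", "++", "+++"),
      right = FALSE, ordered_result = TRUE)
}

#' Summarise a stability experiment as residual-rate trajectories
#'
#' Applies [residual_rate()] row-wise against the time-matched mean of the
#' control condition and aggregates replicates.
#'
#' @param table Data frame with columns `condition`, `time`, `dac_mm` and
#'   optionally `replicate`.
#' @param control_condition Label of the control rows; a control measurement
#'   must exist at every time point that appears in the data.
#' @return A data.frame of class `stability_summary` with one row per
#'   experimental condition and time: `condition`, `time`, `mean_rate`,
#'   `sd_rate` (NA for a single replicate), `n`.
#' @examples
#' tab <- generate_bioassay_table(sim_bioassay_config(seed = 2))
#' head(summarize_stability(tab, "control"))
#' @export
summarize_stability <- function(table, control_condition = "control") {
  stopifnot(all(c("condition", "time", "dac_mm") %in% names(table)))
  ctrl <- table[table$condition == control_condition, , drop = FALSE]
  exper <- table[table$condition != control_condition, , drop = FALSE]
  orphan <- setdiff(unique(exper$time), unique(ctrl$time))
  if (length(orphan) > 0) {
    bad <- exper[exper$time %in% orphan, , drop = FALSE]
    stop("alignment error: no time-matched control for ",
         nrow(bad), " row(s) at time(s) ",
         paste(sort(orphan), collapse = ", "))
  }
  ctrl_mean <- tapply(ctrl$dac_mm, ctrl$time, mean)
  rate <- residual_rate(exper$dac_mm,
                        ctrl_mean[as.character(exper$time)])
  key <- interaction(exper$condition, exper$time, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(rate), key), function(i) {
    data.frame(condition = exper$condition[i[1]],
               time = exper$time[i[1]],
               mean_rate = mean(rate[i]),
               sd_rate = if (length(i) > 1) stats::sd(rate[i]) else NA_real_,
               n = length(i))
  }))
  agg <- agg[order(agg$condition, agg$time), ]
  rownames(agg) <- NULL
  class(agg) <- c("stability_summary", "data.frame")
  agg
}

#' @export
plot.stability_summary <- function(x, y, ...) {
  conds <- unique(x$condition)
  cols <- grDevices::hcl.colors(max(3, length(conds)), "Dark 3")
  graphics::plot(NA, xlim = range(x$time), ylim = range(0, 110, x$mean_rate),
                 xlab = "time (days)", ylab = "residual rate (%)", ...)
  for (i in seq_along(conds)) {
    d <- x[x$condition == conds[i], ]
    graphics::lines(d$time, d$mean_rate, col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("bottomleft", legend = conds, col = cols[seq_along(conds)],
                   lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}
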