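#' Fit a calibration line to a standard series
#'
#' Ordinary least-squares fit of instrument response on spiked standard
#' concentration, the linearity check of an analytical method validation.
#'
#' @param series A data frame with numeric columns `concentration`
#'   (ng/mL, spiked levels) and `response` (instrument signal).
#' @return A one-row tibble with `slope`, `intercept`, `r_squared` and
#'   `n_points`.
#' @export
#' @examples
#' fit_calibration(data.frame(concentration = 0:4, response = 2 * (0:4) + 1))
fit_calibration <- function(series) {
  if (!all(c("concentration", "response") %in% names(series))) {
    abort("`series` needs columns `concentration` and `response`.")
  }
  x <- series$concentration
  y <- series$response
  if (length(x) < 3) abort("Calibration needs at least 3 points.")
  if (sd(x) == 0) abort("Degenerate calibration series: all concentrations equal.")
  fit <- lm(y ~ x)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = cor(x, y)^2,
    n_points = length(x)
  )
}

#' Blank-based limits of detection and quantification
#'
#' The average-blank convention: `LOD = mean(blanks) + 3 * sd(blanks)` and
#' `LOQ = mean(blanks) + 10 * sd(blanks)`, with the sample (n-1) SD.
#'
#' @param blanks Numeric vector (>= 3) of blank measurements in
#'   concentration units.
#' @return A one-row tibble with `lod`, `loq`, `blank_mean`, `blank_sd`.
#' @export
#' @examples
#' compute_lod_loq(c(0, 0.01, 0.02))
compute_lod_loq <- function(blanks) {
  if (length(blanks) < 3) abort("At least 3 blank measurements are required.")
  m <- mean(blanks)
  s <- sd(blanks)
  tibble::tibble(lod = m + 3 * s, loq = m + 10 * s, blank_mean = m, blank_sd = s)
}

#' Spike recovery
#'
#' @param measured Determined concentration (ng/mL).
#' @param spiked Added concentration (ng/mL, > 0).
#' @return Recovery in percent: `100 * measured / spiked`. Vectorised.
#' @export
#' @examples
#' compute_recovery(8.21, 8)
compute_recovery <- function(measured, spiked) {
  if (any(spiked <= 0)) abort("`spiked` must be > 0.")
  100 * measured / spiked
}

#' Relative standard deviation (coefficient of variation)
#'
#' @param replicates Numeric vector (>= 2) of replicate measurements with
#'   nonzero mean.
#' @return RSD in percent: `100 * sd / mean` (sample SD).
#' @export
#' @examples
#' compute_rsd(c(9, 10, 11))
compute_rsd <- function(replicates) {
  if (length(replicates) < 2) abort("At least 2 replicates are required.")
  m <- mean(replicates)
  if (m == 0) abort("RSD is undefined for zero-mean replicates.")
  100 * sd(replicates) / m
}

#' Substitute left-censored values
#'
#' Replaces values flagged as below the limit of detection by a
#' substitution rule (default LOD/2, the common convention for
#' left-censored residue data). Values between LOD and LOQ are retained
#' but reported in the `below_loq` flag. The replacement never exceeds the
#' LOD and the operation is idempotent.
#'
#' @param values Numeric concentrations (NA allowed for censored cells).
#' @param censored Logical vector, `TRUE` where the value is below LOD.
#' @param lod,loq Detection and quantification limits (`lod <= loq`).
#' @param rule One of `"half_lod"`, `"lod"`, `"zero"`.
#' @return A tibble with columns `value` (substituted), `censored` and
#'   `below_loq`.
#' @export
#' @examples
#' substitute_censored(c(NA, 0.2), c(TRUE, FALSE), lod = 0.08, loq = 0.25)
substitute_censored <- function(values, censored = rep(FALSE, length(values)),
                                lod, loq = lod,
                                rule = c("half_lod", "lod", "zero")) {
  rule <- match.arg(rule)
  if (lod > loq) abort("`lod` must be <= `loq`.")
  stopifnot(length(censored) == length(values))
  replacement <- switch(rule, half_lod = lod / 2, lod = lod, zero = 0)
  out <- values
  out[censored] <- replacement
  tibble::tibble(
    value = out,
    censored = censored,
    below_loq = !censored & !is.na(out) & out >= lod & out < loq
  )
}

#' Assemble a method-validation QC report
#'
#' Bundles the calibration fit, blank-based LOD/LOQ, recovery and RSD for
#' one analyte into a single row, mirroring the columns of a published
#' method-validation table.
#'
#' @param congener Analyte label.
#' @param series Calibration series for [fit_calibration()].
#' @param blanks Blank measurements for [compute_lod_loq()].
#' @param measured,spiked Spike-recovery pair for [compute_recovery()].
#' @param replicates Replicates for [compute_rsd()].
#' @return One-row tibble: `congener`, `slope`, `intercept`, `r_squared`,
#'   `lod`, `loq`, `recovery_pct`, `rsd_pct`.
#' @export
qc_report <- function(congener, series, blanks, measured, spiked, replicates) {
  cal <- fit_calibration(series)
  lim <- compute_lod_loq(blanks)
  tibble::tibble(
    congener = congener,
    slope = cal$slope, intercept = cal$intercept, r_squared = cal$r_squared,
    lod = lim$lod, loq = lim$loq,
    recovery_pct = compute_recovery(measured, spiked),
    rsd_pct = compute_rsd(replicates)
  )
}
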