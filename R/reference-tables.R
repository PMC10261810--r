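#' The six indicator non-dioxin-like PCB congeners
#'
#' Character vector of the six NDL-PCB indicator congeners used for residue
#' monitoring in food, in ascending IUPAC number: PCB 28, 52, 101, 138, 153,
#' 180. All concentration tables in this package carry one column per
#' congener, in this order.
#'
#' @format Character vector of length 6.
#' @export
ndl_congeners <- c("PCB28", "PCB52", "PCB101", "PCB138", "PCB153", "PCB180")

#' Products and brands covered by the reference survey
#'
#' @format Character vectors.
#' @name survey-levels
#' @export
dairy_products <- c("yogurt", "doogh", "kashk")

#' @rdname survey-levels
#' @export
dairy_brands <- c("A", "B", "C", "D", "E")

#' Regulatory and toxicological thresholds
#'
#' Returns the threshold constants used throughout the risk assessment:
#' the EU maximum level for the sum of the six indicator NDL-PCBs in
#' milk fat (40 ng/g fat), the WHO tolerable daily intake for NDL-PCBs
#' (10 ng/kg bw/day), the conventional acceptable incremental lifetime
#' cancer risk (1e-4), and the US EPA oral slope factor for PCBs
#' (2 (mg/(kg day))^-1).
#'
#' @return Named list with elements `eu_limit` (ng/g fat), `tdi`
#'   (ng/(kg day)), `ilcr_limit` (dimensionless) and `slope_factor`
#'   ((mg/(kg day))^-1).
#' @export
#' @examples
#' pcb_thresholds()$eu_limit
pcb_thresholds <- function() {
  list(eu_limit = 40, tdi = 10, ilcr_limit = 1e-4, slope_factor = 2)
}

#' Published per-congener summary statistics for Iranian dairy products
#'
#' Min/max/mean/SD of the six NDL-PCB congeners (ng/g fat) measured in a
#' market survey of yogurt, doogh and kashk from Tehran (40 samples per
#' product across five brands). These printed summaries are the calibration
#' targets for [generate_samples()]: the survey's raw per-sample data are
#' not public, so synthetic data matched to these moments stand in for them.
#'
#' `level = "overall"` pools all 120 samples, `"product"` splits by product
#' type, `"brand"` by brand (A-E). Rows with `congener == "total"` are the
#' printed per-group summaries of the per-sample six-congener sums.
#'
#' @param level One of `"overall"`, `"product"`, `"brand"`.
#' @return A tibble with columns `group`, `congener`, `min`, `max`, `mean`,
#'   `sd`, all concentrations in ng/g fat.
#' @export
#' @examples
#' pcb_reference_concentrations("product")
pcb_reference_concentrations <- function(level = c("overall", "product", "brand")) {
  level <- match.arg(level)
  switch(level,
    overall = ref_overall(),
    product = ref_product(),
    brand = ref_brand()
  )
}

ref_row <- function(group, congener, min, max, mean, sd) {
  tibble::tibble(group = group, congener = congener,
                 min = min, max = max, mean = mean, sd = sd)
}

ref_overall <- function() {
  ref_row(
    "overall",
    c(ndl_congeners, "total"),
    min  = c(0.04, 0.04, 0.06, 0.24, 2.65, 6.28, 9.62),
    max  = c(0.26, 0.90, 0.18, 0.76, 6.75, 13.42, 21.71),
    mean = c(0.09, 0.19, 0.10, 0.48, 4.33, 9.98, 15.17),
    sd   = c(0.06, 0.21, 0.05, 0.15, 1.23, 2.04, 3.44)
  )
}

ref_product <- function() {
  dplyr::bind_rows(
    ref_row("yogurt", c(ndl_congeners, "total"),
            min  = c(0.04, 0.04, 0.06, 0.41, 3.24, 8.64, 12.59),
            max  = c(0.15, 0.24, 0.13, 0.61, 5.88, 10.88, 17.89),
            mean = c(0.09, 0.14, 0.09, 0.50, 4.26, 9.58, 14.65),
            sd   = c(0.05, 0.07, 0.04, 0.08, 0.99, 0.93, 2.02)),
    ref_row("doogh", c(ndl_congeners, "total"),
            min  = c(0.04, 0.04, 0.06, 0.24, 2.65, 6.28, 9.62),
            max  = c(0.11, 0.90, 0.14, 0.45, 4.07, 9.74, 15.09),
            mean = c(0.06, 0.25, 0.08, 0.34, 3.33, 8.14, 12.21),
            sd   = c(0.03, 0.37, 0.04, 0.09, 0.62, 1.36, 2.22)),
    ref_row("kashk", c(ndl_congeners, "total"),
            min  = c(0.04, 0.09, 0.06, 0.41, 4.21, 10.82, 15.87),
            max  = c(0.26, 0.34, 0.18, 0.76, 6.75, 13.42, 21.71),
            mean = c(0.13, 0.17, 0.12, 0.61, 5.41, 12.21, 18.66),
            sd   = c(0.08, 0.10, 0.06, 0.14, 1.09, 1.10, 2.42))
  )
}

ref_brand <- function() {
  dplyr::bind_rows(
    ref_row("A", c(ndl_congeners, "total"),
            min  = c(0.11, 0.24, 0.13, 0.45, 3.75, 9.74, 15.09),
            max  = c(0.26, 0.90, 0.18, 0.76, 6.75, 13.42, 21.71),
            mean = c(0.17, 0.49, 0.15, 0.61, 5.46, 11.35, 18.23),
            sd   = c(0.08, 0.36, 0.03, 0.16, 1.54, 1.88, 3.32)),
    ref_row("B", c(ndl_congeners, "total"),
            min  = c(0.04, 0.12, 0.06, 0.34, 3.44, 8.83, 12.83),
            max  = c(0.04, 0.17, 0.14, 0.64, 5.66, 12.51, 19.16),
            mean = c(0.04, 0.15, 0.11, 0.49, 4.48, 10.36, 15.63),
            sd   = c(0.00, 0.03, 0.04, 0.15, 1.12, 1.92, 3.23)),
    ref_row("C", c(ndl_congeners, "total"),
            min  = c(0.04, 0.04, 0.06, 0.41, 4.05, 8.54, 13.16),
            max  = c(0.09, 0.09, 0.06, 0.70, 6.06, 12.97, 19.97),
            mean = c(0.07, 0.06, 0.06, 0.55, 4.73, 10.05, 15.52),
            sd   = c(0.03, 0.03, 0.00, 0.15, 1.15, 2.53, 3.86)),
    ref_row("D", c(ndl_congeners, "total"),
            min  = c(0.09, 0.13, 0.06, 0.27, 2.76, 6.28, 9.62),
            max  = c(0.12, 0.16, 0.06, 0.52, 4.39, 11.35, 16.58),
            mean = c(0.11, 0.14, 0.06, 0.42, 3.64, 9.18, 13.55),
            sd   = c(0.02, 0.02, 0.00, 0.13, 0.82, 2.61, 3.56)),
    ref_row("E", c(ndl_congeners, "total"),
            min  = c(0.04, 0.04, 0.06, 0.24, 2.65, 7.31, 10.34),
            max  = c(0.15, 0.11, 0.17, 0.41, 4.21, 10.82, 15.87),
            mean = c(0.08, 0.09, 0.10, 0.35, 3.37, 8.95, 12.93),
            sd   = c(0.06, 0.04, 0.06, 0.10, 0.79, 1.77, 2.78))
  )
}

#' Published analytical QC characteristics of the GC-MS/MS method
#'
#' Per-congener method-validation metrics from the reference survey:
#' calibration linear range (ng/mL), LOD and LOQ (ng/g fat), relative
#' standard deviation (%), recovery (%), and intra-/inter-day
#' repeatability RSDs (%). Used as the default LODs for censoring
#' substitution and as sanity anchors for the QC arithmetic.
#'
#' @return A tibble, one row per congener.
#' @export
pcb_reference_qc <- function() {
  tibble::tibble(
    congener = ndl_congeners,
    linear_min = 0.10, linear_max = 40,
    lod = c(0.080, 0.080, 0.120, 0.060, 0.100, 0.080),
    loq = c(0.250, 0.250, 0.360, 0.180, 0.310, 0.250),
    rsd_pct = c(6.33, 8.86, 7.54, 7.49, 8.55, 8.29),
    recovery_pct = c(100.21, 102.63, 98.49, 97.45, 101.38, 98.97),
    intra_day = c(7.55, 10.34, 11.44, 9.58, 10.81, 11.83),
    inter_day = c(10.58, 14.92, 13.81, 14.98, 15.22, 15.94)
  )
}

#' Published Monte Carlo EDI percentile table
#'
#' The reference survey's simulated estimated-daily-intake percentiles
#' (5/50/75/95%) per congener and for the six-congener total, by product,
#' in ng/(kg day). The exposure-parameter values behind these numbers were
#' not published; [calibrate_exposure()] back-solves a per-product scalar
#' exposure multiplier from the total medians so that reproduction runs can
#' reach this table's scale.
#'
#' @return A tibble with columns `product`, `percentile` (5, 50, 75, 95),
#'   one column per congener, and `total`.
#' @export
pcb_reference_edi <- function() {
  tb <- tibble::tribble(
    ~product, ~percentile, ~PCB28, ~PCB52, ~PCB101, ~PCB138, ~PCB153, ~PCB180, ~total,
    "yogurt",  5, 5.96e-2, 9.15e-2, 6.01e-2, 3.30e-1, 2.78e0, 6.18e0, 9.72e0,
    "yogurt", 50, 8.91e-2, 1.37e-1, 8.74e-2, 4.95e-1, 4.16e0, 9.26e0, 1.43e1,
    "yogurt", 75, 1.06e-1, 1.62e-1, 1.03e-1, 5.79e-1, 4.87e0, 1.09e1, 1.68e1,
    "yogurt", 95, 1.32e-1, 2.09e-1, 1.27e-1, 7.28e-1, 6.19e0, 1.45e1, 2.12e1,
    "doogh",   5, 3.32e-3, 1.38e-2, 4.31e-3, 1.88e-2, 1.78e-1, 4.43e-1, 6.54e-1,
    "doogh",  50, 4.89e-3, 2.06e-2, 6.42e-3, 2.76e-2, 2.68e-1, 6.68e-1, 1.01e0,
    "doogh",  75, 5.79e-3, 2.40e-2, 7.63e-3, 3.32e-2, 3.17e-1, 7.79e-1, 1.19e0,
    "doogh",  95, 7.40e-3, 3.08e-2, 9.57e-3, 4.11e-2, 4.05e-1, 9.65e-1, 1.49e0,
    "kashk",   5, 2.36e-3, 3.00e-3, 2.16e-3, 1.11e-2, 9.60e-2, 2.21e-1, 3.40e-1,
    "kashk",  50, 3.52e-3, 4.54e-3, 3.25e-3, 1.70e-2, 1.47e-1, 3.34e-1, 5.09e-1,
    "kashk",  75, 4.19e-3, 5.35e-3, 3.85e-3, 1.99e-2, 1.72e-1, 3.94e-1, 6.05e-1,
    "kashk",  95, 5.33e-3, 6.88e-3, 4.83e-3, 2.57e-2, 2.20e-1, 5.02e-1, 7.66e-1
  )
  tb
}

# Internal: reference spec rows (congeners only, no totals) for a level.
ref_specs <- function(level) {
  dplyr::filter(pcb_reference_concentrations(level), .data$congener != "total")
}
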