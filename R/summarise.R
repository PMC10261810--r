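#' Per-sample sum of the six indicator congeners
#'
#' Adds a `total_ndl` column (ng/g fat) holding each sample's sum of the
#' six NDL-PCB congener concentrations.
#'
#' @param data A sample tibble with one numeric column per congener (see
#'   [generate_samples()] / [read_samples()]).
#' @return `data` with a `total_ndl` column appended.
#' @export
#' @examples
#' samples <- generate_samples(pcb_reference_concentrations("product"),
#'                             n_samples = 3, seed = 1)
#' total_ndl(samples)$total_ndl
total_ndl <- function(data) {
  check_congener_columns(data)
  conc <- as.matrix(data[, ndl_congeners])
  if (any(!is.finite(conc))) {
    abort("Congener concentrations contain missing values; substitute censored values first.")
  }
  dplyr::mutate(data, total_ndl = rowSums(conc))
}

check_congener_columns <- function(data) {
  missing <- setdiff(ndl_congeners, names(data))
  if (length(missing)) {
    abort(paste0("Missing congener column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Group summaries of congener concentrations
#'
#' Min/max/mean/SD (sample SD, n-1) of each congener and of the per-sample
#' six-congener total, pooled (`"overall"`) or split by `"product"` or
#' `"brand"`. This is the survey-table view of a sample set.
#'
#' @inheritParams total_ndl
#' @param level Grouping level: `"overall"`, `"product"` or `"brand"`.
#' @return A tibble with columns `group`, `congener` (the six congeners
#'   plus `"total"`), `min`, `max`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' samples <- generate_samples(pcb_reference_concentrations("product"),
#'                             n_samples = 10, seed = 1)
#' summarise_congeners(samples, "product")
summarise_congeners <- function(data, level = c("overall", "product", "brand")) {
  level <- match.arg(level)
  data <- total_ndl(data)
  key <- switch(level, overall = NULL, product = "product", brand = "brand")
  if (!is.null(key)) {
    keep <- !is.na(data[[key]])
    if (!all(keep)) {
      warn(paste0("Dropping ", sum(!keep), " record(s) with missing ", key, "."))
      data <- data[keep, ]
    }
  }
  long <- tidyr::pivot_longer(
    data,
    cols = dplyr::all_of(c(ndl_congeners, "total_ndl")),
    names_to = "congener", values_to = "conc"
  )
  long$congener <- ifelse(long$congener == "total_ndl", "total", long$congener)
  grouped <- if (is.null(key)) {
    dplyr::mutate(long, group = "overall")
  } else {
    dplyr::mutate(long, group = .data[[key]])
  }
  out <- grouped |>
    dplyr::group_by(.data$group, .data$congener) |>
    dplyr::summarise(
      min = min(.data$conc), max = max(.data$conc),
      mean = mean(.data$conc), sd = sd(.data$conc),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$group,
                   match(.data$congener, c(ndl_congeners, "total")))
  small <- dplyr::filter(out, .data$n < 2)
  if (nrow(small) > 0) {
    warn("Some groups have fewer than 2 records; their SDs are undefined.")
  }
  out
}

#' Check a group summary against the EU maximum level
#'
#' Compliance is the strict inequality `total mean < limit`; the margin is
#' `limit - total mean` (negative when exceeded). The EU maximum level for
#' the sum of the six indicator NDL-PCBs in milk fat is 40 ng/g fat.
#'
#' @param summary A tibble from [summarise_congeners()] (or any tibble with
#'   `group`, `congener`, `mean` columns including `congener == "total"`).
#' @param limit Regulatory limit in ng/g fat.
#' @return A tibble with `group`, `total_mean`, `limit`, `compliant`,
#'   `margin`.
#' @export
#' @examples
#' samples <- generate_samples(pcb_reference_concentrations("product"),
#'                             n_samples = 10, seed = 1)
#' check_regulatory_limit(summarise_congeners(samples, "product"))
check_regulatory_limit <- function(summary, limit = pcb_thresholds()$eu_limit) {
  totals <- dplyr::filter(summary, .data$congener == "total")
  if (nrow(totals) == 0) abort("`summary` has no `total` rows.")
  totals |>
    dplyr::transmute(
      group = .data$group,
      total_mean = .data$mean,
      limit = limit,
      compliant = .data$mean < limit,
      margin = limit - .data$mean
    )
}
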