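#' Read a sample concentration CSV
#'
#' Reads the standard sample table: header
#' `sample_id,product,brand,PCB28,PCB52,PCB101,PCB138,PCB153,PCB180`,
#' one row per sample, concentrations in ng/g fat with `.` decimal
#' separator. Cells containing `<LOD` mark left-censored values: they are
#' read as `NA` and flagged in the matching `censored_<congener>` column
#' (substitute them with [substitute_censored_samples()] before computing
#' statistics).
#'
#' @param path CSV file path.
#' @return A tibble with `sample_id`, `product`, `brand`, six numeric
#'   congener columns, and six logical `censored_*` columns.
#' @export
read_samples <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("sample_id", "product", "brand", ndl_congeners)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(paste0("Sample file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_product <- !is.na(raw$product) & !raw$product %in% dairy_products
  if (any(bad_product)) {
    abort(paste0("Unknown product in row(s) ",
                 paste(which(bad_product), collapse = ", "),
                 " (expected ", paste(dairy_products, collapse = "/"), ")."))
  }
  bad_brand <- !is.na(raw$brand) & raw$brand != "" & !raw$brand %in% dairy_brands
  if (any(bad_brand)) {
    abort(paste0("Unknown brand in row(s) ", paste(which(bad_brand), collapse = ", "), "."))
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    product = raw$product,
    brand = dplyr::if_else(is.na(raw$brand) | raw$brand == "", NA_character_, raw$brand)
  )
  for (cg in ndl_congeners) {
    cell <- raw[[cg]]
    censored <- !is.na(cell) & grepl("^\\s*<\\s*LOD\\s*$", cell, ignore.case = TRUE)
    value <- suppressWarnings(as.numeric(cell))
    bad <- !censored & (is.na(value) | value < 0)
    if (any(bad)) {
      abort(paste0("Invalid concentration in column ", cg, ", row(s) ",
                   paste(which(bad), collapse = ", "),
                   ": values must be numeric and >= 0 (or `<LOD`)."))
    }
    value[censored] <- NA_real_
    out[[cg]] <- value
    out[[paste0("censored_", cg)]] <- censored
  }
  out
}

#' Write a sample concentration CSV
#'
#' Inverse of [read_samples()]: censored cells are written back as
#' `<LOD`. Round-trips content-identically for conforming files.
#'
#' @inheritParams total_ndl
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path) {
  check_congener_columns(data)
  out <- tibble::tibble(
    sample_id = data$sample_id,
    product = data$product,
    brand = data$brand
  )
  for (cg in ndl_congeners) {
    cens_col <- paste0("censored_", cg)
    cens <- if (cens_col %in% names(data)) data[[cens_col]] else rep(FALSE, nrow(data))
    cell <- format_number(data[[cg]])
    cell[cens] <- "<LOD"
    out[[cg]] <- cell
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Plain decimal formatting at full double precision, no scientific notation.
format_number <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (grepl("\\.", s)) s <- sub("\\.$", "", sub("0+$", "", s))
    s
  }, character(1))
  out
}

#' Substitute censored cells across a sample table
#'
#' Applies [substitute_censored()] column-wise using per-congener LODs
#' (defaulting to the published method LODs), replacing every cell flagged
#' in a `censored_*` column.
#'
#' @inheritParams total_ndl
#' @param qc A tibble with `congener`, `lod`, `loq` columns; defaults to
#'   [pcb_reference_qc()].
#' @param rule Substitution rule, see [substitute_censored()].
#' @return `data` with censored cells replaced (flags retained).
#' @export
substitute_censored_samples <- function(data, qc = pcb_reference_qc(),
                                        rule = "half_lod") {
  check_congener_columns(data)
  for (cg in ndl_congeners) {
    cens_col <- paste0("censored_", cg)
    if (!cens_col %in% names(data)) next
    row <- qc[qc$congener == cg, ]
    sub <- substitute_censored(data[[cg]], data[[cens_col]],
                               lod = row$lod, loq = row$loq, rule = rule)
    data[[cg]] <- sub$value
  }
  data
}

#' Read / write an exposure configuration as YAML
#'
#' The YAML mirrors [exposure_config()]: either a `multiplier` block or
#' the six full-form parameter blocks, each with a `family` field
#' (`point`, `uniform`, `normal`, `lognormal`) and that family's
#' parameters, plus an optional top-level `sf`.
#'
#' @param path YAML file path.
#' @return [read_exposure_config()] returns an [exposure_config()];
#'   [write_exposure_config()] returns `path` invisibly.
#' @export
read_exposure_config <- function(path) {
  spec <- yaml::read_yaml(path)
  parse_block <- function(b, what) {
    if (is.numeric(b) && length(b) == 1) return(dist_point(b))
    if (is.null(b$family)) abort(paste0("Config block `", what, "` needs a `family`."))
    switch(b$family,
      point = dist_point(b$value),
      uniform = dist_uniform(b$min, b$max),
      normal = dist_normal(b$mean, b$sd),
      lognormal = dist_lognormal(b$mean, b$sd),
      abort(paste0("Unknown distribution family `", b$family, "` in `", what, "`."))
    )
  }
  sf <- if (!is.null(spec$sf)) spec$sf else pcb_thresholds()$slope_factor
  if (!is.null(spec$multiplier)) {
    exposure_config(multiplier = parse_block(spec$multiplier, "multiplier"), sf = sf)
  } else {
    args <- purrr::imap(spec[c("ir", "ef", "ed", "at", "bw", "fat_fraction")],
                        parse_block)
    do.call(exposure_config, c(args, list(sf = sf)))
  }
}

#' @rdname read_exposure_config
#' @param config An [exposure_config()].
#' @export
write_exposure_config <- function(config, path) {
  stopifnot(inherits(config, "exposure_config"))
  blocks <- purrr::map(config$params, function(sp) c(list(family = sp$family), sp$params))
  yaml::write_yaml(c(blocks, list(sf = config$sf)), path)
  invisible(path)
}
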