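#' Generate synthetic per-sample congener concentration tables
#'
#' Draws per-sample concentrations of the six NDL-PCB congeners from
#' independent truncated lognormals calibrated to printed group summary
#' statistics (min/max/mean/SD per congener), emulating a market survey
#' whose raw data were never published. Values are drawn by rejection until
#' inside `[min, max]`, so no sample ever leaves the printed range and
#' support is strictly positive.
#'
#' With `calibrate = "truncated"` (default) the log-scale parameters are
#' solved so the *truncated* distribution has the target mean exactly and
#' the closest attainable SD ([fit_truncated_lognormal()]). With
#' `calibrate = "plain"` the untruncated lognormal is moment-matched
#' ([fit_lognormal_moments()]) and then clipped by rejection; this is
#' simpler but biases the realised mean whenever the window is asymmetric
#' around it.
#'
#' Each (group, congener) pair draws from its own deterministic RNG stream
#' derived from `seed`, so adding or removing a congener or group does not
#' perturb the other columns' draws.
#'
#' @param specs A tibble of moment specs with columns `congener`, `min`,
#'   `max`, `mean`, `sd` and a grouping column `group` (product type or
#'   brand), e.g. from [pcb_reference_concentrations()]. Rows with
#'   `congener == "total"` are ignored. `sd = 0` or `min == max` rows give
#'   constant columns.
#' @param n_samples Samples per group (if `specs` has one spec per
#'   product) or per brand within product. Default 40, the survey design.
#' @param seed Integer root seed; identical `(specs, n_samples, seed)`
#'   give bit-identical tables.
#' @param calibrate `"truncated"` (default) or `"plain"`; see Details.
#' @param product If the `group` column holds brands, the product type to
#'   stamp on the records (brands partition a product's samples equally).
#' @return A tibble with columns `sample_id`, `product`, `brand`, and one
#'   numeric column per congener (ng/g fat).
#' @export
#' @examples
#' specs <- pcb_reference_concentrations("product")
#' head(generate_samples(specs, n_samples = 5, seed = 1))
generate_samples <- function(specs, n_samples = 40, seed = 1,
                             calibrate = c("truncated", "plain"),
                             product = NA_character_) {
  calibrate <- match.arg(calibrate)
  specs <- dplyr::filter(specs, .data$congener != "total")
  validate_specs(specs)
  groups <- unique(specs$group)
  is_brand_level <- all(groups %in% dairy_brands)
  purrr::map_dfr(groups, function(g) {
    gspec <- dplyr::filter(specs, .data$group == g)
    cols <- purrr::map(ndl_congeners, function(cg) {
      row <- dplyr::filter(gspec, .data$congener == cg)
      if (nrow(row) != 1) abort(paste0("Spec for group ", g, " is missing ", cg, "."))
      pars <- if (calibrate == "truncated") {
        fit_truncated_lognormal(row$mean, row$sd, row$min, row$max)
      } else {
        fit_lognormal_moments(row$mean, row$sd)
      }
      with_stream_seed(seed, paste("conc", g, cg, sep = "/"),
                       rlnorm_truncated(n_samples, pars$mu, pars$sigma,
                                        row$min, row$max))
    })
    names(cols) <- ndl_congeners
    tibble::tibble(
      sample_id = paste0(g, "_", sprintf("%03d", seq_len(n_samples))),
      product = if (is_brand_level) product else g,
      brand = if (is_brand_level) g else NA_character_,
      !!!cols
    )
  })
}

validate_specs <- function(specs) {
  needed <- c("group", "congener", "min", "max", "mean", "sd")
  missing <- setdiff(needed, names(specs))
  if (length(missing)) {
    abort(paste0("Spec table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(specs$min > specs$max)) abort("Infeasible bounds: min > max in spec table.")
  if (any(specs$mean <= 0)) abort("Spec means must be > 0.")
  if (any(specs$sd < 0)) abort("Spec SDs must be >= 0.")
  invisible(specs)
}

#' Generate joint draws of the exposure parameters
#'
#' Produces `n_iter` joint draws of the exposure-model inputs (intake rate
#' IR, exposure frequency EF, exposure duration ED, averaging time AT, body
#' weight BW, product fat fraction) from an [exposure_config()]. Each
#' parameter draws from its own labelled RNG stream derived from `seed`,
#' and point-mass specs give constant columns. Within an iteration the same
#' consumer's parameters apply to every congener, which is what induces the
#' positive correlation among congener intakes downstream.
#'
#' @param config An [exposure_config()].
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Integer root seed.
#' @return A tibble with `n_iter` rows and columns `ir`, `ef`, `ed`, `at`,
#'   `bw`, `fat_fraction` (or a single `multiplier` column for a
#'   multiplier-form config), all strictly positive.
#' @export
#' @examples
#' cfg <- exposure_config(ir = 100, ef = 365, ed = 70, at = 25550,
#'                        bw = dist_uniform(15, 70), fat_fraction = 0.03)
#' head(generate_exposure_draws(cfg, 5, seed = 1))
generate_exposure_draws <- function(config, n_iter, seed = 1) {
  stopifnot(inherits(config, "exposure_config"))
  params <- config$params
  draws <- purrr::imap(params, function(spec, nm) {
    with_stream_seed(seed, paste0("exposure/", nm),
                     draw_dist(spec, n_iter))
  })
  out <- tibble::as_tibble(draws)
  if (any(vapply(out, function(x) any(x <= 0), logical(1)))) {
    abort("Exposure draws must be strictly positive; check the distribution specs.")
  }
  out
}
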