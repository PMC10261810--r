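#' Normality-gated group comparison tests
#'
#' For each congener (and the per-sample total), tests whether
#' concentrations differ between the levels of a grouping factor, following
#' the usual screening workflow for survey data: a Kolmogorov-Smirnov
#' normality check per group at alpha = 0.05, then a parametric test when
#' every group looks normal (one-way ANOVA for 3+ groups, two-sample t-test
#' for 2) and a rank-based test otherwise (Kruskal-Wallis, or Mann-Whitney
#' for 2 groups). Significance is declared at p < 0.05.
#'
#' The default normality check is the plain KS test against a normal with
#' the group's estimated mean and SD; `lilliefors = TRUE` switches to the
#' Lilliefors-corrected variant (`nortest::lillie.test`), which accounts
#' for the estimated parameters.
#'
#' @inheritParams total_ndl
#' @param by Grouping factor: `"product"` or `"brand"`.
#' @param congeners Which congeners to test; defaults to all six plus the
#'   total.
#' @param alpha Significance level for the normality gate.
#' @param lilliefors Use the Lilliefors-corrected normality test.
#' @return A tibble with one row per congener: `congener`, `test`
#'   (`"anova"`, `"t_test"`, `"kruskal_wallis"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, `all_normal`, `min_normality_p`, `n_groups`,
#'   `significant`.
#' @export
#' @examples
#' samples <- generate_samples(pcb_reference_concentrations("product"),
#'                             n_samples = 20, seed = 1)
#' compare_groups(samples, by = "product")
compare_groups <- function(data, by = c("product", "brand"),
                           congeners = c(ndl_congeners, "total"),
                           alpha = 0.05, lilliefors = FALSE) {
  by <- match.arg(by)
  data <- total_ndl(data)
  data$total <- data$total_ndl
  fac <- data[[by]]
  if (any(is.na(fac))) {
    data <- data[!is.na(fac), ]
    fac <- data[[by]]
  }
  groups <- unique(fac)
  if (length(groups) < 2) abort("Need at least 2 groups to compare.")
  sizes <- table(fac)
  if (any(sizes < 3)) abort("Each group needs at least 3 records.")
  purrr::map_dfr(congeners, function(cg) {
    x <- data[[cg]]
    if (sd(x) == 0) {
      abort(paste0("Concentrations of ", cg,
                   " are constant across all groups; the tests are undefined."))
    }
    norm_p <- vapply(groups, function(g) {
      xi <- x[fac == g]
      if (sd(xi) == 0) return(0) # constant within group: not plausibly normal
      if (lilliefors) {
        nortest::lillie.test(xi)$p.value
      } else {
        suppressWarnings(ks.test(xi, "pnorm", mean(xi), sd(xi))$p.value)
      }
    }, numeric(1))
    all_normal <- all(norm_p >= alpha)
    k <- length(groups)
    res <- if (all_normal && k == 2) {
      tt <- t.test(x[fac == groups[1]], x[fac == groups[2]], var.equal = TRUE)
      list(test = "t_test", statistic = unname(tt$statistic), p = tt$p.value)
    } else if (all_normal) {
      av <- summary(aov(x ~ factor(fac)))[[1]]
      list(test = "anova", statistic = av$`F value`[1], p = av$`Pr(>F)`[1])
    } else if (k == 2) {
      wt <- suppressWarnings(wilcox.test(x[fac == groups[1]], x[fac == groups[2]]))
      list(test = "mann_whitney", statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      kw <- kruskal.test(x, factor(fac))
      list(test = "kruskal_wallis", statistic = unname(kw$statistic), p = kw$p.value)
    }
    tibble::tibble(
      congener = cg, test = res$test, statistic = res$statistic,
      p_value = res$p, all_normal = all_normal,
      min_normality_p = min(norm_p), n_groups = k,
      significant = res$p < 0.05
    )
  })
}
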