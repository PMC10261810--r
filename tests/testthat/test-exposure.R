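test_that("EDI arithmetic matches an independent recomputation", {
  expect_equal(compute_edi(0, 0.03, 100, 365, 70, 70, 25550), 0)
  # cancellation: ef*ed = at and fat*ir/bw = 1 leaves EDI = c
  expect_equal(compute_edi(7.3, 0.5, 2, 365, 10, 1, 3650), 7.3)
  set.seed(2)
  for (i in 1:20) {
    v <- runif(7, 0.1, 100)
    oracle <- prod(v[1:5]) / (v[6] * v[7])
    expect_equal(compute_edi(v[1], v[2], v[3], v[4], v[5], v[6], v[7]),
                 oracle, tolerance = 1e-12)
  }
  expect_error(compute_edi(1, 1, 1, 1, 1, 0, 1), "> 0")
})

test_that("point-mass inputs collapse every percentile to the deterministic EDI", {
  specs <- tibble::tibble(congener = ndl_congeners,
                          mean = c(0.09, 0.19, 0.1, 0.48, 4.33, 9.98), sd = 0)
  mcs <- run_mcs(specs, exposure_config(multiplier = 1), n_iter = 1000, seed = 1)
  tot <- dplyr::filter(tidy(mcs), congener == "total")
  expect_equal(tot$edi, rep(15.17, 4))
  contrib <- congener_contributions(mcs)
  expect_equal(sum(contrib$fraction), 1, tolerance = 1e-9)
  expect_equal(contrib$congener[1], "PCB180")
  expect_equal(contrib$fraction[1], 9.98 / 15.17, tolerance = 1e-9)
})

test_that("simulated percentiles match analytic lognormal quantiles", {
  mu <- log(10); sigma <- 0.4; k <- 0.5; n <- 1e5
  specs <- tibble::tibble(congener = ndl_congeners, mu = mu, sigma = sigma)
  mcs <- run_mcs(specs, exposure_config(multiplier = k), n_iter = n, seed = 33,
                 probs = c(0.05, 0.5, 0.95))
  for (p in c(0.05, 0.5, 0.95)) {
    q_true <- k * qlnorm(p, mu, sigma)
    se <- k * sqrt(p * (1 - p) / n) / dlnorm(qlnorm(p, mu, sigma), mu, sigma)
    got <- dplyr::filter(mcs$percentiles, congener == "PCB28",
                         percentile == 100 * p)$edi
    expect_lt(abs(got - q_true), 3 * se)
  }
})

test_that("total percentiles dominate each congener's at every level", {
  mcs <- run_mcs(dplyr::filter(table5_specs(), group == "yogurt"),
                 exposure_config(multiplier = 0.976), n_iter = 5000, seed = 8)
  pct <- tidy(mcs)
  tot <- dplyr::filter(pct, congener == "total")
  for (cg in ndl_congeners) {
    one <- dplyr::filter(pct, congener == cg)
    expect_true(all(tot$edi >= one$edi))
  }
  expect_true(all(diff(tot$edi) >= 0)) # nondecreasing in the percentile index
})

test_that("scaling laws: doubling SF or concentrations doubles the results", {
  specs <- tibble::tibble(congener = ndl_congeners, mu = log(2), sigma = 0.3)
  m1 <- run_mcs(specs, exposure_config(multiplier = 1), n_iter = 2000, seed = 4)
  r1 <- compute_ilcr(m1, sf = 2)
  r2 <- compute_ilcr(m1, sf = 4)
  expect_equal(r2$draws, 2 * r1$draws, tolerance = 1e-12)
  m2 <- run_mcs(dplyr::mutate(specs, mu = mu + log(2)),
                exposure_config(multiplier = 1), n_iter = 2000, seed = 4)
  expect_equal(tidy(m2)$edi, 2 * tidy(m1)$edi, tolerance = 1e-9)
})

test_that("the percentile table is bit-reproducible under a fixed seed", {
  specs <- dplyr::filter(table5_specs(), group == "doogh")
  cfg <- exposure_config(multiplier = 0.0827)
  m1 <- run_mcs(specs, cfg, n_iter = 2000, seed = 99)
  m2 <- run_mcs(specs, cfg, n_iter = 2000, seed = 99)
  expect_identical(tidy(m1), tidy(m2))
})

test_that("exposure calibration is the published-median ratio", {
  expect_equal(calibrate_exposure(15, 15), 1)
  expect_equal(calibrate_exposure(14.65, 14.3), 0.97610922, tolerance = 1e-7)
  expect_equal(calibrate_exposure(12.21, 1.01), 0.0827191, tolerance = 1e-5)
  expect_error(calibrate_exposure(0, 1), "> 0")
  m <- calibrated_multipliers()
  expect_named(m, c("yogurt", "doogh", "kashk"))
  expect_equal(unname(m["kashk"]), 0.509 / 18.66, tolerance = 1e-9)
})

test_that("single-congener intake owns the whole contribution", {
  specs <- tibble::tibble(congener = ndl_congeners,
                          mean = c(0, 0, 0, 0, 0, 3) + 1e-12, sd = 0)
  specs$mean[6] <- 3
  mcs <- run_mcs(specs, exposure_config(multiplier = 1), n_iter = 1000, seed = 1)
  contrib <- congener_contributions(mcs)
  expect_equal(contrib$fraction[contrib$congener == "PCB180"], 1, tolerance = 1e-9)
  even <- run_mcs(tibble::tibble(congener = ndl_congeners, mean = 2, sd = 0),
                  exposure_config(multiplier = 1), n_iter = 1000, seed = 1)
  expect_equal(congener_contributions(even)$fraction, rep(1 / 6, 6),
               tolerance = 1e-12)
})

test_that("ILCR applies the ng-to-mg conversion and the 1e-4 threshold", {
  zero <- compute_ilcr(0, sf = 2)
  expect_equal(zero$summary_value, 0)
  expect_equal(zero$classification, "acceptable")
  med <- compute_ilcr(14.3, sf = 2)
  expect_equal(med$summary_value, 2.86e-5, tolerance = 1e-9)
  expect_equal(med$classification, "acceptable")
  huge <- compute_ilcr(1e5, sf = 2)
  expect_equal(huge$summary_value, 0.2)
  expect_equal(huge$classification, "unacceptable")
  expect_error(compute_ilcr(-1), ">= 0")
  expect_error(compute_ilcr(1, sf = 0), "> 0")
})

test_that("TDI comparison is strict", {
  res <- compare_tdi(c(0.509, 10, 14.3))
  expect_equal(res$below_tdi, c(TRUE, FALSE, FALSE))
})
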