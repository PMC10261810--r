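test_that("calibration fit recovers exact lines and matches the normal equations", {
  exact <- fit_calibration(data.frame(concentration = 0:4, response = 2 * (0:4) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  series <- data.frame(concentration = c(0, 1, 2), response = c(0, 1, 3))
  fit <- fit_calibration(series)
  oracle <- ols_oracle(series$concentration, series$response)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:5) {
    x <- sort(runif(7, 0.1, 40))
    y <- 3 * x + rnorm(7)
    fit <- fit_calibration(data.frame(concentration = x, response = y))
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }
})

test_that("degenerate calibration series are rejected", {
  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 1),
                                          response = 1:3)), "Degenerate")
  expect_error(fit_calibration(data.frame(concentration = 1:2, response = 1:2)),
               "3 points")
})

test_that("blank-based LOD/LOQ follows the mean + k*sd convention", {
  flat <- compute_lod_loq(c(0.05, 0.05, 0.05))
  expect_equal(flat$lod, 0.05)
  expect_equal(flat$loq, 0.05)

  b <- c(0, 0.01, 0.02)
  lim <- compute_lod_loq(b)
  expect_equal(lim$lod, mean(b) + 3 * sd(b))
  expect_equal(lim$loq, mean(b) + 10 * sd(b))
  expect_gt(lim$loq, lim$lod) # 10 > 3 whenever sd > 0
  expect_error(compute_lod_loq(c(0.1, 0.2)), "3 blank")
})

test_that("recovery is a simple ratio and homogeneous of degree zero", {
  expect_equal(compute_recovery(8, 8), 100)
  expect_equal(compute_recovery(8.21, 8), 102.625)
  expect_equal(compute_recovery(4, 8), 50)
  expect_equal(compute_recovery(3 * 8.21, 3 * 8), compute_recovery(8.21, 8))
  expect_error(compute_recovery(1, 0), "spiked")
})

test_that("RSD is the sample CV and scale-invariant", {
  expect_equal(compute_rsd(c(5, 5, 5)), 0)
  expect_equal(compute_rsd(c(9, 10, 11)), 10)
  set.seed(8)
  x <- runif(10, 1, 2)
  expect_equal(compute_rsd(7 * x), compute_rsd(x), tolerance = 1e-12)
  expect_error(compute_rsd(c(-1, 1)), "zero-mean")
  expect_error(compute_rsd(5), "2 replicates")
})

test_that("censoring substitution follows the rule, caps at LOD and is idempotent", {
  sub <- substitute_censored(c(NA, 0.2, 0.1), c(TRUE, FALSE, FALSE),
                             lod = 0.08, loq = 0.25)
  expect_equal(sub$value, c(0.04, 0.2, 0.1))
  expect_true(sub$below_loq[2])  # in [lod, loq)
  expect_false(sub$below_loq[1])

  zero <- substitute_censored(c(NA), TRUE, lod = 0.08, loq = 0.25, rule = "zero")
  expect_equal(zero$value, 0)
  at_lod <- substitute_censored(c(NA), TRUE, lod = 0.08, loq = 0.25, rule = "lod")
  expect_equal(at_lod$value, 0.08)
  expect_true(all(at_lod$value <= 0.08))

  # identity without flags, idempotence with them
  x <- c(0.5, 1.2)
  expect_equal(substitute_censored(x, c(FALSE, FALSE), lod = 0.1)$value, x)
  once <- substitute_censored(c(NA, 0.5), c(TRUE, FALSE), lod = 0.1, loq = 0.3)
  twice <- substitute_censored(once$value, once$censored, lod = 0.1, loq = 0.3)
  expect_equal(twice$value, once$value)
  expect_error(substitute_censored(1, FALSE, lod = 0.5, loq = 0.1), "lod")
})

test_that("qc_report assembles all metrics for one analyte", {
  rep <- qc_report("PCB28",
                   series = data.frame(concentration = c(0.1, 8, 12, 20, 40),
                                       response = c(0.1, 8, 12, 20, 40) * 1.9 + 0.2),
                   blanks = c(0.01, 0.02, 0.03),
                   measured = 8.02, spiked = 8,
                   replicates = c(7.9, 8.0, 8.1))
  expect_equal(rep$slope, 1.9, tolerance = 1e-9)
  expect_true(rep$loq >= rep$lod && rep$lod >= 0)
  expect_gt(rep$recovery_pct, 0)
  expect_lt(rep$rsd_pct, 15.94) # the method's repeatability gate
})
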