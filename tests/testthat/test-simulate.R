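test_that("zero-variance specs give constant samples at the means", {
  specs <- table5_specs() |>
    dplyr::filter(group == "yogurt") |>
    dplyr::mutate(sd = 0, min = mean / 2, max = mean * 2)
  s <- generate_samples(specs, n_samples = 5, seed = 3)
  for (cg in ndl_congeners) {
    expect_equal(s[[cg]], rep(specs$mean[specs$congener == cg], 5))
  }
})

test_that("all draws fall inside the published range (kashk spec)", {
  specs <- table5_specs() |> dplyr::filter(group == "kashk")
  s <- generate_samples(specs, n_samples = 40, seed = 17)
  expect_equal(nrow(s), 40)
  row <- specs[specs$congener == "PCB180", ]
  expect_true(all(s$PCB180 >= row$min & s$PCB180 <= row$max))
  for (cg in ndl_congeners) {
    r <- specs[specs$congener == cg, ]
    expect_true(all(s[[cg]] >= r$min & s[[cg]] <= r$max))
  }
})

test_that("empirical mean converges to the spec mean", {
  specs <- tibble::tibble(group = "yogurt", congener = ndl_congeners,
                          min = 0, max = Inf, mean = 5, sd = 1)
  s <- generate_samples(specs, n_samples = 1e5, seed = 2)
  expect_lt(abs(mean(s$PCB28) - 5), 3 * 1 / sqrt(1e5))
})

test_that("generation is seed-deterministic and stream-stable across row order", {
  specs <- table5_specs()
  s1 <- generate_samples(specs, n_samples = 10, seed = 5)
  s2 <- generate_samples(specs, n_samples = 10, seed = 5)
  expect_identical(s1, s2)
  s3 <- generate_samples(specs, n_samples = 10, seed = 6)
  expect_false(identical(s1, s3))
  # shuffling spec rows must not perturb any congener's stream
  shuffled <- specs[sample(nrow(specs)), ]
  s4 <- generate_samples(shuffled, n_samples = 10, seed = 5)
  expect_equal(s1[order(s1$sample_id), ], s4[order(s4$sample_id), ])
})

test_that("brand-level specs partition a product into brands", {
  specs <- dplyr::filter(pcb_reference_concentrations("brand"), congener != "total")
  s <- generate_samples(specs, n_samples = 8, seed = 9, product = "yogurt")
  expect_equal(nrow(s), 40)
  expect_equal(sort(unique(s$brand)), dairy_brands)
  expect_true(all(s$product == "yogurt"))
  # brand B PCB28 is a printed point mass at 0.04
  expect_equal(s$PCB28[s$brand == "B"], rep(0.04, 8))
})

test_that("infeasible specs are rejected", {
  bad <- tibble::tibble(group = "yogurt", congener = ndl_congeners,
                        min = 2, max = 1, mean = 1.5, sd = 0.1)
  expect_error(generate_samples(bad, 5, seed = 1), "Infeasible")
})

test_that("exposure draws honour point masses, closed-form means and seeds", {
  cfg <- exposure_config(ir = 100, ef = 365, ed = 70, at = 25550,
                         bw = dist_uniform(15, 70), fat_fraction = 0.03)
  d <- generate_exposure_draws(cfg, 1e5, seed = 4)
  expect_equal(unique(d$ir), 100)
  expect_equal(unique(d$fat_fraction), 0.03)
  se <- (70 - 15) / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(d$bw) - 42.5), 3 * se)
  expect_identical(d, generate_exposure_draws(cfg, 1e5, seed = 4))

  all_points <- exposure_config(ir = 1, ef = 2, ed = 3, at = 4, bw = 5,
                                fat_fraction = 6)
  dp <- generate_exposure_draws(all_points, 10, seed = 1)
  expect_true(all(vapply(dp, function(x) length(unique(x)) == 1, logical(1))))
})

test_that("unknown distribution families are rejected", {
  bogus <- structure(list(family = "beta", params = list(a = 1, b = 2)),
                     class = "dist_spec")
  expect_error(draw_dist(bogus, 5), "Unknown distribution family")
})
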