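test_that("effective range adds the range-shifter water-equivalent thickness", {
  expect_equal(effective_range(treatment_plan(100, 10, 5, TRUE, 10)), 13.1)
  expect_equal(effective_range(treatment_plan(100, 10, 5, FALSE)), 10)
  expect_equal(effective_range(treatment_plan(100, 25, 10, TRUE, 10,
                                              rs_wet_cm = 0)), 25)
})

test_that("plan validation enforces the physical constraints", {
  expect_error(treatment_plan(100, 10, 15), # modulation > range
               class = "neutrondose_invalid_argument")
  expect_warning(treatment_plan(1000, 15, 10), "outside the supported domain")
  expect_error(treatment_plan(1000, 15, 10, strict = TRUE),
               class = "neutrondose_invalid_argument")
})

test_that("predictions are exactly linear in field-size area", {
  model <- default_scaling_model()
  base <- treatment_plan(100, 18, 8)
  h_base <- predict_h10(base, model, "B", quiet = TRUE)$h10_uSv_per_Gy
  for (k in c(0.09, 2.25, 6.25)) {
    scaled <- treatment_plan(100 * k, 18, 8)
    h_k <- predict_h10(scaled, model, "B", quiet = TRUE)$h10_uSv_per_Gy
    expect_equal(h_k / h_base, k, tolerance = 1e-14)
  }
  # the reference plan returns the baseline itself
  ref <- treatment_plan(100, 15, 10)
  for (p in c("A", "B", "D")) {
    expect_equal(predict_h10(ref, model, p, quiet = TRUE)$h10_uSv_per_Gy,
                 model$coefficients$a0[model$coefficients$position == p])
  }
})

test_that("the 3x3 to 30x30 cm2 field-size ratio is the linear-law factor 100", {
  model <- default_scaling_model()
  small <- treatment_plan(9, 15, 10)
  large <- suppressWarnings(treatment_plan(900, 15, 10))
  h_small <- predict_h10(small, model, "B", quiet = TRUE)$h10_uSv_per_Gy
  h_large <- suppressWarnings(
    predict_h10(large, model, "B", quiet = TRUE)$h10_uSv_per_Gy
  )
  expect_equal(h_large / h_small, 100, tolerance = 1e-12)
})

test_that("a range shifter raises the prediction via the effective range", {
  model <- default_scaling_model()
  on <- treatment_plan(100, 12, 5, TRUE, 10)
  off <- treatment_plan(100, 12, 5, FALSE)
  h_on <- predict_h10(on, model, "B", quiet = TRUE)$h10_uSv_per_Gy
  h_off <- predict_h10(off, model, "B", quiet = TRUE)$h10_uSv_per_Gy
  expect_gt(h_on, h_off)
})

test_that("range-shifter on/off ratio stays below 2.5 away from position D", {
  model <- default_scaling_model()
  grid <- tidyr::expand_grid(
    field_size_cm2 = c(9, 100, 625),
    range_cm = c(8, 10, 15, 20, 25),
    modulation_cm = c(3, 10, 25)
  )
  grid <- grid[grid$modulation_cm <= grid$range_cm, ]
  for (p in c("A", "B", "C", "E", "F")) {
    on <- predict_h10(dplyr::mutate(grid, range_shifter = TRUE, rs_wet_cm = 3.1),
                      model, p, quiet = TRUE)$h10_uSv_per_Gy
    off <- predict_h10(dplyr::mutate(grid, range_shifter = FALSE),
                       model, p, quiet = TRUE)$h10_uSv_per_Gy
    expect_true(all(on / off >= 1))
    expect_true(all(on / off <= 2.5))
  }
  # position D (range shifter in line of sight) may exceed the bound
  on_d <- predict_h10(dplyr::mutate(grid, range_shifter = TRUE, rs_wet_cm = 3.1),
                      model, "D", quiet = TRUE)$h10_uSv_per_Gy
  off_d <- predict_h10(dplyr::mutate(grid, range_shifter = FALSE),
                       model, "D", quiet = TRUE)$h10_uSv_per_Gy
  expect_gt(max(on_d / off_d), 2.5)
})

test_that("fitting a noise-free campaign recovers the generating model exactly", {
  camp <- make_campaign(seed = 5, noise = 0)
  fit <- fit_scaling_model(camp$truth)
  truth <- camp$truth_model$coefficients
  est <- fit$model$coefficients[match(truth$position,
                                      fit$model$coefficients$position), ]
  for (cn in c("a0", "c_r", "c_m1", "c_m2")) {
    expect_equal(est[[cn]], truth[[cn]], tolerance = 1e-6)
  }
  # and the fitted model reproduces the data it was fitted to
  pred <- predict_h10(camp$truth[camp$truth$position == "B", ],
                      fit$model, "B", quiet = TRUE)
  expect_equal(pred$h10_uSv_per_Gy,
               camp$truth$h10_uSv_per_Gy[camp$truth$position == "B"],
               tolerance = 1e-8)
})

test_that("fitting a noisy campaign recovers coefficients within 3 standard errors", {
  camp <- make_campaign(seed = 1, noise = 0.15)
  expect_gte(nrow(camp$plans), 60)
  fit <- fit_scaling_model(camp$measured)
  td <- tidy(fit)
  truth <- tidyr::pivot_longer(camp$truth_model$coefficients, -position,
                               names_to = "term", values_to = "truth")
  m <- dplyr::inner_join(td, truth, by = c("position", "term"))
  expect_equal(nrow(m), 24)
  expect_true(all(abs(m$estimate - m$truth) <= 3 * m$std.error))
})

test_that("degenerate designs fail with the missing axis named", {
  camp <- make_campaign(seed = 2, noise = 0)$truth
  one_fs <- camp[camp$field_size_cm2 == 100, ]
  expect_error(fit_scaling_model(one_fs), "field_size")
  one_r <- camp[camp$range_cm == 15, ]
  expect_error(fit_scaling_model(one_r), "range_cm")
  one_m <- camp[camp$modulation_cm == 10, ]
  expect_error(fit_scaling_model(one_m), "modulation_cm")
})

test_that("fits are deterministic under row permutation", {
  camp <- make_campaign(seed = 3, noise = 0.2)$measured
  fit1 <- fit_scaling_model(camp)
  withr::with_seed(1, shuffled <- camp[sample(nrow(camp)), ])
  fit2 <- fit_scaling_model(shuffled)
  expect_equal(fit1$model$coefficients, fit2$model$coefficients,
               tolerance = 1e-12)
})

test_that("tidy and glance expose the per-position fit", {
  fit <- fit_scaling_model(make_campaign(seed = 4, noise = 0.1)$measured)
  td <- tidy(fit)
  expect_setequal(names(td), c("position", "term", "estimate", "std.error"))
  expect_equal(nrow(td), 6 * 4)
  g <- glance(fit)
  expect_setequal(names(g), c("position", "n", "sigma_log"))
  expect_true(all(g$sigma_log > 0))
})

test_that("inverse-square extrapolation is the exact closed form", {
  expect_equal(extrapolate_inverse_square(10, 1, 1), 10)
  expect_equal(extrapolate_inverse_square(10, 1, 0.5), 40)
  expect_equal(extrapolate_inverse_square(10, 1, 0.1), 1000)
  expect_error(extrapolate_inverse_square(10, 0, 1),
               class = "neutrondose_invalid_argument")
})

test_that("organ-dose estimation factorises into the documented corrections", {
  model <- default_scaling_model()
  pos_b <- default_positions()[2, ]
  ref_plan <- treatment_plan(100, 20, 5)
  # identical plans at the reference distance leave the dose unchanged
  same <- estimate_organ_dose(50, ref_plan, ref_plan, pos_b, 1, model)
  expect_equal(same$h10_uSv_per_Gy, 50)
  expect_equal(same$field_size_factor, 1)
  expect_equal(same$range_factor, 1)
  expect_equal(same$modulation_factor, 1)
  expect_equal(same$inverse_square_factor, 1)
  # inverse square only
  closer <- estimate_organ_dose(50, ref_plan, ref_plan, pos_b, 0.5, model)
  expect_equal(closer$h10_uSv_per_Gy, 200)
  # the 100 -> 33 cm2 field-size step is a division by 100/33 = 3.03
  target <- treatment_plan(33, 18, 5)
  est <- estimate_organ_dose(50, ref_plan, target, pos_b, 1, model)
  expect_equal(est$field_size_factor, 33 / 100)
  expect_lt(est$range_factor, 1)  # shallower plan produces fewer neutrons
  # the factorisation identity: product of factors times reference = dose
  expect_equal(
    est$h10_uSv_per_Gy,
    50 * est$field_size_factor * est$range_factor * est$modulation_factor *
      est$inverse_square_factor,
    tolerance = 1e-12
  )
  # placeholder positions demand explicit distances
  pos_a <- default_positions()[1, ]
  expect_error(estimate_organ_dose(50, ref_plan, target, pos_a, 1, model),
               class = "neutrondose_invalid_argument")
})
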