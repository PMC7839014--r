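test_that("noiseless power-law points are recovered to machine precision", {
  pts <- data.frame(weight = c(0.02, 0.25, 3.5), value = 5 * c(0.02, 0.25, 3.5))
  fit <- fit_power_law(pts)
  expect_equal(fit$coefficient_a, 5, tolerance = 1e-12)
  expect_equal(fit$exponent_b, 1, tolerance = 1e-12)
})

test_that("three-species fit matches the published DSTP3086S parameters", {
  fit <- fit_power_law(data.frame(weight = c(0.02, 0.25, 3.5),
                                  value = c(0.20, 2.37, 46.9)))
  expect_equal(round(fit$coefficient_a, 1), 11.7)
  expect_equal(round(fit$exponent_b, 2), 1.06)
})

test_that("two-point fits interpolate both points exactly", {
  for (pair in list(c(0.02, 0.2, 3.5, 46.9), c(0.25, 2.37, 3.5, 46.9),
                    c(1, 3, 10, 4))) {
    pts <- data.frame(weight = pair[c(1, 3)], value = pair[c(2, 4)])
    fit <- fit_power_law(pts)
    fitted <- fit$coefficient_a * pts$weight^fit$exponent_b
    expect_equal(fitted, pts$value, tolerance = 1e-12)
  }
})

test_that("OLS fit agrees with the grid-search oracle on every bundled series", {
  d <- adc_clearance_data()
  for (i in seq_len(nrow(d))) {
    animals <- d$animals[[i]]
    fit <- fit_series(animals)
    oracle <- grid_search_power_law(animals$body_weight_kg,
                                    animals$clearance_ml_per_day,
                                    centre_a = fit$coefficient_a,
                                    centre_b = fit$exponent_b)
    res <- grid_resolution(fit$coefficient_a, fit$exponent_b)
    expect_lt(abs(oracle["a"] - fit$coefficient_a), res["a"])
    expect_lt(abs(oracle["b"] - fit$exponent_b), res["b"])
  }
})

test_that("rescaling all weights by k leaves b unchanged and scales a by k^-b", {
  pts <- data.frame(weight = c(0.02, 0.25, 3.5), value = c(0.18, 3.98, 46.55))
  fit <- fit_power_law(pts)
  for (k in c(0.001, 2.2, 1000)) {
    scaled <- fit_power_law(transform(pts, weight = weight * k))
    expect_equal(scaled$exponent_b, fit$exponent_b, tolerance = 1e-9)
    expect_equal(scaled$coefficient_a, fit$coefficient_a * k^(-fit$exponent_b),
                 tolerance = 1e-9)
    # human prediction is invariant when the human weight is rescaled too
    expect_equal(scaled$coefficient_a * (70 * k)^scaled$exponent_b,
                 fit$coefficient_a * 70^fit$exponent_b, tolerance = 1e-9)
  }
})

test_that("fitting errors are raised for degenerate inputs", {
  expect_error(fit_power_law(data.frame(weight = 1, value = 2)),
               "At least two")
  expect_error(fit_power_law(data.frame(weight = c(1, 1), value = c(2, 3))),
               "distinct")
  expect_error(fit_power_law(data.frame(weight = c(1, 2), value = c(-1, 3))),
               "positive")
  expect_error(fit_power_law(data.frame(w = 1:3, v = 1:3)), "columns")
})

test_that("corrected fits reduce to simple allometry when constants are all one", {
  animals <- as_series_table(exact_panel(9, 0.8))$animals[[1]]
  flat_constants <- species_constants()
  flat_constants$mlp_years <- 1
  flat_constants$brain_weight_g <- 1
  simple <- fit_series(animals, method = "simple")
  mlp <- fit_series(animals, flat_constants, method = "mlp_product")
  brw <- fit_series(animals, flat_constants, method = "brain_weight_product")
  expect_equal(mlp$coefficient_a, simple$coefficient_a, tolerance = 1e-12)
  expect_equal(brw$exponent_b, simple$exponent_b, tolerance = 1e-12)
})

test_that("predict_human divides corrected fits by the human constant", {
  animals <- adc_clearance_data()$animals[[
    which(adc_clearance_data()$drug == "T-DM1" &
            adc_clearance_data()$analyte == "total")]]
  mlp <- fit_series(animals, method = "mlp_product")
  expect_equal(predict_human(mlp),
               mlp$coefficient_a * 70^mlp$exponent_b / 93.4)
  # constant model: a = 1, b = 0 predicts 1 mL/day
  const <- fit_power_law(data.frame(weight = c(1, 2), value = c(1, 1)))
  expect_equal(predict_human(const), 1, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_series(adc_clearance_data()$animals[[2]])
  td <- tidy(fit)
  expect_equal(td$term, c("coefficient_a", "exponent_b"))
  expect_equal(td$estimate, c(fit$coefficient_a, fit$exponent_b))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "simple")
  expect_gt(gl$r.squared, 0.9)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
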