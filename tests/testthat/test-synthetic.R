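test_that("noiseless generation evaluates the power law exactly", {
  spec <- synthetic_spec(5, 1, noise_cv = 0, seed = 1)
  d <- simulate_clearance_data(spec)
  expect_equal(d$animals[[1]]$clearance_ml_per_day, c(0.1, 1.25, 17.5))
  expect_equal(d$human_cl_ml_per_day, 350)
})

test_that("noiseless panels recover the generating parameters to machine precision", {
  for (truth in list(c(11.7, 1.06), c(9.9, 0.82), c(0.3, 1.4))) {
    d <- simulate_clearance_data(
      synthetic_spec(truth[1], truth[2], noise_cv = 0, seed = 3)
    )
    fit <- fit_series(d$animals[[1]])
    expect_equal(fit$coefficient_a, truth[1], tolerance = 1e-10)
    expect_equal(fit$exponent_b, truth[2], tolerance = 1e-10)
  }
  # exact also for any two-species panel
  d2 <- simulate_clearance_data(
    synthetic_spec(7, 0.9, species_panel = c("mouse", "monkey"),
                   noise_cv = 0, seed = 4)
  )
  fit2 <- fit_series(d2$animals[[1]])
  expect_equal(c(fit2$coefficient_a, fit2$exponent_b), c(7, 0.9),
               tolerance = 1e-10)
})

test_that("generation is reproducible from the seed", {
  spec <- synthetic_spec(11.7, 1.06, noise_cv = 0.3, n_replicates = 5,
                         seed = 99)
  expect_equal(simulate_clearance_data(spec), simulate_clearance_data(spec))
  other <- simulate_clearance_data(
    synthetic_spec(11.7, 1.06, noise_cv = 0.3, n_replicates = 5, seed = 100)
  )
  expect_false(identical(simulate_clearance_data(spec), other))
})

test_that("synthetic specs validate their parameters", {
  expect_error(synthetic_spec(-1, 1), "true_a")
  expect_error(synthetic_spec(1, 1, noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_spec(1, 1, species_panel = character(0)), "non-empty")
  expect_error(synthetic_spec(1, 1, species_panel = c("mouse", "human")),
               "human")
})

test_that("synthetic data flows through dataset IO unchanged", {
  d <- simulate_clearance_data(
    synthetic_spec(8, 0.95, noise_cv = 0.2, n_replicates = 3, seed = 11)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_clearance_data(d, path)
  back <- read_clearance_data(path)
  expect_equal(back$animals, d$animals)
  expect_equal(back$human_cl_ml_per_day, d$human_cl_ml_per_day)
})

test_that("noiseless recovery experiment shows zero bias and perfect matching strategy", {
  rep <- recovery_experiment(
    synthetic_spec(6, 1.0, noise_cv = 0, n_replicates = 3, seed = 5),
    fixed_exponents = c(0.85, 1.0)
  )
  expect_equal(rep$parameter_summary$bias_a, 0, tolerance = 1e-9)
  expect_equal(rep$parameter_summary$bias_b, 0, tolerance = 1e-9)
  perf <- rep$strategy_performance
  # every strategy whose fixed exponent equals true b is exact, as are the
  # fitted strategies
  exact <- perf$prop_within[grepl("b=1$|three_species|two_species",
                                  perf$strategy_label)]
  expect_true(all(exact == 1))
})

test_that("mouse exponent-1.0 scaling over-predicts by (70/0.02)^0.15 when true b is 0.85", {
  d <- simulate_clearance_data(
    synthetic_spec(5, 0.85, species_panel = "mouse", noise_cv = 0, seed = 2)
  )
  pred <- scale_one_species(d, species = "mouse", exponents = 1.0)
  expect_equal(pred$ratio, 3500^0.15, tolerance = 1e-9)
  expect_equal(pred$classification, "over")
})

test_that("log-space OLS is unbiased for b under lognormal noise", {
  rep <- recovery_experiment(
    synthetic_spec(11.7, 1.06, noise_cv = 0.2, n_replicates = 1000,
                   seed = 123)
  )
  s <- rep$parameter_summary
  expect_lt(abs(s$bias_b), 3 * s$se_b)
})

test_that("wider weight span shrinks the variance of the fitted exponent", {
  narrow <- recovery_experiment(
    synthetic_spec(10, 1, species_panel = c("mouse", "rat"), noise_cv = 0.25,
                   n_replicates = 400, seed = 21)
  )$parameter_summary
  wide <- recovery_experiment(
    synthetic_spec(10, 1, species_panel = c("mouse", "monkey"),
                   noise_cv = 0.25, n_replicates = 400, seed = 21)
  )$parameter_summary
  expect_lt(wide$rmse_b, narrow$rmse_b)
})
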