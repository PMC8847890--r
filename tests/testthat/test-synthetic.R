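test_that("the generator is deterministic given its seed", {
  cfg <- generator_config(seed = 99, n_timepoints = 10)
  d1 <- generate_trial(cfg)
  d2 <- generate_trial(cfg)
  expect_identical(d1$observations, d2$observations)
  expect_identical(d1$times, d2$times)
  d3 <- generate_trial(generator_config(seed = 100, n_timepoints = 10))
  expect_false(identical(d1$observations, d3$observations))
})

test_that("vanishing noise reproduces the simulated trajectory", {
  cfg <- generator_config(seed = 5, n_timepoints = 8, noise_sd = 1e-12)
  d <- generate_trial(cfg)
  gt <- attr(d, "ground_truth")
  clean <- gt$trajectory[, ferm_state_names()]
  unit <- sweep(clean, 2, gt$peak_factors, "/")
  raw <- sweep(unit, 2, gt$scale_factors, "*")
  expect_equal(d$observations, raw, tolerance = 1e-9)
})

test_that("observation noise is Gaussian at the configured level", {
  resid <- c()
  for (s in 1:50) {
    d <- generate_trial(generator_config(seed = 3000 + s, n_timepoints = 8,
                                         noise_sd = 0.05, grid = "uniform"))
    gt <- attr(d, "ground_truth")
    unit_obs <- sweep(d$observations, 2, gt$scale_factors, "/")
    unit_true <- sweep(gt$trajectory[, ferm_state_names()], 2,
                       gt$peak_factors, "/")
    r <- (unit_obs - unit_true)[-1, ]    # first row is noise-free
    # keep residuals away from the clip-at-zero boundary
    resid <- c(resid, r[unit_true[-1, ] > 0.2])
  }
  set.seed(1)
  expect_gt(stats::shapiro.test(sample(resid, min(4000, length(resid))))$p.value, 0.01)
  expect_lt(abs(stats::sd(resid) - 0.05) / 0.05, 0.1)
})

test_that("ground truth records are sufficient for recovery checks", {
  d <- generate_trial(generator_config(seed = 8, n_timepoints = 9))
  gt <- attr(d, "ground_truth")
  expect_equal(gt$variant$label, "MI(0)")
  expect_length(gt$true_params_raw, 24)
  # the unit-space truth must reproduce the unit-peak trajectory
  unit_init <- gt$trajectory[1, ferm_state_names()] / gt$peak_factors
  tr <- simulate_variant(gt$variant, gt$true_params_unit, unit_init, d$times)
  unit_true <- sweep(gt$trajectory[, ferm_state_names()], 2,
                     gt$peak_factors, "/")
  expect_equal(tr[, -1], unit_true, tolerance = 1e-3)
})

test_that("cohorts attach class labels and apply parameter offsets", {
  base <- generator_config(seed = 21, n_timepoints = 8)
  coh <- generate_cohort(base,
                         classes = list(A = c(), B = c(mu_LAB_Glc = 1.5)),
                         n_per_class = 3, feature = "cultivar")
  expect_length(coh$datasets, 6)
  expect_equal(coh$classes, rep(c("A", "B"), each = 3))
  expect_equal(coh$datasets[[4]]$features$cultivar, "B")
  gt_b <- attr(coh$datasets[[4]], "ground_truth")
  expect_equal(unname(gt_b$true_params["mu_LAB_Glc"]),
               unname(base$true_params["mu_LAB_Glc"]) * 1.5)
  codes <- vapply(coh$datasets, function(d) d$code, character(1))
  expect_equal(anyDuplicated(codes), 0L)
  expect_error(generate_cohort(base, classes = list(A = c(bogus = 2))),
               "offset names")
  expect_error(generate_cohort(base, classes = list(A = c(mu_Y_Glc = -1))),
               "positive")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_timepoints = 5), "6..17")
  expect_error(generator_config(n_timepoints = 18), "6..17")
  expect_error(generator_config(noise_sd = 0), "positive")
})
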