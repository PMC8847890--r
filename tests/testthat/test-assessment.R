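test_that("PSIS-LOO reduces to the log predictive density for constant draws", {
  S <- 400; n <- 6
  p <- 0.2
  log_lik <- matrix(log(p), S, n)
  loo <- psis_loo(log_lik)
  expect_equal(loo$elpd, n * log(p))
  expect_true(all(is.nan(loo$pareto_k)))
  expect_error(psis_loo(log_lik[1:50, ]), "100 draws")
})

test_that("PSIS-LOO agrees with exact refit LOO on the conjugate model", {
  cc <- conjugate_case()
  loo <- psis_loo(cc$log_lik)
  expect_lt(abs(loo$elpd - cc$exact_elpd), 2 * loo$se)
  expect_true(all(loo$pareto_k < 0.7))
  expect_equal(sum(loo$pointwise), loo$elpd)
  expect_gte(loo$se, 0)
})

test_that("pseudo-BMA weights are a shift-invariant softmax of elpd", {
  expect_equal(pseudo_bma_weights(c(0, 0)), c(0.5, 0.5))
  expect_equal(pseudo_bma_weights(c(0, log(3))), c(0.25, 0.75))
  w1 <- pseudo_bma_weights(c(-3, -1, -2))
  w2 <- pseudo_bma_weights(c(-3, -1, -2) + 100)
  expect_equal(w1, w2)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  expect_error(pseudo_bma_weights(list()), "at least one")
})

test_that("OSR counts successes over datasets fitted by any variant", {
  success <- matrix(c(TRUE, TRUE, FALSE,
                      TRUE, FALSE, FALSE,
                      FALSE, FALSE, FALSE), 3, 3, byrow = TRUE,
                    dimnames = list(c("MI(0)", "MI(1)", "MI(5)"),
                                    c("d1", "d2", "d3")))
  # d3 has no success anywhere: excluded from the denominator
  osr <- compute_osr(success)
  expect_equal(unname(osr), c(1, 0.5, 0))
  # removing a success never increases OSR while the dataset stays fitted
  # by at least one variant (here d1 keeps its MI(0) success)
  success2 <- success; success2["MI(1)", "d1"] <- FALSE
  expect_true(all(compute_osr(success2) <= osr))
  expect_error(compute_osr(success & FALSE), "no dataset")
  # printed at 2 decimals: 18 of 23 -> 0.78
  expect_equal(round(18 / 23, 2), 0.78)
})

test_that("ESR is the product of elementary observed success rates", {
  osr_singles <- c(0.52, 0.61, 0.83, 0.65, 0.09)
  expect_equal(compute_esr(osr_singles, c(1, 2, 5)), 0.52 * 0.61 * 0.09)
  expect_equal(compute_esr(osr_singles, c(2, 3)), 0.61 * 0.83)
  expect_equal(compute_esr(c(0.5, 0, 0.8, 0.1, 0.2), c(2, 4)), 0)
  expect_error(compute_esr(osr_singles, 3), "two or more")
  expect_error(compute_esr(osr_singles, integer(0)), "two or more")
})

test_that("ESR equals the OSR product for arbitrary success matrices", {
  set.seed(33)
  labels <- vapply(enumerate_variants(), attr, character(1), "label")
  for (rep in 1:10) {
    success <- matrix(runif(32 * 6) < 0.5, 32, 6,
                      dimnames = list(labels, paste0("d", 1:6)))
    success[1, 1] <- TRUE   # keep the denominator non-empty
    osr <- compute_osr(success)
    singles <- osr[paste0("MI(", 1:5, ")")]
    for (lab in c("MI(1,2,5)", "MI(2,3)", "MI(1,2,3,4,5)")) {
      ms <- mechanism_set(lab)
      expect_equal(compute_esr(unname(singles), ms),
                   prod(singles[which(ms)]), info = lab)
    }
  }
})

test_that("mean BMA weights average successes over qualifying datasets", {
  success <- matrix(c(TRUE, TRUE,
                      TRUE, FALSE), 2, 2, byrow = TRUE,
                    dimnames = list(c("MI(0)", "MI(1)"), c("d1", "d2")))
  w <- list(d1 = c("MI(0)" = 0.6, "MI(1)" = 0.4),
            d2 = c("MI(0)" = 1))
  bma <- mean_bma(w, success)
  expect_equal(unname(bma["MI(0)"]), (0.6 + 1) / 2)
  expect_equal(unname(bma["MI(1)"]), 0.2)     # (0.4 + 0) / 2
  # a variant failing everywhere has zero weight
  success3 <- rbind(success, "MI(5)" = c(FALSE, FALSE))
  expect_equal(unname(mean_bma(w, success3)["MI(5)"]), 0)
  # single dataset, sole successful variant
  s1 <- matrix(TRUE, 1, 1, dimnames = list("MI(0)", "d1"))
  expect_equal(unname(mean_bma(list(d1 = c("MI(0)" = 1)), s1)), 1)
})

test_that("the assessment table integrates LOO, weights and success rates", {
  # synthetic fits: two variants, two datasets, one failure
  fake_fit <- function(elpd_per_obs, success, n_obs = 12, S = 300) {
    ll <- matrix(elpd_per_obs + rnorm(S * n_obs, 0, 0.01), S, n_obs)
    list(log_lik = ll, success = success)
  }
  set.seed(8)
  fits <- list(
    "MI(0)" = list(d1 = fake_fit(-0.1, TRUE), d2 = fake_fit(-0.2, TRUE)),
    "MI(1)" = list(d1 = fake_fit(-0.3, TRUE), d2 = fake_fit(-0.2, FALSE)))
  tab <- assessment_table(fits)
  expect_equal(tab$variant, c("MI(0)", "MI(1)"))
  expect_equal(tab$n_params, c(24L, 27L))
  expect_equal(tab$OSR, c(1, 0.5))
  expect_true(all(is.na(tab$ESR)))          # no multi-mechanism variants
  w <- attr(tab, "weights_by_dataset")
  expect_equal(vapply(w, sum, numeric(1)), c(d1 = 1, d2 = 1))
  expect_length(w$d2, 1)                    # only the successful variant
  expect_true(tab$BMA_w[1] > tab$BMA_w[2])
  expect_lte(sum(tab$BMA_w), 1 + 1e-12)
})
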