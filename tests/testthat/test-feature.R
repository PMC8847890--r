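test_that("CI filtering retains the central mass, per chain and jointly", {
  fit <- fixture_fit()
  kept <- filter_ci_draws(fit, strict = FALSE, rescale = FALSE)
  expect_true(nrow(kept) > 0)
  expect_equal(ncol(kept), 24)
  expect_lt(attr(kept, "retention"), 1)
  # every retained coordinate lies inside its own chain's central interval
  ch1 <- fit$draws[fit$chain_id == 1, 1:24]
  lo <- apply(ch1, 2, quantile, 0.025); hi <- apply(ch1, 2, quantile, 0.975)
  rows1 <- kept[attr(kept, "chain") == 1, , drop = FALSE]
  expect_true(all(sweep(rows1, 2, lo, ">=") & sweep(rows1, 2, hi, "<=")))
})

test_that("joint retention matches marginal products for independent draws", {
  # synthetic fit-like object: one chain of independent standard normals
  set.seed(12)
  d <- 10; n <- 4000
  fake <- fixture_fit()
  fake$variant <- list(n_params = d, label = "synthetic",
                       parameter_names = paste0("p", 1:d))
  fake$draws <- matrix(abs(rnorm(n * d)) + 0.01, n, d,
                       dimnames = list(NULL, paste0("p", 1:d)))
  fake$chain_id <- rep(1L, n)
  class(fake) <- "ferm_fit"
  kept <- filter_ci_draws(fake, strict = FALSE, rescale = FALSE)
  expect_lt(abs(attr(kept, "retention") - 0.95^d), 0.05)
  # constant draws: everything retained
  fake$draws[] <- 0.7
  kept2 <- filter_ci_draws(fake, strict = FALSE, rescale = FALSE)
  expect_equal(attr(kept2, "retention"), 1)
})

test_that("parameter subgroups follow the typology and microbe association", {
  fit <- fixture_fit()
  # fixture has no cultivar label -> draw_table must refuse
  expect_error(draw_table(list(fit), feature = "cultivar", strict = FALSE),
               "no fit carries")
  fit$features$cultivar <- "cf"
  tabd <- draw_table(list(fit), feature = "cultivar", strict = FALSE)
  expect_equal(ncol(subset_params(tabd, "mortality_rates")$draws), 3)
  expect_equal(ncol(subset_params(tabd, "max_growth_rates")$draws), 5)
  expect_equal(ncol(subset_params(tabd, "yield_coefficients")$draws), 11)
  expect_identical(subset_params(tabd, "all"), tabd)
  lab_cols <- colnames(subset_params(tabd, "LAB_related")$draws)
  expect_setequal(lab_cols, c("mu_LAB_Glc", "K_LAB_Glc", "k_LAB",
                              "Y_Glc_LAB", "Y_LA_LAB_Glc", "Y_Ac_LAB_Glc"))
  # saturation constants never form their own subgroup but appear in
  # microbe-related sets
  expect_true("K_LAB_Glc" %in% lab_cols)
  groups <- c("max_growth_rates", "mortality_rates", "yield_coefficients")
  for (g in groups)
    expect_false(any(grepl("^K_", colnames(subset_params(tabd, g)$draws))))
})

test_that("LAB-related subgroup of MI(2,3) includes the M2 parameters", {
  v <- build_variant("MI(2,3)")
  tab <- ferm_parameter_table()
  tab <- tab[tab$name %in% v$parameter_names, ]
  lab_names <- tab$name[tab$microbe %in% "LAB"]
  expect_setequal(lab_names,
                  c("mu_LAB_Glc", "mu_LAB_Fru", "K_LAB_Glc", "K_LAB_Fru",
                    "k_LAB", "Y_Glc_LAB", "Y_Fru_LAB", "Y_EtOH_LAB_Glc",
                    "Y_EtOH_LAB_Fru", "Y_LA_LAB_Glc", "Y_LA_LAB_Fru",
                    "Y_Ac_LAB_Glc", "Y_Ac_LAB_Fru"))
})

test_that("PCA uses centred unscaled data with a fixed sign convention", {
  # 1-D data along an axis: PC1 explains everything
  set.seed(3)
  t_ax <- rnorm(200)
  x <- cbind(a = 2 * t_ax, b = -t_ax, c = 0.5 * t_ax)
  pc <- run_pca(x)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  # largest-magnitude loading is positive
  expect_gt(pc$loadings[which.max(abs(pc$loadings[, 1])), 1], 0)
  # isotropic 2-D Gaussian: explained variance close to (0.5, 0.5)
  set.seed(4)
  iso <- matrix(rnorm(8000), ncol = 2)
  expect_lt(abs(run_pca(iso)$explained[1] - 0.5), 0.05)
  # orthogonal reconstruction recovers the centred data
  set.seed(5)
  y <- matrix(rnorm(600), ncol = 6)
  pcy <- run_pca(y)
  rec <- pcy$scores %*% t(pcy$loadings)
  expect_equal(rec, scale(y, scale = FALSE), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(run_pca(y[1, , drop = FALSE]), "at least 2")
})

test_that("pairwise squared Mahalanobis distance matches closed forms", {
  # identical centroids -> zero distance
  set.seed(6)
  base <- matrix(rnorm(600), ncol = 2)
  cls <- rep(c("a", "b"), each = 150)
  d0 <- pairwise_mahalanobis(base, cls)
  expect_lt(d0$D["a", "b"], 0.15)
  expect_equal(d0$D["a", "a"], 0)
  expect_equal(d0$D, t(d0$D))
  # centroid offset (3, 4) under identity within-class covariance -> 25
  set.seed(7)
  n <- 60000
  x <- matrix(rnorm(2 * n), ncol = 2)
  x[(n / 2 + 1):n, ] <- sweep(x[(n / 2 + 1):n, ], 2, c(3, 4), "+")
  cls2 <- rep(c("a", "b"), each = n / 2)
  d1 <- pairwise_mahalanobis(x, cls2)
  expect_equal(d1$D["a", "b"], 25, tolerance = 0.5)
  # a single pair: the median is that pair's distance
  expect_equal(d1$median_D, d1$D["a", "b"])
})

test_that("class separation recovers a designed Mahalanobis gap", {
  # two classes at squared separation 8 under anisotropic covariance
  set.seed(8)
  n <- 500
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  L <- chol(S)
  delta <- drop(t(L) %*% c(sqrt(8), 0))  # Mahalanobis length sqrt(8)
  a <- matrix(rnorm(2 * n), ncol = 2) %*% L
  b <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% L, 2, delta, "+")
  res <- pairwise_mahalanobis(rbind(a, b), rep(c("a", "b"), each = n))
  expect_lt(abs(res$D["a", "b"] - 8) / 8, 0.25)
})

test_that("Mahalanobis separation is invariant under affine score maps", {
  set.seed(9)
  x <- cbind(rnorm(300), rnorm(300, sd = 3))
  x[101:300, 1] <- x[101:300, 1] + 2
  cls <- rep(c("a", "b", "c"), each = 100)
  d_ref <- pairwise_mahalanobis(x, cls)$D
  A <- matrix(c(2, 1, -0.5, 3), 2)
  y <- x %*% A + matrix(c(5, -7), 300, 2, byrow = TRUE)
  d_map <- pairwise_mahalanobis(y, cls)$D
  expect_equal(d_map, d_ref, tolerance = 1e-8)
})

test_that("separation requires enough classes, rows and a non-singular S", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(pairwise_mahalanobis(x, rep("a", 10)), "two classes")
  expect_error(pairwise_mahalanobis(x, c(rep("a", 8), "b", "b")),
               "at least 3")
  sing <- cbind(1:12, 2 * (1:12))
  expect_error(pairwise_mahalanobis(sing, rep(c("a", "b"), each = 6)),
               "singular")
})
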