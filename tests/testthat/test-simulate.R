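test_that("a zero vector field leaves the trajectory at the initial state", {
  v <- build_variant("MI(0)")
  p <- stats::setNames(rep(0, 24), v$parameter_names)
  # all growth/mortality zero: saturation constants must stay positive
  p[grep("^K_", names(p))] <- 0.5
  init <- default_initial_state()
  tr <- simulate_variant(v, p, init, seq(0, 160, by = 20))
  for (i in seq_len(nrow(tr)))
    expect_equal(unname(tr[i, -1]), unname(init), tolerance = 1e-10)
})

test_that("adaptive trajectories match a fine fixed-step RK4 oracle", {
  times <- seq(0, 160, length.out = 17)
  for (lab in c("MI(0)", "MI(1,2,3,4,5)")) {
    v <- build_variant(lab)
    p <- default_true_params(v)
    adaptive <- simulate_variant(v, p, default_initial_state(), times)
    oracle <- simulate_rk4_fixed(v, p, default_initial_state(), times,
                                 h = 0.001)
    # per state: worst absolute deviation relative to the state's scale
    for (s in ferm_state_names()) {
      rel <- max(abs(adaptive[, s] - oracle[, s])) / max(abs(oracle[, s]))
      expect_lt(rel, 1e-4, label = paste(lab, s, "relative error"))
    }
  }
})

test_that("product decay only removes mass relative to the baseline", {
  v1 <- build_variant("MI(1)")
  p <- default_true_params(v1)
  p[c("b_EtOH", "b_LA", "b_Ac")] <- c(0.05, 0.05, 0.05)
  times <- seq(0, 160, length.out = 17)
  with_decay <- simulate_variant(v1, p, default_initial_state(), times)
  baseline <- simulate_variant("MI(0)",
                               p[build_variant("MI(0)")$parameter_names],
                               default_initial_state(), times)
  for (s in c("EtOH", "LA", "Ac"))
    expect_true(all(with_decay[, s] <= baseline[, s] + 1e-8), info = s)
})

test_that("switching a mechanism's parameters to zero reproduces the submodel", {
  times <- seq(0, 160, length.out = 9)
  p_full <- default_true_params("MI(1,2,3,4,5)")
  cases <- list(c(sub = "MI(2)", sup = "MI(2,5)", off = "M5"),
                c(sub = "MI(0)", sup = "MI(3)", off = "M3"))
  tab <- ferm_parameter_table()
  for (cs in cases) {
    p_sup <- p_full[build_variant(cs[["sup"]])$parameter_names]
    p_sup[tab$name[tab$mechanism == cs[["off"]]]] <- 0
    tr_sup <- simulate_variant(cs[["sup"]], p_sup,
                               default_initial_state(), times)
    p_sub <- p_full[build_variant(cs[["sub"]])$parameter_names]
    tr_sub <- simulate_variant(cs[["sub"]], p_sub,
                               default_initial_state(), times)
    expect_equal(tr_sup, tr_sub, tolerance = 1e-8)
  }
})

test_that("trajectories stay essentially non-negative for all 32 variants", {
  times <- seq(0, 160, length.out = 17)
  p_full <- default_true_params("MI(1,2,3,4,5)")
  for (v in enumerate_variants()) {
    bv <- build_variant(v)
    tr <- simulate_variant(bv, p_full[bv$parameter_names],
                           default_initial_state(), times)
    expect_true(all(tr[, -1] >= 0), info = bv$label)
  }
})

test_that("simulation failures carry the failing time", {
  v <- build_variant("MI(0)")
  p <- default_true_params(v)
  err <- tryCatch(
    simulate_variant(v, p, default_initial_state(), seq(0, 160, by = 10),
                     solver_config(max_steps = 2)),
    cocoaferm_simulation_error = function(e) e)
  expect_s3_class(err, "cocoaferm_simulation_error")
  expect_true(is.numeric(err$time))
  expect_error(simulate_variant(v, p, rep(-1, 8), c(0, 1)), "non-negative")
  expect_error(simulate_variant(v, p, rep(1, 8), c(1, 0)), "increasing")
})

test_that("trajectory CSV round-trips through the documented layout", {
  tr <- simulate_variant("MI(0)", default_true_params("MI(0)"),
                         default_initial_state(), seq(0, 100, by = 25))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("time", ferm_state_names()))
  expect_equal(as.matrix(back), tr, tolerance = 1e-12,
               ignore_attr = TRUE)
})
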