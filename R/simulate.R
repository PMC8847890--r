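#' Numerical solver configuration
#'
#' Defaults follow the estimation set-up used throughout the package:
#' adaptive Runge-Kutta 4(5) (Dormand-Prince) with relative and absolute
#' tolerances of 1e-6 and at most 1e4 steps.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance; also the clamp threshold for integrator
#'   undershoot below zero.
#' @param max_steps maximum number of integration steps.
#' @param method deSolve Runge-Kutta method tag.
#' @return An object of class \code{"solver_config"}.
#' @export
solver_config <- function(rtol = 1e-6, atol = 1e-6, max_steps = 1e4,
                          method = "ode45") {
  stopifnot(rtol > 0, atol > 0, max_steps > 0)
  structure(list(rtol = rtol, atol = atol, max_steps = max_steps,
                 method = method),
            class = "solver_config")
}

#' Simulate a fermentation model variant
#'
#' Integrates the 8-state ODE system of a variant from a given initial
#' state over the requested output times, using the compiled right-hand
#' side through \code{deSolve} (or the reference R implementation with
#' \code{engine = "R"}, mainly for cross-checks).
#'
#' States that undershoot zero by at most \code{atol} are clamped to zero;
#' larger negative values, non-finite states, or step-limit exhaustion raise
#' a \code{"cocoaferm_simulation_error"} condition carrying the failing time.
#'
#' @param variant a \code{ferm_variant}, mechanism set, label or index vector.
#' @param params named parameter vector covering the variant's free
#'   parameters (extra entries are ignored; inactive-mechanism entries are
#'   forced to zero).
#' @param init non-negative initial state (length 8, canonical order).
#' @param times strictly increasing output times in hours; the first entry
#'   is the initial time.
#' @param solver a \code{\link{solver_config}}.
#' @param engine \code{"C"} (default) or \code{"R"}.
#' @return A numeric matrix with \code{length(times)} rows and columns
#'   \code{time, Glc, Fru, EtOH, LA, Ac, Y, LAB, AAB}.
#' @examples
#' v <- build_variant("MI(0)")
#' p <- default_true_params("MI(0)")
#' tr <- simulate_variant(v, p, default_initial_state(), seq(0, 160, by = 10))
#' head(tr)
#' @export
simulate_variant <- function(variant, params, init, times,
                             solver = solver_config(), engine = c("C", "R")) {
  engine <- match.arg(engine)
  variant <- as_ferm_variant(variant)
  init <- as.numeric(init)
  if (length(init) != 8) stop("init must have 8 components")
  if (any(!is.finite(init)) || any(init < 0)) stop("init must be finite and non-negative")
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing with at least 2 entries")
  full <- expand_params(params, variant)
  flags <- as.numeric(variant$mechanisms)
  names(init) <- ferm_state_names()

  out <- if (engine == "C") {
    parms <- c(unname(full), flags)
    tryCatch(
      deSolve::ode(y = init, times = times, func = "cocoaferm_derivs",
                   parms = parms, dllname = "cocoaferm",
                   initfunc = "cocoaferm_initmod",
                   method = solver$method, rtol = solver$rtol,
                   atol = solver$atol, maxsteps = solver$max_steps),
      warning = function(w) simulation_error(times, conditionMessage(w)),
      error = function(e) simulation_error(times, conditionMessage(e)))
  } else {
    rhs <- function(t, y, parms) list(ferm_rhs(pmax(y, 0), full, variant$mechanisms))
    tryCatch(
      deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                   method = solver$method, rtol = solver$rtol,
                   atol = solver$atol, maxsteps = solver$max_steps),
      warning = function(w) simulation_error(times, conditionMessage(w)),
      error = function(e) simulation_error(times, conditionMessage(e)))
  }

  out <- unclass(out)
  if (nrow(out) < length(times) || any(!is.finite(out)))
    simulation_error(times[min(nrow(out) + 1, length(times))],
                     "integration did not reach all output times")
  states <- out[, -1, drop = FALSE]
  low <- states < 0
  if (any(states[low] < -solver$atol)) {
    bad <- which(apply(states < -solver$atol, 1, any))[1]
    simulation_error(times[bad], "state undershoot beyond tolerance")
  }
  states[low] <- 0
  res <- cbind(time = times, states)
  colnames(res) <- c("time", ferm_state_names())
  res
}

simulation_error <- function(time, msg) {
  time <- time[1]
  stop(structure(class = c("cocoaferm_simulation_error", "error", "condition"),
                 list(message = paste0("simulation failed at t = ", time, ": ", msg),
                      call = sys.call(-1), time = time)))
}

#' Fixed-step classical Runge-Kutta integration (reference oracle)
#'
#' A deliberately simple fixed-step RK4 integrator over the reference R
#' right-hand side, used to validate the adaptive solver. States are clamped
#' to zero at rate evaluation, matching the adaptive path's boundary
#' handling.
#'
#' @inheritParams simulate_variant
#' @param h step size in hours.
#' @return Trajectory matrix in the same layout as
#'   \code{\link{simulate_variant}}.
#' @export
simulate_rk4_fixed <- function(variant, params, init, times, h = 0.001) {
  variant <- as_ferm_variant(variant)
  full <- expand_params(params, variant)
  ms <- variant$mechanisms
  f <- function(y) unname(ferm_rhs(pmax(y, 0), full, ms))
  y <- as.numeric(init)
  out <- matrix(NA_real_, length(times), 8)
  out[1, ] <- y
  t <- times[1]
  for (i in 2:length(times)) {
    target <- times[i]
    while (t < target - 1e-12) {
      step <- min(h, target - t)
      k1 <- f(y)
      k2 <- f(y + step / 2 * k1)
      k3 <- f(y + step / 2 * k2)
      k4 <- f(y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- y
  }
  out[out < 0] <- 0
  res <- cbind(time = times, out)
  colnames(res) <- c("time", ferm_state_names())
  res
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory matrix from \code{\link{simulate_variant}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
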