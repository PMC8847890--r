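#' Prior specification for kinetic parameters and noise
#'
#' Every kinetic parameter (in scaled units) gets an independent weakly
#' informative Normal(0.5, 0.3) prior truncated to the positive reals; the
#' shared observation noise sd gets a half-Cauchy(0, 1). Fits run under any
#' other prior are never labelled successful (success is defined for the
#' default prior only).
#'
#' @param theta_mean,theta_sd mean and sd of the (untruncated) Normal prior.
#' @param sigma_scale scale of the (untruncated) Cauchy prior for sigma.
#' @return An object of class \code{"prior_spec"} with a \code{default} flag.
#' @export
prior_spec <- function(theta_mean = 0.5, theta_sd = 0.3, sigma_scale = 1) {
  stopifnot(theta_sd > 0, sigma_scale > 0)
  default <- isTRUE(all.equal(c(theta_mean, theta_sd, sigma_scale),
                              c(0.5, 0.3, 1)))
  structure(list(theta_mean = theta_mean, theta_sd = theta_sd,
                 sigma_scale = sigma_scale, default = default),
            class = "prior_spec")
}

#' Joint log prior density
#'
#' Sum of positive-truncated Normal log densities over the kinetic
#' parameters plus the positive-truncated Cauchy log density of the noise
#' sd, each including its truncation normaliser. Returns \code{-Inf} outside
#' the support.
#'
#' @param theta positive parameter vector (scaled units).
#' @param sigma positive noise sd.
#' @param prior a \code{\link{prior_spec}}.
#' @return Scalar log density.
#' @export
log_prior <- function(theta, sigma, prior = prior_spec()) {
  if (any(theta <= 0) || sigma <= 0) return(-Inf)
  ltheta <- sum(stats::dnorm(theta, prior$theta_mean, prior$theta_sd, log = TRUE)) -
    length(theta) * stats::pnorm(0, prior$theta_mean, prior$theta_sd,
                                 lower.tail = FALSE, log.p = TRUE)
  lsigma <- stats::dcauchy(sigma, 0, prior$sigma_scale, log = TRUE) + log(2)
  ltheta + lsigma
}

#' Sampler configuration
#'
#' Defaults mirror the estimation protocol used throughout the package:
#' four chains of 3000 iterations with 1000 warm-up, and a single rerun at
#' doubled length (6000 iterations, 2000 warm-up) when effective sample
#' sizes fail the convergence check.
#'
#' @param chains number of chains (>= 2, required for split R-hat).
#' @param iter total iterations per chain (> warmup).
#' @param warmup warm-up (adaptation) iterations per chain.
#' @param thin keep every thin-th post-warm-up iteration (the random-walk
#'   kernel is autocorrelated; thinning trades wall-clock for per-draw
#'   information when a target number of retained draws is wanted).
#' @param temps inverse-temperature ladder for parallel tempering within
#'   each chain (first entry must be 1, descending); hotter rungs flatten
#'   the likelihood and help traverse the curved, weakly identified ridges
#'   typical of saturation-kinetics posteriors. Length-1 disables
#'   tempering.
#' @param seed integer RNG seed.
#' @param rerun_on_ess_failure apply the doubling rerun policy once.
#' @return An object of class \code{"sampler_config"}.
#' @export
sampler_config <- function(chains = 4, iter = 3000, warmup = 1000, thin = 1,
                           temps = c(1, 0.35, 0.12, 0.04),
                           seed = 1, rerun_on_ess_failure = TRUE) {
  stopifnot(chains >= 2, iter > warmup, warmup >= 10, thin >= 1,
            temps[1] == 1, all(diff(temps) < 0), all(temps > 0))
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 temps = as.numeric(temps), seed = as.integer(seed),
                 rerun_on_ess_failure = isTRUE(rerun_on_ess_failure)),
            class = "sampler_config")
}

# Internal: fast likelihood engine bound to one (variant, dataset, solver).
# resid(theta) returns the signed residual vector (NULL on simulation
# failure); lik(theta, sigma) the Gaussian log likelihood built on it.
make_loglik <- function(variant, scaled, solver) {
  variant <- as_ferm_variant(variant)
  stopifnot(inherits(scaled, "ferm_scaled"))
  obs <- scaled$observations
  times <- scaled$times
  init <- obs[1, ]
  if (anyNA(init)) stop("first observation row must be complete")
  tab_names <- ferm_parameter_table()$name
  full_template <- stats::setNames(numeric(length(tab_names)), tab_names)
  active <- variant$parameter_names
  # series-major, time-minor observation order, missing entries skipped
  obs_t <- t(obs)                       # 8 x T, series-major when flattened
  keep <- which(!is.na(obs_t))
  y <- obs_t[keep]
  idx <- arrayInd(keep, dim(obs_t))
  obs_index <- data.frame(series = ferm_state_names()[idx[, 1]],
                          time = times[idx[, 2]])
  state_names <- ferm_state_names()

  flags <- as.numeric(variant$mechanisms)
  series0 <- as.integer(idx[, 1] - 1L)   # 0-based state index
  time0 <- as.integer(idx[, 2] - 1L)     # 0-based time index
  init_num <- as.numeric(init)

  resid <- function(theta, engine = "C") {
    if (engine == "C") {
      full <- full_template
      full[active] <- theta
      r <- .Call(ferm_resid_c, c(unname(full), flags), init_num,
                 as.numeric(times), y, series0, time0,
                 solver$rtol, solver$atol, as.numeric(solver$max_steps))
      return(r)   # NULL on integration failure
    }
    full <- full_template
    full[active] <- theta
    sim <- tryCatch(
      simulate_variant(variant, full, init, times, solver),
      cocoaferm_simulation_error = function(e) NULL,
      error = function(e) NULL)
    if (is.null(sim)) return(NULL)
    y - t(sim[, state_names])[keep]
  }
  lik <- function(theta, sigma) {
    r <- resid(theta)
    if (is.null(r)) return(list(total = -Inf, pointwise = NULL))
    pw <- stats::dnorm(r, 0, sigma, log = TRUE)
    list(total = sum(pw), pointwise = pw)
  }
  list(lik = lik, resid = resid, n_obs = length(y), obs_index = obs_index,
       init = init, full_template = full_template, active = active,
       flags = flags, series0 = series0, time0 = time0, times = times, y = y)
}

# Internal: multi-start penalized Levenberg-Marquardt search for posterior
# modes on the log-parameter scale, used to give every chain its own
# overdispersed high-probability starting point (the weakly identified
# ridges of saturation-kinetics posteriors host many near-equivalent local
# optima; seeding chains across them makes pooled credible intervals
# reflect ridge spread instead of a single basin). Deterministic given
# `seed`. Returns one solution per requested start (recycled if some
# starts fail), each with psi, sigma and a Gauss-Newton covariance.
find_modes <- function(eng, prior, n_params, seed, n_starts = 4) {
  local_rng(seed)
  obj <- function(psi, sig) {
    th <- exp(psi)
    r <- eng$resid(th)
    if (is.null(r)) return(rep(1e4, eng$n_obs + n_params))
    c(r / sig, (th - prior$theta_mean) / prior$theta_sd)
  }
  sols <- list()
  for (s in seq_len(max(n_starts, 2))) {
    psi <- if (s == 1) log(rep(prior$theta_mean, n_params)) else
      log(pmax(stats::rnorm(n_params, prior$theta_mean, prior$theta_sd), 0.02))
    sig <- 0.1
    ok <- TRUE
    for (round in 1:3) {
      fit <- tryCatch(
        minpack.lm::nls.lm(psi, fn = obj, sig = sig,
                           control = minpack.lm::nls.lm.control(maxiter = 120)),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      psi <- fit$par
      r <- eng$resid(exp(psi))
      if (is.null(r)) { ok <- FALSE; break }
      sig <- max(sqrt(mean(r^2)), 1e-4)
    }
    if (!ok) next
    cov <- tryCatch({
      h <- fit$hessian
      solve((h + t(h)) / 2 + diag(1e-6, n_params))
    }, error = function(e) NULL)
    if (is.null(cov)) cov <- diag(0.01, n_params)
    sols[[length(sols) + 1]] <- list(psi = psi, sigma = sig, cov = cov,
                                     ssr = mean(r^2))
  }
  if (!length(sols)) return(NULL)
  sols
}

#' Pointwise Gaussian log likelihood of a parameter vector
#'
#' Simulates the variant from the dataset's first (scaled) observation at
#' the observation times and scores every non-missing observation under a
#' Normal with the simulated value as mean and a single shared sd. The
#' pointwise vector is ordered series-major (all times of Glc, then Fru,
#' ...), skipping missing entries.
#'
#' @param theta named (or manifest-ordered) free parameters of the variant.
#' @param sigma shared observation noise sd (> 0).
#' @param variant model variant.
#' @param scaled a \code{\link{max_scale}}d dataset.
#' @param solver a \code{\link{solver_config}}.
#' @return List with \code{total} (scalar; \code{-Inf} on simulation
#'   failure) and \code{pointwise} (vector summing to \code{total}).
#' @export
log_likelihood <- function(theta, sigma, variant, scaled,
                           solver = solver_config()) {
  if (sigma <= 0) stop("sigma must be positive")
  variant <- as_ferm_variant(variant)
  if (is.null(names(theta))) names(theta) <- variant$parameter_names
  eng <- make_loglik(variant, scaled, solver)
  eng$lik(theta[variant$parameter_names], sigma)
}

#' Fit a model variant to a scaled dataset by MCMC
#'
#' Samples the posterior of the variant's kinetic parameters and the shared
#' noise sd under \code{\link{prior_spec}} truncated priors, using an
#' adaptive random-walk Metropolis sampler on the log-parameter scale
#' (global proposal covariance adapted during warm-up, frozen afterwards).
#' Simulation failures inside sampling are treated as log-posterior
#' \code{-Inf}. If bulk or tail ESS criteria fail, the sampler is rerun once
#' at doubled length before declaring non-convergence. Runs are
#' deterministic given the sampler seed.
#'
#' @param variant model variant (any form accepted by
#'   \code{\link{build_variant}}).
#' @param scaled a \code{\link{max_scale}}d dataset.
#' @param prior a \code{\link{prior_spec}}.
#' @param sampler a \code{\link{sampler_config}}.
#' @param solver a \code{\link{solver_config}}.
#' @return An object of class \code{"ferm_fit"}: post-warm-up \code{draws}
#'   (matrix with one column per parameter plus \code{sigma}),
#'   \code{chain_id}, \code{log_lik} (draws x observations pointwise
#'   matrix), \code{diagnostics} (per-parameter R-hat and ESS, mean
#'   ESS/N_draws ratio), \code{success} flag with \code{reasons},
#'   \code{summary} (posterior means and 95\% credible intervals), and
#'   provenance (\code{variant}, \code{scale_factors}, configs, seed).
#' @export
fit_variant <- function(variant, scaled, prior = prior_spec(),
                        sampler = sampler_config(), solver = solver_config()) {
  variant <- as_ferm_variant(variant)
  res <- run_mcmc(variant, scaled, prior, sampler, solver)
  verdict <- check_convergence(res)
  ess_fail <- any(c("bulk-ESS", "tail-ESS", "ESS ratio") %in% verdict$reasons)
  if (ess_fail && sampler$rerun_on_ess_failure) {
    sampler2 <- sampler
    sampler2$iter <- 2L * sampler$iter
    sampler2$warmup <- 2L * sampler$warmup
    sampler2$rerun_on_ess_failure <- FALSE
    res <- run_mcmc(variant, scaled, prior, sampler2, solver)
    res$rerun <- TRUE
    verdict <- check_convergence(res)
  }
  res$success <- verdict$success
  res$reasons <- verdict$reasons
  res
}

run_mcmc <- function(variant, scaled, prior, sampler, solver) {
  eng <- make_loglik(variant, scaled, solver)
  d <- variant$n_params
  par_names <- c(variant$parameter_names, "sigma")
  n_keep <- (sampler$iter - sampler$warmup) %/% sampler$thin
  draws <- matrix(NA_real_, n_keep * sampler$chains, d + 1L,
                  dimnames = list(NULL, par_names))
  chain_id <- integer(n_keep * sampler$chains)
  log_lik <- matrix(NA_real_, n_keep * sampler$chains, eng$n_obs)
  lp <- numeric(n_keep * sampler$chains)
  accept <- numeric(sampler$chains)
  n_obs <- eng$n_obs

  # posterior mode search shared by all chains (deterministic given seed);
  # one overdispersed starting solution per chain
  modes <- find_modes(eng, prior, d, sampler$seed, n_starts = sampler$chains)

  # The tempered DE-MCz kernel itself runs in compiled code (one call per
  # chain); the ladder tempers only the likelihood, so the hottest rung
  # explores the prior freely and feeds diversity down through swap moves.
  betas <- sampler$temps
  nt <- length(betas)
  parms_template <- c(unname(eng$full_template), eng$flags)
  active0 <- as.integer(match(eng$active, ferm_parameter_table()$name) - 1L)
  # keep modes whose fit quality is comparable to the best; a clearly worse
  # local optimum would pin its chain in a low-probability basin
  if (!is.null(modes)) {
    ssrs <- vapply(modes, function(m) m$ssr, numeric(1))
    modes <- modes[ssrs <= 2 * min(ssrs)]
  }

  for (ch in seq_len(sampler$chains)) {
    local_rng(sampler$seed + 1000003L * ch)
    mode <- if (is.null(modes)) NULL else
      modes[[(ch - 1L) %% length(modes) + 1L]]
    psi0 <- matrix(NA_real_, d, nt)
    sigma0 <- numeric(nt)
    if (!is.null(mode)) {
      for (t in seq_len(nt)) {
        psi0[, t] <- mode$psi + stats::rnorm(d, 0, 0.05)
        sigma0[t] <- mode$sigma * exp(stats::rnorm(1, 0, 0.1))
      }
      sd0 <- sqrt(pmax(diag(mode$cov), 1e-6))
    } else {
      for (t in seq_len(nt)) {
        repeat { th0 <- stats::rnorm(d, prior$theta_mean, prior$theta_sd)
                 if (all(th0 > 0)) break }
        psi0[, t] <- log(th0)
        sigma0[t] <- 0.2
      }
      sd0 <- rep(0.1, d)
    }
    out <- .Call(ferm_mcmc_c, parms_template, active0,
                 as.numeric(eng$init), as.numeric(eng$times), eng$y,
                 eng$series0, eng$time0,
                 c(solver$rtol, solver$atol, solver$max_steps),
                 c(prior$theta_mean, prior$theta_sd, prior$sigma_scale),
                 as.numeric(betas),
                 as.integer(c(sampler$iter, sampler$warmup, sampler$thin)),
                 psi0, sigma0, sd0)
    if (is.null(out)) stop("could not find a feasible starting point")
    rows <- (ch - 1L) * n_keep + seq_len(n_keep)
    draws[rows, ] <- out$draws
    chain_id[rows] <- ch
    log_lik[rows, ] <- out$log_lik
    lp[rows] <- out$lp
    accept[ch] <- out$accept
  }

  diag_tab <- compute_diagnostics(draws, chain_id, sampler$chains, n_keep)
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  summary <- data.frame(parameter = par_names,
                        mean = colMeans(draws),
                        ci_lower = qs[1, ], ci_upper = qs[2, ],
                        rhat = diag_tab$rhat,
                        ess_bulk = diag_tab$ess_bulk,
                        ess_tail = diag_tab$ess_tail,
                        row.names = NULL)
  structure(list(draws = draws, chain_id = chain_id, log_lik = log_lik,
                 log_posterior = lp,
                 diagnostics = list(table = diag_tab,
                                    mean_ess_ratio = mean(diag_tab$ess_bulk) /
                                      nrow(draws),
                                    accept_rate = accept),
                 summary = summary, variant = variant,
                 dataset_code = scaled$code,
                 scale_factors = scaled$scale_factors,
                 features = scaled$features,
                 obs_index = eng$obs_index, init_state = eng$init,
                 prior = prior, sampler = sampler, solver = solver,
                 seed = sampler$seed, rerun = FALSE,
                 success = NA, reasons = character(0)),
            class = "ferm_fit")
}

compute_diagnostics <- function(draws, chain_id, chains, n_keep) {
  per_chain <- function(v) matrix(v, nrow = n_keep, ncol = chains)
  stats_tab <- data.frame(parameter = colnames(draws),
                          rhat = NA_real_, ess_bulk = NA_real_,
                          ess_tail = NA_real_, row.names = NULL)
  for (j in seq_len(ncol(draws))) {
    m <- per_chain(draws[, j])
    stats_tab$rhat[j] <- rhat(m)
    stats_tab$ess_bulk[j] <- ess_bulk(m)
    stats_tab$ess_tail[j] <- ess_tail(m)
  }
  stats_tab
}

#' @export
print.ferm_fit <- function(x, ...) {
  cat("<ferm_fit>", x$variant$label, "on", x$dataset_code,
      "-", nrow(x$draws), "draws,",
      if (isTRUE(x$success)) "successful" else "NOT successful", "\n")
  if (length(x$reasons)) cat("  failed criteria:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Convergence verdict for a fit
#'
#' A fit is successful iff all of: max R-hat < 1.05, min bulk-ESS > 100,
#' min tail-ESS > 100, mean bulk-ESS over total post-warm-up draws strictly
#' above 0.125, and the default prior was used (a run needing distinct
#' priors does not count as a successful fit). Degenerate diagnostics (NA)
#' fail their criterion.
#'
#' @param fit a \code{"ferm_fit"}.
#' @return List with \code{success} (logical) and \code{reasons} (character
#'   vector naming every violated criterion).
#' @export
check_convergence <- function(fit) {
  tab <- fit$diagnostics$table
  reasons <- character(0)
  bad <- function(v, thr, cmp) any(!is.finite(v)) || cmp(v, thr)
  if (bad(tab$rhat, 1.05, function(v, t) max(v) >= t)) reasons <- c(reasons, "R-hat")
  if (bad(tab$ess_bulk, 100, function(v, t) min(v) <= t)) reasons <- c(reasons, "bulk-ESS")
  if (bad(tab$ess_tail, 100, function(v, t) min(v) <= t)) reasons <- c(reasons, "tail-ESS")
  ratio <- fit$diagnostics$mean_ess_ratio
  if (!is.finite(ratio) || ratio <= 0.125) reasons <- c(reasons, "ESS ratio")
  if (!isTRUE(fit$prior$default)) reasons <- c(reasons, "non-default prior")
  list(success = length(reasons) == 0, reasons = reasons)
}

#' Posterior predictive trajectories
#'
#' Simulates the fitted variant for each retained draw (optionally a
#' deterministic thinned subset) and summarises, per series and output
#' time, the pointwise median and central 95\% interval. With
#' \code{include_noise = TRUE} the observation noise sd of each draw is
#' added, giving a predictive band for new observations.
#'
#' @param fit a successful \code{"ferm_fit"}.
#' @param times output times (default: the fitted observation times).
#' @param max_draws cap on the number of simulated draws (thinned evenly).
#' @param include_noise include Gaussian observation noise in the band.
#' @return List of matrices \code{median}, \code{lower}, \code{upper}
#'   (times x 8 series), plus \code{times} and \code{n_failed} (draws
#'   dropped due to simulation failure).
#' @export
posterior_predict <- function(fit, times = NULL, max_draws = 400,
                              include_noise = FALSE) {
  stopifnot(inherits(fit, "ferm_fit"))
  if (is.null(times)) {
    # reconstruct observation times from the stored pointwise index
    times <- sort(unique(fit$obs_index$time))
  }
  variant <- fit$variant
  idx <- unique(round(seq(1, nrow(fit$draws),
                          length.out = min(max_draws, nrow(fit$draws)))))
  init <- fit$init_state
  sims <- array(NA_real_, c(length(idx), length(times), 8))
  n_failed <- 0
  local_rng(fit$seed + 777L)
  for (k in seq_along(idx)) {
    theta <- fit$draws[idx[k], seq_len(variant$n_params)]
    sim <- tryCatch(
      simulate_variant(variant, theta, init, times, fit$solver),
      error = function(e) NULL)
    if (is.null(sim)) { n_failed <- n_failed + 1; next }
    s <- sim[, ferm_state_names()]
    if (include_noise)
      s <- s + stats::rnorm(length(s), 0, fit$draws[idx[k], "sigma"])
    sims[k, , ] <- s
  }
  if (all(!is.finite(sims))) stop("all posterior draws failed to simulate")
  qfun <- function(p) apply(sims, c(2, 3), stats::quantile, probs = p, na.rm = TRUE)
  med <- qfun(0.5); lo <- qfun(0.025); up <- qfun(0.975)
  dimnames(med) <- dimnames(lo) <- dimnames(up) <-
    list(NULL, ferm_state_names())
  list(times = times, median = med, lower = lo, upper = up,
       n_failed = n_failed)
}
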