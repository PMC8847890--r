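#' Default generating parameters for synthetic trials
#'
#' A hand-tuned parameter preset in scaled units (all values inside the
#' support of the fitting priors) that reproduces the canonical three-phase
#' microbial succession over a 160 h fermentation: an early yeast bloom on
#' glucose and fructose with ethanol accumulation, a LAB phase producing
#' lactic and acetic acid, and a late AAB phase oxidising ethanol and
#' lactate into acetate while product toxicity drives all three populations
#' down. Mechanism parameters (all 43 entries are populated) keep the same
#' qualitative picture when the corresponding mechanism is switched on.
#'
#' @param variant variant whose free-parameter subset to return; use
#'   \code{"MI(1,2,3,4,5)"} for the full vector.
#' @return Named vector of the variant's free parameters (scaled units).
#' @export
default_true_params <- function(variant = "MI(0)") {
  variant <- as_ferm_variant(variant)
  full <- c(
    # maximum specific growth rates (h^-1)
    mu_Y_Glc = 0.12, mu_Y_Fru = 0.10, mu_Y_LA = 0.03,
    mu_LAB_Glc = 0.19, mu_LAB_Fru = 0.07,
    mu_AAB_EtOH = 0.08, mu_AAB_LA = 0.08, mu_AAB_Ac = 0.03,
    # substrate saturation constants (scaled substrate units)
    K_Y_Glc = 0.5, K_Y_Fru = 0.5, K_Y_LA = 0.6,
    K_LAB_Glc = 0.6, K_LAB_Fru = 0.6,
    K_AAB_EtOH = 0.6, K_AAB_LA = 0.7, K_AAB_Ac = 0.6,
    # mortality rate constants
    k_Y = 0.25, k_LAB = 0.28, k_AAB = 0.45,
    # yield coefficients
    Y_Glc_Y = 0.55, Y_Glc_LAB = 0.5, Y_Fru_Y = 0.55, Y_Fru_LAB = 0.45,
    Y_EtOH_Y_Glc = 0.45, Y_EtOH_Y_Fru = 0.4, Y_EtOH_Y_LA = 0.3,
    Y_EtOH_LAB_Glc = 0.2, Y_EtOH_LAB_Fru = 0.2, Y_EtOH_AAB = 0.4,
    Y_LA_LAB_Glc = 1.1, Y_LA_LAB_Fru = 0.4, Y_LA_AAB = 0.3, Y_LA_Y = 0.3,
    Y_Ac_LAB_Glc = 0.45, Y_Ac_LAB_Fru = 0.2,
    Y_Ac_AAB_EtOH = 0.5, Y_Ac_AAB_LA = 0.35,
    Y_Ac_Y_Glc = 0.1, Y_Ac_Y_Fru = 0.1, Y_Ac_AAB = 0.3,
    # abiotic decay rates (h^-1)
    b_EtOH = 0.01, b_LA = 0.006, b_Ac = 0.006)
  full[variant$parameter_names]
}

#' @rdname default_true_params
#' @return \code{default_initial_state}: scaled initial state with sugars
#'   near their maxima, trace products and small microbial inocula.
#' @export
default_initial_state <- function() {
  c(Glc = 1, Fru = 1, EtOH = 0.001, LA = 0.001, Ac = 0.001,
    Y = 0.05, LAB = 0.02, AAB = 0.01)
}

#' @rdname default_true_params
#' @return \code{default_scale_factors}: representative raw-unit maxima used
#'   to emit synthetic observations in original units (mg per g pulp).
#' @export
default_scale_factors <- function() {
  c(Glc = 60, Fru = 55, EtOH = 20, LA = 6, Ac = 8,
    Y = 0.08, LAB = 0.05, AAB = 0.03)
}

#' Configuration for the synthetic trial generator
#'
#' @param variant generating model variant (label, indices or
#'   \code{ferm_variant}).
#' @param true_params named generating parameters in scaled units; defaults
#'   to \code{\link{default_true_params}} for the variant.
#' @param init scaled initial state.
#' @param n_timepoints number of observation times, 6..17 (the sampling-rate
#'   range of published trials).
#' @param horizon trial duration in hours.
#' @param noise_sd observation noise standard deviation in scaled units.
#' @param seed integer RNG seed.
#' @param scale_factors raw-unit series maxima used to emit observations in
#'   original units.
#' @param features trial metadata labels (country, cultivar, method,
#'   turning, controlled_temperature).
#' @param grid \code{"jittered"} (default) or \code{"uniform"} observation
#'   grid; both start at t = 0.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(variant = "MI(0)",
                             true_params = NULL,
                             init = default_initial_state(),
                             n_timepoints = 17,
                             horizon = 160,
                             noise_sd = 0.03,
                             seed = 1,
                             scale_factors = default_scale_factors(),
                             features = list(),
                             grid = c("jittered", "uniform")) {
  variant <- as_ferm_variant(variant)
  if (is.null(true_params)) true_params <- default_true_params(variant)
  if (n_timepoints < 6 || n_timepoints > 17)
    stop("n_timepoints must lie in 6..17")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (any(true_params <= 0)) stop("true_params must be positive")
  structure(list(variant = variant, true_params = true_params, init = init,
                 n_timepoints = as.integer(n_timepoints), horizon = horizon,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 scale_factors = scale_factors, features = features,
                 grid = match.arg(grid)),
            class = "generator_config")
}

#' Generate one synthetic fermentation trial
#'
#' Simulates the configured variant at \code{n_timepoints} observation times
#' (t = 0 plus a uniform or jittered-uniform grid over the horizon),
#' max-scales the noiseless trajectory so every series peaks at 1 (the space
#' in which the Gaussian observation model operates when real data are
#' max-scaled for fitting), adds independent Normal(0, \code{noise_sd})
#' noise there (negative values clipped to zero), and emits raw-unit
#' observations by multiplying with the configured series maxima.
#'
#' The returned dataset carries a \code{ground_truth} attribute with the
#' generating variant, the generating parameters in three unit systems
#' (\code{true_params}: generator space; \code{true_params_unit}: the
#' unit-peak space a fit of the noiseless data would estimate in;
#' \code{true_params_raw}: original units, the reference for recovery
#' checks), the noise level, the noiseless trajectory and the scale
#' factors -- sufficient to run parameter-recovery experiments with no
#' other inputs.
#'
#' @param config a \code{\link{generator_config}}.
#' @param solver a \code{\link{solver_config}}.
#' @return A \code{\link{fermentation_dataset}} with attribute
#'   \code{ground_truth}.
#' @examples
#' d <- generate_trial(generator_config(seed = 42))
#' attr(d, "ground_truth")$variant$label
#' @export
generate_trial <- function(config, solver = solver_config()) {
  stopifnot(inherits(config, "generator_config"))
  rng <- local_rng(config$seed)
  n <- config$n_timepoints
  times <- seq(0, config$horizon, length.out = n)
  if (config$grid == "jittered" && n > 2) {
    gap <- config$horizon / (n - 1)
    times[2:(n - 1)] <- times[2:(n - 1)] + stats::runif(n - 2, -0.3, 0.3) * gap
    times <- sort(times)
  }
  traj <- simulate_variant(config$variant, config$true_params, config$init,
                           times, solver)
  clean <- traj[, ferm_state_names()]
  peak <- apply(clean, 2, max)
  if (any(peak <= 0)) stop("a simulated series is identically zero; adjust the configuration")
  unit <- sweep(clean, 2, peak, "/")
  noisy <- unit + stats::rnorm(length(unit), 0, config$noise_sd)
  noisy[noisy < 0] <- 0
  # the inference scheme conditions on the first observation as the exact
  # initial state, so the generator emits t = 0 noise-free for coherence
  noisy[1, ] <- unit[1, ]
  sf <- config$scale_factors[ferm_state_names()]
  raw <- sweep(noisy, 2, sf, "*")
  code <- sprintf("syn_%s_s%d", gsub("[(),]", "", config$variant$label),
                  config$seed)
  ds <- fermentation_dataset(times, raw, code = code,
                             features = config$features)
  params_unit <- rescale_params(config$true_params, peak, config$variant,
                                "to_scaled")
  params_raw <- rescale_params(params_unit, sf, config$variant, "to_original")
  attr(ds, "ground_truth") <- list(
    variant = config$variant, true_params = config$true_params,
    true_params_unit = params_unit, true_params_raw = params_raw,
    peak_factors = peak, init = config$init, noise_sd = config$noise_sd,
    trajectory = traj, scale_factors = sf, seed = config$seed)
  ds
}

#' Generate a labelled cohort of synthetic trials
#'
#' Builds \code{n_per_class} trials for each class, applying the class's
#' multiplicative parameter offsets to the base generating parameters and
#' attaching the class label to the requested metadata feature. Seeds are
#' derived deterministically from the base seed.
#'
#' @param base a \code{\link{generator_config}} shared by all classes.
#' @param classes named list: class label -> named vector of multiplicative
#'   parameter offsets (e.g. \code{c(mu_LAB_Glc = 1.5)} for +50\%); an empty
#'   vector means no shift.
#' @param n_per_class trials per class.
#' @param feature which metadata field carries the class label.
#' @return An object of class \code{"ferm_cohort"}: list with
#'   \code{datasets} (list of \code{ferm_dataset}) and \code{classes}
#'   (character vector of labels, one per dataset).
#' @export
generate_cohort <- function(base, classes, n_per_class = 3,
                            feature = "cultivar") {
  stopifnot(inherits(base, "generator_config"), length(classes) >= 1,
            !is.null(names(classes)))
  datasets <- list()
  labels <- character(0)
  idx <- 0L
  for (cl in names(classes)) {
    offs <- classes[[cl]]
    pars <- base$true_params
    if (length(offs)) {
      if (!all(names(offs) %in% names(pars)))
        stop("offset names must be generating parameters of the base variant")
      pars[names(offs)] <- pars[names(offs)] * offs
      if (any(pars <= 0)) stop("offsets must keep parameters positive")
    }
    for (r in seq_len(n_per_class)) {
      idx <- idx + 1L
      cfg <- base
      cfg$true_params <- pars
      cfg$seed <- base$seed + 1000L * idx
      cfg$features[[feature]] <- cl
      ds <- generate_trial(cfg)
      ds$code <- sprintf("%s_%s_%d", ds$code, cl, r)
      datasets[[idx]] <- ds
      labels[idx] <- cl
    }
  }
  structure(list(datasets = datasets, classes = labels, feature = feature),
            class = "ferm_cohort")
}
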