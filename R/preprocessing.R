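#' Convert microbial counts to biomass concentration
#'
#' Population counts reported as log10 colony-forming units per gram of pulp
#' are converted to mg of microbial group per g of pulp, the unit in which
#' kinetic constants of single-strain growth studies are reported:
#' \code{mass = cell_mass * 10^log10_cfu}.
#'
#' The per-cell mass factor is configurable per microbial group; the default
#' of 1e-8 mg per CFU is a typical order of magnitude for single microbial
#' cells. Because every series is subsequently max-scaled, the factor cancels
#' in fitting and only affects reporting in original units.
#'
#' @param log10_cfu numeric, log10(CFU per g pulp).
#' @param cell_mass mass per CFU in mg (> 0).
#' @return Biomass concentration in mg per g pulp.
#' @examples
#' cfu_to_mass(6, 1e-8)   # 0.01 mg/g
#' @export
cfu_to_mass <- function(log10_cfu, cell_mass = 1e-8) {
  if (!is.numeric(cell_mass) || cell_mass <= 0) stop("cell_mass must be positive")
  if (any(!is.finite(log10_cfu))) stop("log10_cfu must be finite")
  cell_mass * 10^log10_cfu
}

#' Max-scale a fermentation dataset
#'
#' Divides each of the eight series by its own maximum (ignoring missing
#' values), mapping every series into [0, 1] with maximum exactly 1. This
#' regularization puts all parameters of the kinetic models on a common
#' order of magnitude for fitting.
#'
#' @param dataset a \code{\link{fermentation_dataset}}.
#' @return An object of class \code{"ferm_scaled"}: list with
#'   \code{observations} (scaled T x 8 matrix), \code{scale_factors}
#'   (named 8-vector of the original maxima), \code{times}, \code{code},
#'   \code{features} and \code{dataset} (the source object).
#' @export
max_scale <- function(dataset) {
  stopifnot(inherits(dataset, "ferm_dataset"))
  obs <- dataset$observations
  fac <- apply(obs, 2, max, na.rm = TRUE)
  if (any(!is.finite(fac)) || any(fac <= 0))
    stop("every series needs a positive, finite maximum to be scaled")
  scaled <- sweep(obs, 2, fac, "/")
  structure(list(observations = scaled, scale_factors = fac,
                 times = dataset$times, code = dataset$code,
                 features = dataset$features, dataset = dataset),
            class = "ferm_scaled")
}

#' @rdname max_scale
#' @param scaled a \code{"ferm_scaled"} object.
#' @return \code{unscale}: the raw-unit observation matrix.
#' @export
unscale <- function(scaled) {
  stopifnot(inherits(scaled, "ferm_scaled"))
  sweep(scaled$observations, 2, scaled$scale_factors, "*")
}

#' @export
print.ferm_scaled <- function(x, ...) {
  cat("<ferm_scaled>", x$code, "- per-series maxima:\n")
  print(signif(x$scale_factors, 4))
  invisible(x)
}

#' Rescale parameter estimates between scaled and original units
#'
#' Fitting happens on max-scaled series; estimates are mapped back to
#' original units by the dimensional-analysis transformations that make the
#' scaled and raw dynamics exactly equivalent: maximum growth rates and
#' decay rates are unit-invariant; a Monod saturation constant is multiplied
#' by its substrate's maximum (the Contois constant by the LA-to-AAB maxima
#' ratio); a yield coefficient of metabolite a per microbial group b is
#' multiplied by max(a)/max(b); a mortality constant is divided by its toxic
#' product's maximum raised to the kinetic order (1 for yeast/LAB, 2 for
#' AAB). \code{direction = "to_scaled"} applies the exact inverse.
#'
#' @param params named vector of (at least) the variant's free parameters.
#' @param scale_factors named 8-vector of series maxima (from
#'   \code{\link{max_scale}}).
#' @param variant the fitted variant (any form accepted by
#'   \code{\link{build_variant}}).
#' @param direction \code{"to_original"} (default) or \code{"to_scaled"}.
#' @return Named vector of the variant's free parameters in target units.
#' @export
rescale_params <- function(params, scale_factors, variant,
                           direction = c("to_original", "to_scaled")) {
  direction <- match.arg(direction)
  variant <- as_ferm_variant(variant)
  nm <- ferm_state_names()
  if (is.null(names(scale_factors)) && length(scale_factors) == 8)
    names(scale_factors) <- nm
  if (!all(nm %in% names(scale_factors)) || any(scale_factors <= 0))
    stop("scale_factors must be positive and named by the 8 series")
  tab <- ferm_parameter_table()
  tab <- tab[match(variant$parameter_names, tab$name), ]
  if (is.null(names(params)))
    names(params) <- variant$parameter_names
  out <- params[variant$parameter_names]
  mult <- vapply(seq_len(nrow(tab)), function(i) {
    num <- strsplit(tab$scale_num[i], ",")[[1]]
    den <- strsplit(tab$scale_den[i], ",")[[1]]
    prod(scale_factors[num]) / prod(scale_factors[den])
  }, numeric(1))
  if (direction == "to_scaled") mult <- 1 / mult
  out * mult
}
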