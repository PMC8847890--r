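#' Elementary kinetic rate laws
#'
#' The building blocks of all model variants: Monod and Contois growth
#' kinetics, Chick-Watson product-dependent mortality, and first-order
#' abiotic decay. All rates are non-negative for non-negative arguments.
#'
#' @param mu_max maximum specific growth rate (h^-1)
#' @param K substrate saturation constant (substrate units for Monod;
#'   dimensionless substrate-per-biomass ratio for Contois)
#' @param S substrate concentration
#' @param X biomass concentration
#' @return Growth rate \code{mu_max * S / (S + K) * X} (Monod) or
#'   \code{mu_max * S / (S + K * X) * X} (Contois); 0 when S (or X) is 0.
#' @examples
#' monod_rate(0.4, 2, 3, 1.5)    # 0.36
#' contois_rate(0.5, 2, 4, 1)    # 1/3
#' @export
monod_rate <- function(mu_max, K, S, X) {
  check_nonneg(mu_max = mu_max, K = K, S = S, X = X)
  ifelse(S == 0, 0, mu_max * S / (S + K) * X)
}

#' @rdname monod_rate
#' @export
contois_rate <- function(mu_max, K, S, X) {
  check_nonneg(mu_max = mu_max, K = K, S = S, X = X)
  ifelse(S == 0 | X == 0, 0, mu_max * S / (S + K * X) * X)
}

#' @rdname monod_rate
#' @param k mortality rate constant
#' @param P concentration of the toxic product driving mortality
#' @param order exponent of the product term: 1 for yeast and LAB mortality
#'   (second-order kinetics overall), 2 for AAB mortality (third-order)
#' @export
mortality_rate <- function(k, X, P, order = 1) {
  if (!order %in% c(1, 2)) stop("mortality order must be 1 or 2")
  check_nonneg(k = k, X = X, P = P)
  k * X * P^order
}

#' @rdname monod_rate
#' @param b first-order decay rate (h^-1)
#' @param M metabolite concentration
#' @export
decay_rate <- function(b, M) {
  check_nonneg(b = b, M = M)
  b * M
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || anyNA(v)) stop("argument '", nm, "' must be numeric and non-missing")
    if (any(v < 0)) stop("argument '", nm, "' must be non-negative")
  }
  invisible(NULL)
}

#' Right-hand side of the fermentation ODE system
#'
#' Time derivative of the eight state variables (Glc, Fru, EtOH, LA, Ac, Y,
#' LAB, AAB) under a given mechanism set. The baseline couples five growth
#' rates (v1, v2: yeast on Glc/Fru; v3: LAB on Glc; v4: AAB on EtOH; v5:
#' Contois, AAB on LA) and three mortality rates (v6..v8) through yield
#' coefficients. Mechanisms add: M1 linear decay of EtOH/LA/Ac; M2 the LAB
#' growth rate v9 on Fru plus EtOH/LA/Ac production by LAB (EtOH from Glc
#' routed through v3); M3 Ac production tied to yeast growth v1/v2; M4 the
#' yeast growth rate v10 on LA producing EtOH; M5 the AAB growth rate v11 on
#' Ac. Rates of inactive mechanisms are identically zero.
#'
#' This is the reference R implementation; \code{\link{simulate_variant}}
#' uses a compiled equivalent for speed.
#'
#' @param state numeric vector of the 8 states (canonical order, or named).
#' @param params full 43-entry named parameter vector (see
#'   \code{\link{expand_params}}); entries of inactive mechanisms are ignored.
#' @param mechanisms a \code{\link{mechanism_set}} or coercible.
#' @return Named numeric vector of the 8 time derivatives.
#' @export
ferm_rhs <- function(state, params, mechanisms = integer(0)) {
  ms <- mechanism_set(mechanisms)
  s <- as.numeric(state)
  if (length(s) != 8) stop("state must have 8 components")
  if (any(s < 0)) stop("state must be non-negative")
  names(s) <- ferm_state_names()
  p <- params
  m <- as.numeric(ms)  # 0/1 flags m1..m5

  v1  <- monod_rate(p[["mu_Y_Glc"]],    p[["K_Y_Glc"]],    s[["Glc"]],  s[["Y"]])
  v2  <- monod_rate(p[["mu_Y_Fru"]],    p[["K_Y_Fru"]],    s[["Fru"]],  s[["Y"]])
  v3  <- monod_rate(p[["mu_LAB_Glc"]],  p[["K_LAB_Glc"]],  s[["Glc"]],  s[["LAB"]])
  v4  <- monod_rate(p[["mu_AAB_EtOH"]], p[["K_AAB_EtOH"]], s[["EtOH"]], s[["AAB"]])
  v5  <- contois_rate(p[["mu_AAB_LA"]], p[["K_AAB_LA"]],   s[["LA"]],   s[["AAB"]])
  v6  <- mortality_rate(p[["k_Y"]],   s[["Y"]],   s[["EtOH"]], 1)
  v7  <- mortality_rate(p[["k_LAB"]], s[["LAB"]], s[["LA"]],   1)
  v8  <- mortality_rate(p[["k_AAB"]], s[["AAB"]], s[["Ac"]],   2)
  v9  <- m[2] * monod_rate(p[["mu_LAB_Fru"]], p[["K_LAB_Fru"]], s[["Fru"]], s[["LAB"]])
  v10 <- m[4] * monod_rate(p[["mu_Y_LA"]],    p[["K_Y_LA"]],    s[["LA"]],  s[["Y"]])
  v11 <- m[5] * monod_rate(p[["mu_AAB_Ac"]],  p[["K_AAB_Ac"]],  s[["Ac"]],  s[["AAB"]])
  d1  <- m[1] * decay_rate(p[["b_EtOH"]], s[["EtOH"]])
  d2  <- m[1] * decay_rate(p[["b_LA"]],   s[["LA"]])
  d3  <- m[1] * decay_rate(p[["b_Ac"]],   s[["Ac"]])

  c(Glc  = -p[["Y_Glc_Y"]] * v1 - p[["Y_Glc_LAB"]] * v3,
    Fru  = -p[["Y_Fru_Y"]] * v2 - m[2] * p[["Y_Fru_LAB"]] * v9,
    EtOH = p[["Y_EtOH_Y_Glc"]] * v1 + p[["Y_EtOH_Y_Fru"]] * v2 -
           p[["Y_EtOH_AAB"]] * v4 +
           m[2] * (p[["Y_EtOH_LAB_Glc"]] * v3 + p[["Y_EtOH_LAB_Fru"]] * v9) +
           m[4] * p[["Y_EtOH_Y_LA"]] * v10 - d1,
    LA   = p[["Y_LA_LAB_Glc"]] * v3 - p[["Y_LA_AAB"]] * v5 +
           m[2] * p[["Y_LA_LAB_Fru"]] * v9 - m[4] * p[["Y_LA_Y"]] * v10 - d2,
    Ac   = p[["Y_Ac_LAB_Glc"]] * v3 + p[["Y_Ac_AAB_EtOH"]] * v4 +
           p[["Y_Ac_AAB_LA"]] * v5 + m[2] * p[["Y_Ac_LAB_Fru"]] * v9 +
           m[3] * (p[["Y_Ac_Y_Glc"]] * v1 + p[["Y_Ac_Y_Fru"]] * v2) -
           m[5] * p[["Y_Ac_AAB"]] * v11 - d3,
    Y    = v1 + v2 - v6 + m[4] * v10,
    LAB  = v3 - v7 + m[2] * v9,
    AAB  = v4 + v5 - v8 + m[5] * v11)
}
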