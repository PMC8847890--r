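#' The full kinetic parameter table
#'
#' Returns the 43-row manifest of kinetic parameters used across all model
#' variants: 8 maximum specific growth rates (h^-1), 8 substrate saturation
#' constants (substrate units), 3 mortality rate constants, 21 yield
#' coefficients and 3 first-order decay rates (h^-1). Each row is tagged with
#' the model component that introduces it: \code{"B"} for the baseline model
#' or \code{"M1"}..\code{"M5"} for one of the five optional mechanisms.
#'
#' Columns beyond \code{name}, \code{mechanism} and \code{type} encode the
#' metadata the rest of the package needs:
#' \describe{
#'   \item{microbe}{the microbial group the parameter belongs to
#'     (\code{"Y"}, \code{"LAB"}, \code{"AAB"}, or \code{NA} for the decay
#'     rates, which describe abiotic losses);}
#'   \item{scale_num, scale_den}{series names whose observed maxima multiply
#'     (numerator) or divide (denominator) a scaled estimate when it is
#'     rescaled to original units; comma-separated, \code{""} for none.}
#' }
#'
#' @return A data.frame with 43 rows and columns \code{name},
#'   \code{mechanism}, \code{type} (one of \code{"growth_rate"},
#'   \code{"saturation"}, \code{"mortality"}, \code{"yield"},
#'   \code{"decay"}), \code{microbe}, \code{scale_num}, \code{scale_den}.
#' @examples
#' tab <- ferm_parameter_table()
#' table(tab$mechanism)   # 24 baseline rows, 3+7+2+4+3 mechanism rows
#' @export
ferm_parameter_table <- function() {
  if (!is.null(.cocoaferm_cache$param_table)) return(.cocoaferm_cache$param_table)
  p <- function(name, mechanism, type, microbe, num, den)
    data.frame(name = name, mechanism = mechanism, type = type,
               microbe = microbe, scale_num = num, scale_den = den,
               stringsAsFactors = FALSE)
  rbind(
    # maximum specific growth rates: unit h^-1, invariant under max-scaling
    p("mu_Y_Glc",    "B",  "growth_rate", "Y",   "", ""),
    p("mu_Y_Fru",    "B",  "growth_rate", "Y",   "", ""),
    p("mu_Y_LA",     "M4", "growth_rate", "Y",   "", ""),
    p("mu_LAB_Glc",  "B",  "growth_rate", "LAB", "", ""),
    p("mu_LAB_Fru",  "M2", "growth_rate", "LAB", "", ""),
    p("mu_AAB_EtOH", "B",  "growth_rate", "AAB", "", ""),
    p("mu_AAB_LA",   "B",  "growth_rate", "AAB", "", ""),
    p("mu_AAB_Ac",   "M5", "growth_rate", "AAB", "", ""),
    # saturation constants: scale with their substrate's maximum; the
    # Contois constant K_AAB_LA is a LA-per-AAB ratio, hence the denominator
    p("K_Y_Glc",    "B",  "saturation", "Y",   "Glc",  ""),
    p("K_Y_Fru",    "B",  "saturation", "Y",   "Fru",  ""),
    p("K_Y_LA",     "M4", "saturation", "Y",   "LA",   ""),
    p("K_LAB_Glc",  "B",  "saturation", "LAB", "Glc",  ""),
    p("K_LAB_Fru",  "M2", "saturation", "LAB", "Fru",  ""),
    p("K_AAB_EtOH", "B",  "saturation", "AAB", "EtOH", ""),
    p("K_AAB_LA",   "B",  "saturation", "AAB", "LA",   "AAB"),
    p("K_AAB_Ac",   "M5", "saturation", "AAB", "Ac",   ""),
    # mortality constants: k X P^order, so original units carry 1/P_max^order
    p("k_Y",   "B", "mortality", "Y",   "", "EtOH"),
    p("k_LAB", "B", "mortality", "LAB", "", "LA"),
    p("k_AAB", "B", "mortality", "AAB", "", "Ac,Ac"),
    # yield coefficients: mg metabolite per mg microbial group grown
    p("Y_Glc_Y",        "B",  "yield", "Y",   "Glc",  "Y"),
    p("Y_Glc_LAB",      "B",  "yield", "LAB", "Glc",  "LAB"),
    p("Y_Fru_Y",        "B",  "yield", "Y",   "Fru",  "Y"),
    p("Y_Fru_LAB",      "M2", "yield", "LAB", "Fru",  "LAB"),
    p("Y_EtOH_Y_Glc",   "B",  "yield", "Y",   "EtOH", "Y"),
    p("Y_EtOH_Y_Fru",   "B",  "yield", "Y",   "EtOH", "Y"),
    p("Y_EtOH_Y_LA",    "M4", "yield", "Y",   "EtOH", "Y"),
    p("Y_EtOH_LAB_Glc", "M2", "yield", "LAB", "EtOH", "LAB"),
    p("Y_EtOH_LAB_Fru", "M2", "yield", "LAB", "EtOH", "LAB"),
    p("Y_EtOH_AAB",     "B",  "yield", "AAB", "EtOH", "AAB"),
    p("Y_LA_LAB_Glc",   "B",  "yield", "LAB", "LA",   "LAB"),
    p("Y_LA_LAB_Fru",   "M2", "yield", "LAB", "LA",   "LAB"),
    p("Y_LA_AAB",       "B",  "yield", "AAB", "LA",   "AAB"),
    p("Y_LA_Y",         "M4", "yield", "Y",   "LA",   "Y"),
    p("Y_Ac_LAB_Glc",   "B",  "yield", "LAB", "Ac",   "LAB"),
    p("Y_Ac_LAB_Fru",   "M2", "yield", "LAB", "Ac",   "LAB"),
    p("Y_Ac_AAB_EtOH",  "B",  "yield", "AAB", "Ac",   "AAB"),
    p("Y_Ac_AAB_LA",    "B",  "yield", "AAB", "Ac",   "AAB"),
    p("Y_Ac_Y_Glc",     "M3", "yield", "Y",   "Ac",   "Y"),
    p("Y_Ac_Y_Fru",     "M3", "yield", "Y",   "Ac",   "Y"),
    p("Y_Ac_AAB",       "M5", "yield", "AAB", "Ac",   "AAB"),
    # abiotic decay rates: h^-1, invariant under max-scaling
    p("b_EtOH", "M1", "decay", NA_character_, "", ""),
    p("b_LA",   "M1", "decay", NA_character_, "", ""),
    p("b_Ac",   "M1", "decay", NA_character_, "", "")
  ) -> tab
  .cocoaferm_cache$param_table <- tab
  tab
}

.cocoaferm_cache <- new.env(parent = emptyenv())

#' Names of the eight model state variables, in canonical order
#'
#' Metabolites glucose, fructose, ethanol, lactic acid and acetic acid,
#' followed by the microbial groups yeast, lactic acid bacteria and acetic
#' acid bacteria. All concentrations are mg per g pulp (or dimensionless
#' after max-scaling).
#'
#' @return Character vector of length 8.
#' @export
ferm_state_names <- function() {
  c("Glc", "Fru", "EtOH", "LA", "Ac", "Y", "LAB", "AAB")
}
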