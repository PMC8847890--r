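#' Define a set of model mechanisms
#'
#' A model variant is identified by the subset of the five optional
#' mechanisms it adds to the baseline fermentation model:
#' \describe{
#'   \item{M1}{abiotic decay of the products ethanol, lactic acid, acetic acid;}
#'   \item{M2}{consumption of fructose by LAB (with EtOH/LA/Ac production);}
#'   \item{M3}{production of acetic acid by yeast;}
#'   \item{M4}{consumption of lactic acid by yeast (producing EtOH);}
#'   \item{M5}{over-oxidation of acetic acid by AAB.}
#' }
#'
#' @param mechanisms integer vector of active mechanism indices (subset of
#'   1:5), or a label string such as \code{"MI(2,3)"}; \code{"MI(0)"},
#'   \code{integer(0)} and \code{0} all denote the baseline.
#' @return An object of class \code{"mechanism_set"}: logical vector of
#'   length 5 named \code{m1}..\code{m5}, with the canonical label as
#'   attribute.
#' @examples
#' mechanism_set(c(2, 3))
#' mechanism_set("MI(1,2,3,4,5)")
#' @export
mechanism_set <- function(mechanisms = integer(0)) {
  if (is.character(mechanisms)) mechanisms <- parse_variant_label(mechanisms)
  if (inherits(mechanisms, "mechanism_set")) return(mechanisms)
  m <- as.integer(mechanisms)
  m <- m[m != 0L]
  if (anyNA(m) || any(m < 1L | m > 5L))
    stop("mechanism indices must lie in 1..5 (0 alone denotes the baseline)")
  flags <- stats::setNames(1:5 %in% m, paste0("m", 1:5))
  structure(flags, label = make_variant_label(flags), class = "mechanism_set")
}

make_variant_label <- function(flags) {
  idx <- which(flags)
  if (length(idx) == 0) "MI(0)" else paste0("MI(", paste(idx, collapse = ","), ")")
}

#' @rdname mechanism_set
#' @param label a variant label string, e.g. \code{"MI(0)"} or \code{"MI(1,4)"}
#' @export
parse_variant_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  m <- regmatches(label, regexec("^MI\\(([0-5](,[1-5])*)\\)$", label))[[1]]
  if (length(m) == 0) stop("malformed variant label: ", label)
  idx <- as.integer(strsplit(m[2], ",")[[1]])
  if (identical(idx, 0L)) return(integer(0))
  if (any(idx == 0L) || any(duplicated(idx)) || is.unsorted(idx, strictly = TRUE))
    stop("variant label must list distinct mechanism indices in ascending order: ", label)
  idx
}

#' @export
print.mechanism_set <- function(x, ...) {
  cat("<mechanism_set>", attr(x, "label"), "\n")
  invisible(x)
}

#' Enumerate all 32 model variants
#'
#' All subsets of mechanisms M1..M5 in deterministic order: the baseline
#' first, then by number of active mechanisms, ties broken lexicographically
#' by mechanism indices.
#'
#' @return A list of 32 \code{mechanism_set} objects with unique labels.
#' @examples
#' length(enumerate_variants())           # 32
#' attr(enumerate_variants()[[1]], "label")  # "MI(0)"
#' @export
enumerate_variants <- function() {
  subsets <- list(integer(0))
  for (k in 1:5) {
    comb <- utils::combn(5L, k)
    subsets <- c(subsets, lapply(seq_len(ncol(comb)), function(j) comb[, j]))
  }
  lapply(subsets, mechanism_set)
}

#' Build a model variant
#'
#' Assembles the parameter manifest of a variant: the 24 baseline entries
#' plus the entries tagged with each active mechanism, kept in the canonical
#' row order of \code{\link{ferm_parameter_table}}. The baseline has 24 free
#' parameters; the five mechanisms add 3, 7, 2, 4 and 3 parameters
#' respectively, up to 43 in the full model.
#'
#' @param mechanisms a \code{\link{mechanism_set}}, label string, or index
#'   vector.
#' @return An object of class \code{"ferm_variant"} with elements
#'   \code{mechanisms}, \code{label}, \code{parameter_names} and
#'   \code{n_params}.
#' @examples
#' build_variant("MI(0)")$n_params        # 24
#' build_variant(c(1, 2, 3, 4, 5))$n_params  # 43
#' @export
build_variant <- function(mechanisms = integer(0)) {
  ms <- mechanism_set(mechanisms)
  tab <- ferm_parameter_table()
  tags <- c("B", paste0("M", which(ms)))
  active <- tab$name[tab$mechanism %in% tags]
  structure(
    list(mechanisms = ms,
         label = attr(ms, "label"),
         parameter_names = active,
         n_params = length(active)),
    class = "ferm_variant")
}

#' @export
print.ferm_variant <- function(x, ...) {
  cat("<ferm_variant>", x$label, "-", x$n_params, "free parameters\n")
  invisible(x)
}

as_ferm_variant <- function(x) {
  if (inherits(x, "ferm_variant")) x else build_variant(x)
}

#' Expand an active parameter vector to the full 43-entry vector
#'
#' Entries of inactive mechanisms are set to zero, which makes their rates
#' vanish identically in the shared right-hand side.
#'
#' @param params named numeric vector covering (at least) the variant's
#'   active parameters, or an unnamed vector in manifest order.
#' @param variant a \code{ferm_variant} (or anything coercible to one).
#' @return Named numeric vector of length 43 in canonical order.
#' @export
expand_params <- function(params, variant) {
  variant <- as_ferm_variant(variant)
  tab <- ferm_parameter_table()
  full <- stats::setNames(numeric(nrow(tab)), tab$name)
  if (is.null(names(params))) {
    if (length(params) != variant$n_params)
      stop("unnamed parameter vector must have length ", variant$n_params,
           " for variant ", variant$label)
    names(params) <- variant$parameter_names
  }
  missing <- setdiff(variant$parameter_names, names(params))
  if (length(missing))
    stop("missing parameters for ", variant$label, ": ",
         paste(missing, collapse = ", "))
  full[variant$parameter_names] <- params[variant$parameter_names]
  full
}
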