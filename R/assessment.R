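#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (elpd) of a
#' fitted model by leave-one-out importance sampling. For each observation
#' the raw importance ratios are the reciprocal pointwise likelihoods; the
#' largest \code{min(0.2 S, 3 sqrt(S))} ratios are replaced by quantiles of
#' a generalized Pareto distribution fitted to them (smoothing the heavy
#' tail), and smoothed weights are truncated at the raw maximum. The
#' per-observation Pareto shape k diagnoses estimator reliability (values
#' above ~0.7 are untrustworthy).
#'
#' @param log_lik draws x observations matrix of pointwise log likelihoods
#'   (e.g. the \code{log_lik} element of a \code{\link{fit_variant}} result).
#' @return An object of class \code{"ferm_loo"}: \code{elpd}, \code{se},
#'   \code{pointwise} (per-observation elpd), \code{pareto_k}
#'   (per-observation; NaN when the tail is degenerate).
#' @export
psis_loo <- function(log_lik) {
  log_lik <- as.matrix(log_lik)
  S <- nrow(log_lik); n <- ncol(log_lik)
  if (S < 100) stop("psis_loo needs at least 100 draws")
  if (any(!is.finite(log_lik))) stop("log_lik must be finite")
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (i in seq_len(n)) {
    lr <- -log_lik[, i]           # log raw importance ratios
    lr <- lr - max(lr)
    if (stats::sd(lr) == 0) {
      # constant predictive density: plain average, no tail to smooth
      pointwise[i] <- logsumexp(log_lik[, i]) - log(S)
      pareto_k[i] <- NaN
      next
    }
    ord <- order(lr)
    tail_idx <- ord[(S - M + 1):S]
    cutoff <- lr[ord[S - M]]
    exceed <- exp(lr[tail_idx]) - exp(cutoff)
    gpd <- gpd_fit(exceed[exceed > 0])
    pareto_k[i] <- gpd$k
    lw <- lr
    if (is.finite(gpd$k) && gpd$sigma > 0) {
      # replace tail by expected GPD order statistics, keep original order
      p <- (rank(lr[tail_idx], ties.method = "first") - 0.5) / M
      smoothed <- log(exp(cutoff) + gpd_quantile(p, gpd$k, gpd$sigma))
      lw[tail_idx] <- pmin(smoothed, 0)   # truncate at max raw ratio (=1)
    }
    pointwise[i] <- logsumexp(lw + log_lik[, i]) - logsumexp(lw)
  }
  structure(list(elpd = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k,
                 n_obs = n, n_draws = S),
            class = "ferm_loo")
}

#' @export
print.ferm_loo <- function(x, ...) {
  cat("<ferm_loo> elpd =", round(x$elpd, 2), "(se", paste0(round(x$se, 2), ")"),
      "over", x$n_obs, "observations; max Pareto k =",
      round(max(c(x$pareto_k, -Inf), na.rm = TRUE), 2), "\n")
  invisible(x)
}

# Generalized Pareto fit by the Zhang & Stephens (2009) profile posterior
# mean, with the usual weak prior shrinking k towards 0.5.
gpd_fit <- function(x) {
  x <- sort(x[is.finite(x) & x > 0])
  n <- length(x)
  if (n < 5) return(list(k = NaN, sigma = NaN))
  m <- 30 + floor(sqrt(n))
  q1 <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * q1)
  k_of <- function(th) -mean(log1p(-th * x))
  prof <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(prof - prof[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  sigma <- k / theta_hat
  k <- (n * k + 5) / (n + 10)   # regularising prior on k
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pseudo-BMA model weights from elpd values
#'
#' Softmax of the elpd estimates: \code{w_m = exp(elpd_m - max) / sum}.
#' Weights sum to one and are invariant under adding a constant to all
#' elpds. The Bayesian-bootstrap regularisation of pseudo-BMA+ is not
#' applied.
#'
#' @param loos list of \code{"ferm_loo"} objects (or a numeric vector of
#'   elpd values) for the competing models on one dataset.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' pseudo_bma_weights(c(0, log(3)))   # 0.25, 0.75
#' @export
pseudo_bma_weights <- function(loos) {
  if (length(loos) == 0) stop("at least one model is required")
  elpd <- if (is.numeric(loos)) loos else
    vapply(loos, function(l) l$elpd, numeric(1))
  w <- exp(elpd - max(elpd))
  w / sum(w)
}

#' Success matrix across variants and datasets
#'
#' @param fits nested list: \code{fits[[variant_label]][[dataset_code]]} of
#'   \code{"ferm_fit"} objects (entries may be missing / NULL for tasks not
#'   run).
#' @param variants,datasets character vectors fixing row/column order;
#'   default: the names found in \code{fits}.
#' @return Logical matrix (TRUE = successful fit, FALSE = unsuccessful,
#'   NA = not run), variants x datasets.
#' @export
success_matrix <- function(fits, variants = names(fits),
                           datasets = NULL) {
  if (is.null(datasets))
    datasets <- unique(unlist(lapply(fits, names)))
  m <- matrix(NA, length(variants), length(datasets),
              dimnames = list(variants, datasets))
  for (v in variants) for (d in intersect(names(fits[[v]]), datasets)) {
    f <- fits[[v]][[d]]
    if (!is.null(f)) m[v, d] <- isTRUE(f$success)
  }
  m
}

#' Observed success rate per variant
#'
#' OSR = successful fits of the variant divided by the number of datasets
#' fitted successfully by at least one variant; datasets that no variant
#' fits are excluded from the denominator. Full precision is retained;
#' round only at report time.
#'
#' @param success logical success matrix (variants x datasets; NA = not run).
#' @return Named numeric vector of OSR values in [0, 1].
#' @export
compute_osr <- function(success) {
  fitted_any <- colSums(success, na.rm = TRUE) > 0
  D <- sum(fitted_any)
  if (D == 0) stop("no dataset was fitted by any variant")
  rowSums(success[, fitted_any, drop = FALSE], na.rm = TRUE) / D
}

#' Expected success rate of a multi-mechanism variant
#'
#' The product of the stand-alone OSRs of the variant's constituent
#' single-mechanism models; defined only for variants with at least two
#' active mechanisms.
#'
#' @param osr_singles numeric vector of length 5: OSR of MI(1)..MI(5).
#' @param mechanisms the composite variant's mechanisms.
#' @return Scalar ESR.
#' @examples
#' compute_esr(c(0.52, 0.61, 0.83, 0.65, 0.09), c(1, 2, 5))  # 0.0285...
#' @export
compute_esr <- function(osr_singles, mechanisms) {
  ms <- mechanism_set(mechanisms)
  if (sum(ms) < 2)
    stop("ESR is defined only for variants combining two or more mechanisms")
  stopifnot(length(osr_singles) == 5)
  prod(osr_singles[which(ms)])
}

#' Mean pseudo-BMA weight per variant across datasets
#'
#' For each dataset fitted by at least one variant, pseudo-BMA weights are
#' computed over the variants that succeeded on it; a failed (or not-run)
#' variant contributes zero. BMA_w is the per-variant mean over all
#' qualifying datasets.
#'
#' @param weights_by_dataset named list: dataset code -> named weight vector
#'   over the successful variants of that dataset.
#' @param success logical success matrix (variants x datasets).
#' @return Named numeric vector of BMA_w per variant.
#' @export
mean_bma <- function(weights_by_dataset, success) {
  fitted_any <- colSums(success, na.rm = TRUE) > 0
  D <- sum(fitted_any)
  if (D == 0) stop("no dataset was fitted by any variant")
  out <- stats::setNames(numeric(nrow(success)), rownames(success))
  for (d in names(weights_by_dataset)) {
    w <- weights_by_dataset[[d]]
    out[names(w)] <- out[names(w)] + w
  }
  out / D
}

#' Assemble the per-variant assessment table
#'
#' Runs PSIS-LOO and pseudo-BMA weighting over a collection of fits and
#' combines them with OSR and ESR into one table (one row per variant,
#' columns \code{variant}, \code{n_params}, \code{BMA_w}, \code{OSR},
#' \code{ESR}). ESR is NA for the baseline and single-mechanism variants.
#'
#' @inheritParams success_matrix
#' @param round_digits digits for report rounding; NULL keeps full
#'   precision.
#' @return A data.frame, plus attributes \code{success} (the success
#'   matrix) and \code{weights_by_dataset}.
#' @export
assessment_table <- function(fits, variants = names(fits), datasets = NULL,
                             round_digits = NULL) {
  success <- success_matrix(fits, variants, datasets)
  weights_by_dataset <- list()
  for (d in colnames(success)) {
    ok <- rownames(success)[which(success[, d])]
    if (!length(ok)) next
    elpd <- vapply(ok, function(v) psis_loo(fits[[v]][[d]]$log_lik)$elpd,
                   numeric(1))
    weights_by_dataset[[d]] <- pseudo_bma_weights(elpd)
  }
  bma <- mean_bma(weights_by_dataset, success)
  osr <- compute_osr(success)
  singles <- paste0("MI(", 1:5, ")")
  osr_singles <- osr[singles]
  esr <- vapply(variants, function(v) {
    ms <- mechanism_set(v)
    if (sum(ms) < 2 || anyNA(osr_singles[which(ms)])) NA_real_
    else compute_esr(unname(osr_singles), ms)
  }, numeric(1))
  n_params <- vapply(variants, function(v) build_variant(v)$n_params, integer(1))
  tab <- data.frame(variant = variants, n_params = n_params,
                    BMA_w = bma[variants], OSR = osr[variants],
                    ESR = esr, row.names = NULL)
  if (!is.null(round_digits))
    tab[c("BMA_w", "OSR", "ESR")] <- round(tab[c("BMA_w", "OSR", "ESR")],
                                           round_digits)
  attr(tab, "success") <- success
  attr(tab, "weights_by_dataset") <- weights_by_dataset
  tab
}
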