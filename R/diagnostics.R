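#' MCMC convergence diagnostics
#'
#' Rank-normalised split R-hat and bulk/tail effective sample sizes,
#' following the modern recommendations for MCMC convergence assessment
#' (rank-normalisation plus folding for R-hat; Geyer initial-monotone
#' autocorrelation sums for ESS; tail ESS as the minimum ESS of the 5% and
#' 95% quantile indicator functions).
#'
#' @param draws numeric matrix, iterations x chains, for one scalar
#'   quantity.
#' @return \code{rhat}: the rank-normalised split R-hat (the maximum of the
#'   bulk and folded variants); \code{ess_bulk} / \code{ess_tail}: effective
#'   sample sizes. All return \code{NA} for degenerate (constant) chains.
#' @name diagnostics
NULL

split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

z_scale <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(as.matrix(x)))
}

rhat_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname diagnostics
#' @export
rhat <- function(draws) {
  x <- split_chains(draws)
  if (all(x == x[1])) return(NA_real_)
  bulk <- rhat_basic(z_scale(x))
  folded <- rhat_basic(z_scale(abs(x - stats::median(x))))
  max(bulk, folded, na.rm = TRUE)
}

ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4 || all(x == x[1])) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  # mean autocovariance across chains, per lag
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus   # rho[t + 1] estimates lag-t autocorrelation
  # Geyer initial positive monotone sequence over pair sums
  # P_k = rho_{2k} + rho_{2k+1}, k = 0, 1, ...
  max_pairs <- floor(n / 2)
  pair <- numeric(0)
  for (k in seq_len(max_pairs) - 1L) {
    i1 <- 2 * k + 1; i2 <- 2 * k + 2
    if (i2 > length(rho)) break
    pk <- rho[i1] + rho[i2]
    if (!is.finite(pk) || pk <= 0) break
    if (length(pair)) pk <- min(pk, pair[length(pair)])
    pair <- c(pair, pk)
  }
  if (!length(pair)) pair <- max(rho[1], 0)
  tau <- max(2 * sum(pair) - rho[1], 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

#' @rdname diagnostics
#' @export
ess_bulk <- function(draws) {
  x <- split_chains(draws)
  if (all(x == x[1])) return(NA_real_)
  ess_basic(z_scale(x))
}

#' @rdname diagnostics
#' @export
ess_tail <- function(draws) {
  x <- split_chains(draws)
  if (all(x == x[1])) return(NA_real_)
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  min(ess_basic(1 * (x <= qs[1])), ess_basic(1 * (x <= qs[2])))
}
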