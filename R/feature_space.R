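#' Filter posterior draws to their 95% credible region
#'
#' Per chain, computes each parameter's central credible interval and
#' retains the draws (complete rows) whose every coordinate lies inside its
#' own parameter's interval. Joint-row filtering keeps draw vectors intact
#' for downstream PCA. The noise sd column is dropped.
#'
#' @param fit a \code{"ferm_fit"}; by convention only successful fits enter
#'   feature-space analyses (set \code{strict = FALSE} to accept any fit,
#'   e.g. in simulation studies).
#' @param level credible level (default 0.95).
#' @param rescale return draws in original units using the fit's scale
#'   factors. The default (FALSE) keeps the max-scaled estimation space,
#'   where all parameters share comparable magnitudes — the premise of the
#'   downstream variance-unscaled PCA; original units (TRUE) suit
#'   comparisons against literature kinetic constants but let the
#'   large-magnitude yields dominate unscaled PCA.
#' @param strict error on non-successful fits.
#' @return Matrix of retained draws (rows) with attributes \code{chain}
#'   (chain id per row) and \code{retention} (fraction retained).
#' @export
filter_ci_draws <- function(fit, level = 0.95, rescale = FALSE,
                            strict = TRUE) {
  stopifnot(inherits(fit, "ferm_fit"))
  if (strict && !isTRUE(fit$success))
    stop("fit is not successful; pass strict = FALSE to filter anyway")
  a <- (1 - level) / 2
  theta_cols <- seq_len(fit$variant$n_params)
  kept <- list(); chains <- list()
  for (ch in unique(fit$chain_id)) {
    x <- fit$draws[fit$chain_id == ch, theta_cols, drop = FALSE]
    lo <- apply(x, 2, stats::quantile, probs = a)
    hi <- apply(x, 2, stats::quantile, probs = 1 - a)
    inside <- rowSums(sweep(x, 2, lo, ">=") & sweep(x, 2, hi, "<=")) == ncol(x)
    kept[[length(kept) + 1]] <- x[inside, , drop = FALSE]
    chains[[length(chains) + 1]] <- rep(ch, sum(inside))
  }
  out <- do.call(rbind, kept)
  if (nrow(out) == 0) stop("CI filtering retained no draws")
  if (rescale)
    out <- t(apply(out, 1, rescale_params, fit$scale_factors, fit$variant))
  attr(out, "chain") <- unlist(chains)
  attr(out, "retention") <- nrow(out) / nrow(fit$draws)
  out
}

#' Pooled draw table over a collection of fits
#'
#' Stacks CI-filtered draws of one variant fitted to several datasets and
#' attaches per-row dataset codes and feature-class labels, forming the
#' input of the feature-classification PCA.
#'
#' @param fits list of \code{"ferm_fit"} objects of the same variant.
#' @param feature metadata field whose class labels the rows carry
#'   (\code{"country"}, \code{"cultivar"}, \code{"method"},
#'   \code{"turning"}, \code{"controlled_temperature"}).
#' @param ... passed to \code{\link{filter_ci_draws}}.
#' @return An object of class \code{"draw_table"}: list with \code{draws}
#'   (pooled matrix), \code{dataset} and \code{class} (per-row labels),
#'   \code{variant}.
#' @export
draw_table <- function(fits, feature = "cultivar", ...) {
  stopifnot(length(fits) >= 1)
  labels <- unique(vapply(fits, function(f) f$variant$label, character(1)))
  if (length(labels) != 1) stop("all fits must share one variant")
  rows <- list(); ds <- list(); cls <- list()
  for (f in fits) {
    lab <- f$features[[feature]]
    if (is.null(lab) || is.na(lab)) next  # unknown feature: excluded
    x <- filter_ci_draws(f, ...)
    rows[[length(rows) + 1]] <- x
    ds[[length(ds) + 1]] <- rep(f$dataset_code, nrow(x))
    cls[[length(cls) + 1]] <- rep(lab, nrow(x))
  }
  if (!length(rows)) stop("no fit carries a known label for feature ", feature)
  structure(list(draws = do.call(rbind, rows), dataset = unlist(ds),
                 class = unlist(cls), variant = fits[[1]]$variant,
                 feature = feature),
            class = "draw_table")
}

#' Subset a draw table to a biologically defined parameter subgroup
#'
#' Subgroups follow the parameter typology: \code{all} (identity),
#' \code{max_growth_rates}, \code{mortality_rates},
#' \code{yield_coefficients}, and the microbe-association groups
#' \code{Y_related}, \code{LAB_related}, \code{AAB_related} (a parameter is
#' X-related iff its definition names microbial group X; saturation
#' constants appear only in \code{all} and the X-related groups, never as a
#' subgroup of their own).
#'
#' @param table a \code{"draw_table"}.
#' @param subgroup subgroup name (see above).
#' @return The column-subset \code{"draw_table"}.
#' @export
subset_params <- function(table,
                          subgroup = c("all", "max_growth_rates",
                                       "mortality_rates",
                                       "yield_coefficients", "Y_related",
                                       "LAB_related", "AAB_related")) {
  subgroup <- match.arg(subgroup)
  stopifnot(inherits(table, "draw_table"))
  if (subgroup == "all") return(table)
  tab <- ferm_parameter_table()
  tab <- tab[match(colnames(table$draws), tab$name), ]
  sel <- switch(subgroup,
    max_growth_rates = tab$type == "growth_rate",
    mortality_rates = tab$type == "mortality",
    yield_coefficients = tab$type == "yield",
    Y_related = tab$microbe %in% "Y",
    LAB_related = tab$microbe %in% "LAB",
    AAB_related = tab$microbe %in% "AAB")
  if (!any(sel)) stop("subgroup '", subgroup, "' is empty for this variant")
  table$draws <- table$draws[, sel, drop = FALSE]
  table
}

#' PCA over a draw table
#'
#' Principal component analysis of the pooled draws with mean-centring and
#' no variance scaling (the draws live on comparable scales). The sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive, making loadings reproducible.
#'
#' @param table a \code{"draw_table"} (or plain numeric matrix).
#' @return An object of class \code{"ferm_pca"}: \code{scores},
#'   \code{loadings}, \code{explained} (variance fractions), plus the
#'   row labels carried over from the table.
#' @export
run_pca <- function(table) {
  x <- if (inherits(table, "draw_table")) table$draws else as.matrix(table)
  if (nrow(x) < 2 || ncol(x) < 2) stop("PCA needs at least 2 rows and 2 columns")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained = ev / sum(ev),
                 class = if (inherits(table, "draw_table")) table$class else NULL,
                 dataset = if (inherits(table, "draw_table")) table$dataset else NULL),
            class = "ferm_pca")
}

#' @export
print.ferm_pca <- function(x, ...) {
  cat("<ferm_pca>", nrow(x$scores), "rows,", ncol(x$loadings), "parameters;",
      "PC1/PC2 explain", paste0(round(100 * x$explained[1], 1), "%/",
                                round(100 * x$explained[2], 1), "%\n"))
  invisible(x)
}

#' Pairwise squared Mahalanobis separation of classes in PC1/PC2 space
#'
#' Computes class centroids on the first two principal-component scores and
#' the squared Mahalanobis distance between every class pair,
#' \code{D = (x1 - x2)' S^-1 (x1 - x2)}, with S the pooled within-class
#' covariance of the scores. The median over pairs summarises a feature's
#' separation in a single value.
#'
#' @param scores two-column matrix of PC1/PC2 scores, or a
#'   \code{"ferm_pca"} object (its class labels are used by default).
#' @param classes class label per row.
#' @return An object of class \code{"ferm_separation"}: symmetric
#'   \code{D} matrix of squared distances, \code{median_D}, class
#'   \code{centroids} and the pooled covariance \code{S}.
#' @export
pairwise_mahalanobis <- function(scores, classes = NULL) {
  if (inherits(scores, "ferm_pca")) {
    if (is.null(classes)) classes <- scores$class
    scores <- scores$scores[, 1:2, drop = FALSE]
  }
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  classes <- as.character(classes)
  stopifnot(nrow(scores) == length(classes))
  lv <- unique(classes)
  if (length(lv) < 2) stop("at least two classes are required")
  counts <- table(classes)
  if (any(counts < 3)) stop("every class needs at least 3 rows")
  centroids <- t(vapply(lv, function(cl)
    colMeans(scores[classes == cl, , drop = FALSE]), numeric(2)))
  # pooled within-class covariance
  S <- matrix(0, 2, 2)
  for (cl in lv) {
    xc <- scale(scores[classes == cl, , drop = FALSE], scale = FALSE)
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(scores) - length(lv))
  cond <- kappa(S)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular (condition number ", signif(cond, 3), ")"))
  D <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i < j) {
      dd <- centroids[i, ] - centroids[j, ]
      D[i, j] <- D[j, i] <- drop(t(dd) %*% Sinv %*% dd)
    }
  }
  pairs <- D[upper.tri(D)]
  structure(list(D = D, median_D = stats::median(pairs),
                 centroids = centroids, S = S, condition = cond),
            class = "ferm_separation")
}

#' @export
print.ferm_separation <- function(x, ...) {
  cat("<ferm_separation>", nrow(x$D), "classes; median squared Mahalanobis =",
      signif(x$median_D, 4), "\n")
  invisible(x)
}
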