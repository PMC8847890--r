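#' Plan a fitting campaign over variants and datasets
#'
#' Builds the task manifest of a full campaign: one fit task per
#' (variant, dataset) pair, in deterministic order.
#'
#' @param datasets list of \code{\link{fermentation_dataset}} objects (or a
#'   \code{"ferm_cohort"}).
#' @param variants character vector of variant labels, or \code{"all"} for
#'   all 32.
#' @return A data.frame manifest with columns \code{task}, \code{variant},
#'   \code{dataset}, \code{status}.
#' @examples
#' cohort <- generate_cohort(generator_config(n_timepoints = 8),
#'                           classes = list(A = c(), B = c()),
#'                           n_per_class = 3)
#' nrow(plan_pipeline(cohort, "all"))   # 32 * 6
#' @export
plan_pipeline <- function(datasets, variants = "all") {
  if (inherits(datasets, "ferm_cohort")) datasets <- datasets$datasets
  if (length(datasets) == 0) stop("no datasets supplied")
  codes <- vapply(datasets, function(d) d$code, character(1))
  if (any(duplicated(codes))) stop("dataset codes must be unique")
  if (identical(variants, "all"))
    variants <- vapply(enumerate_variants(), attr, character(1), "label")
  grid <- expand.grid(dataset = codes, variant = variants,
                      stringsAsFactors = FALSE)[, c("variant", "dataset")]
  data.frame(task = seq_len(nrow(grid)), grid, status = "pending",
             stringsAsFactors = FALSE)
}

#' Run the generate-fit-assess pipeline
#'
#' Executes every task of \code{\link{plan_pipeline}}: max-scales each
#' dataset, fits each requested variant, and records per-task success.
#' Completed fits are cached on disk keyed by variant, dataset code and a
#' hash of the sampler/solver/prior configuration, so re-running with an
#' identical configuration reuses cached results. Per-task failures are
#' recorded in the manifest and do not stop the campaign.
#'
#' @inheritParams plan_pipeline
#' @param sampler a \code{\link{sampler_config}}; the seed of task i is
#'   \code{sampler$seed + i}.
#' @param solver a \code{\link{solver_config}}.
#' @param prior a \code{\link{prior_spec}}.
#' @param out_dir cache/output directory (created if missing); NULL
#'   disables caching.
#' @return List with \code{manifest} (task table with \code{status}
#'   \code{"success"}, \code{"non-convergence"}, \code{"error"} or
#'   \code{"cached"}), \code{fits} (nested list variant -> dataset ->
#'   \code{ferm_fit}) and \code{assessment} (the
#'   \code{\link{assessment_table}}, when at least one fit succeeded).
#' @export
run_pipeline <- function(datasets, variants = "all",
                         sampler = sampler_config(),
                         solver = solver_config(),
                         prior = prior_spec(),
                         out_dir = NULL) {
  if (inherits(datasets, "ferm_cohort")) datasets <- datasets$datasets
  manifest <- plan_pipeline(datasets, variants)
  codes <- vapply(datasets, function(d) d$code, character(1))
  scaled <- lapply(datasets, max_scale)
  names(scaled) <- codes
  cfg_hash <- config_hash(sampler, solver, prior)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fits <- list()
  for (i in seq_len(nrow(manifest))) {
    v <- manifest$variant[i]; d <- manifest$dataset[i]
    cache <- if (is.null(out_dir)) NULL else
      file.path(out_dir, sprintf("fit_%s_%s_%s.rds",
                                 gsub("[(),]", "", v), d, cfg_hash))
    if (!is.null(cache) && file.exists(cache)) {
      fit <- readRDS(cache)
      manifest$status[i] <- "cached"
    } else {
      samp <- sampler; samp$seed <- sampler$seed + i
      fit <- tryCatch(
        fit_variant(v, scaled[[d]], prior = prior, sampler = samp,
                    solver = solver),
        error = function(e) e)
      if (inherits(fit, "error")) {
        manifest$status[i] <- "error"
        next
      }
      manifest$status[i] <- if (isTRUE(fit$success)) "success" else "non-convergence"
      if (!is.null(cache)) saveRDS(fit, cache)
    }
    if (is.null(fits[[v]])) fits[[v]] <- list()
    fits[[v]][[d]] <- fit
  }
  assessment <- NULL
  ok <- any(vapply(fits, function(fv)
    any(vapply(fv, function(f) isTRUE(f$success), logical(1))), logical(1)))
  if (length(fits) && ok)
    assessment <- assessment_table(fits, variants = unique(manifest$variant),
                                   datasets = codes)
  list(manifest = manifest, fits = fits, assessment = assessment,
       config_hash = cfg_hash, seed = sampler$seed)
}

config_hash <- function(sampler, solver, prior) {
  key <- paste(c(unlist(sampler), unlist(solver), unlist(prior)),
               collapse = "|")
  # small stable hash, no extra dependencies
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 100000L
}

#' Serialize fit results to JSON
#'
#' Writes the summary, diagnostics and verdict of a fit (not the raw draw
#' table) to a JSON file; the draw table can be exported separately as CSV.
#'
#' @param fit a \code{"ferm_fit"}.
#' @param path output path (.json).
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(variant = fit$variant$label,
              dataset = fit$dataset_code,
              seed = fit$seed,
              success = isTRUE(fit$success),
              reasons = fit$reasons,
              rerun = isTRUE(fit$rerun),
              mean_ess_ratio = fit$diagnostics$mean_ess_ratio,
              summary = fit$summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
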