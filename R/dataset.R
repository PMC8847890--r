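#' Construct a fermentation trial dataset
#'
#' A fermentation trial is a set of time series sampled over the course of
#' one fermentation: five metabolites (glucose, fructose, ethanol, lactic
#' acid, acetic acid; mg per g pulp) and three microbial groups (yeast, LAB,
#' AAB), observed at a common set of time points. Microbial counts may be
#' supplied either already converted to mg per g pulp or as log10 CFU per g
#' (see \code{\link{cfu_to_mass}}). Missing observations are allowed (NA)
#' except in the first row, which seeds the initial state when fitting.
#'
#' @param times observation times in hours, strictly increasing, at least 5.
#' @param observations numeric matrix or data.frame, \code{length(times)}
#'   rows and the 8 columns \code{Glc, Fru, EtOH, LA, Ac, Y, LAB, AAB}.
#' @param code short trial identifier, e.g. \code{"mywb3"}.
#' @param features named list of trial metadata: \code{country},
#'   \code{cultivar}, \code{method}, \code{turning} (\code{"yes"},
#'   \code{"no"} or NA), \code{controlled_temperature} (\code{"yes"} or
#'   \code{"no"}). Missing keys are stored as NA.
#' @return An object of class \code{"ferm_dataset"}.
#' @export
fermentation_dataset <- function(times, observations, code = "trial",
                                 features = list()) {
  times <- as.numeric(times)
  if (length(times) < 5) stop("a trial needs at least five observation times")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  obs <- as.matrix(observations)
  if (is.data.frame(observations)) obs <- data.matrix(observations)
  if (nrow(obs) != length(times)) stop("observations must have one row per time")
  nm <- ferm_state_names()
  if (!all(nm %in% colnames(obs)))
    stop("observations must contain columns ", paste(nm, collapse = ", "))
  obs <- obs[, nm, drop = FALSE]
  if (any(obs < 0, na.rm = TRUE)) stop("observations must be non-negative")
  if (anyNA(obs[1, ])) stop("the first observation row must be complete")
  keys <- c("country", "cultivar", "method", "turning", "controlled_temperature")
  feat <- stats::setNames(rep(list(NA_character_), length(keys)), keys)
  for (k in intersect(names(features), keys))
    feat[[k]] <- as.character(features[[k]])
  structure(list(code = code, times = times, observations = obs,
                 features = feat),
            class = "ferm_dataset")
}

#' @export
print.ferm_dataset <- function(x, ...) {
  cat("<ferm_dataset>", x$code, "-", length(x$times), "time points over",
      round(max(x$times), 1), "h\n")
  invisible(x)
}

#' Read / write fermentation trial CSV files
#'
#' The CSV layout has a \code{time} column (hours) followed by the eight
#' series columns \code{Glc,Fru,EtOH,LA,Ac,Y,LAB,AAB}. Trial metadata
#' (country, cultivar, method, turning, controlled_temperature) lives in an
#' optional YAML sidecar \code{<path>.yml}.
#'
#' @param path CSV file path.
#' @param code trial code; defaults to the file name without extension.
#' @return \code{read_fermentation_csv}: a \code{\link{fermentation_dataset}}.
#' @export
read_fermentation_csv <- function(path, code = NULL) {
  df <- utils::read.csv(path)
  if (is.null(code)) code <- sub("\\.csv$", "", basename(path))
  sidecar <- paste0(path, ".yml")
  feat <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  fermentation_dataset(df$time, df[, ferm_state_names()], code = code,
                       features = feat)
}

#' @rdname read_fermentation_csv
#' @param dataset a \code{ferm_dataset}.
#' @export
write_fermentation_csv <- function(dataset, path) {
  df <- data.frame(time = dataset$times, dataset$observations,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!all(is.na(unlist(dataset$features))))
    yaml::write_yaml(dataset$features, paste0(path, ".yml"))
  invisible(path)
}
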