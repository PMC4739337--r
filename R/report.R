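resultToList <- function(r) {
  list(index = r@index, k = r@k, values = r@values, metadata = r@metadata,
       mean = stabilityMean(r), variance = stabilityVariance(r))
}

resultFromList <- function(l) {
  new("StabilityResult", index = l$index, k = as.integer(l$k),
      values = as.numeric(l$values), metadata = as.list(l$metadata))
}

pairIds <- function(k) {
  p <- t(utils::combn(k, 2))
  sprintf("%d-%d", p[, 1], p[, 2])
}

tidyRows <- function(results, protocol, method, arm) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(protocol = protocol, method = method, arm = arm,
               index = r@index, pair_id = pairIds(r@k), value = r@values,
               row.names = NULL)
  }))
}

summaryRows <- function(results, arm) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(arm = arm, index = r@index, mean = stabilityMean(r),
               variance = stabilityVariance(r), row.names = NULL)
  }))
}

#' Write a stability experiment to disk
#'
#' Serialises a \linkS4class{StabilityExperiment} or
#' \linkS4class{PairedStabilityExperiment} to three files under \code{dir}:
#' \code{<prefix>.json} (full provenance: protocol, parameters, every seed,
#' and all pairwise index values at maximum precision),
#' \code{<prefix>_pairwise.csv} (tidy: one row per protocol/method/arm/
#' index/pair) and \code{<prefix>_summary.csv} (mean and variance per
#' index, the shape of the usual per-dataset summary tables).
#'
#' @param x the experiment object.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix (default: the protocol).
#' @return Invisibly, the paths written.
#' @export
writeStabilityReport <- function(x, dir, prefix = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  if (is.null(prefix)) prefix <- x@protocol
  paths <- file.path(dir, paste0(prefix, c(".json", "_pairwise.csv",
                                           "_summary.csv")))
  if (is(x, "StabilityExperiment")) {
    payload <- list(type = "StabilityExperiment", protocol = x@protocol,
                    method = x@method, params = x@params, seeds = x@seeds,
                    results = lapply(x@results, resultToList))
    tidy <- tidyRows(x@results, x@protocol, x@method, "intrinsic")
    summ <- summaryRows(x@results, "intrinsic")
  } else if (is(x, "PairedStabilityExperiment")) {
    payload <- list(type = "PairedStabilityExperiment", protocol = x@protocol,
                    method = x@method, params = x@params, seeds = x@seeds,
                    variation = lapply(x@variation, resultToList),
                    intrinsic = lapply(x@intrinsic, resultToList),
                    perUnit = x@perUnit)
    tidy <- rbind(tidyRows(x@variation, x@protocol, x@method, "variation"),
                  tidyRows(x@intrinsic, x@protocol, x@method, "intrinsic"))
    summ <- rbind(summaryRows(x@variation, "variation"),
                  summaryRows(x@intrinsic, "intrinsic"))
  } else stop("unsupported object of class ", class(x))
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(tidy, paths[2], row.names = FALSE)
  utils::write.csv(summ, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Reload a stability experiment from its JSON report
#'
#' Inverse of \code{\link{writeStabilityReport}} for the JSON file: rebuilds
#' the experiment object, including all pairwise values and seeds.
#'
#' @param path path to the \code{.json} file written by
#'   \code{\link{writeStabilityReport}}.
#' @return A \linkS4class{StabilityExperiment} or
#'   \linkS4class{PairedStabilityExperiment}.
#' @export
readStabilityReport <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  if (identical(l$type, "StabilityExperiment")) {
    new("StabilityExperiment", protocol = l$protocol, method = l$method,
        results = lapply(l$results, resultFromList),
        seeds = as.list(l$seeds), params = as.list(l$params))
  } else if (identical(l$type, "PairedStabilityExperiment")) {
    pu <- as.data.frame(l$perUnit, stringsAsFactors = FALSE)
    new("PairedStabilityExperiment", protocol = l$protocol,
        method = l$method,
        variation = lapply(l$variation, resultFromList),
        intrinsic = lapply(l$intrinsic, resultFromList),
        perUnit = pu, seeds = as.list(l$seeds), params = as.list(l$params))
  } else stop("unrecognised report type in ", path)
}
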