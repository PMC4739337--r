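#' Dataset indicators
#'
#' The four descriptors used to characterise a classification dataset —
#' number of features, number of samples, number of classes and the
#' out-of-bag accuracy of a fitted forest (a proxy for dataset complexity) —
#' plus the synthetic indicator #feature/#sample, a degree of
#' high-dimension/small-sample.
#'
#' @param data a \linkS4class{VimDataset}.
#' @param model a \linkS4class{RandomForestFit} fitted on \code{data}.
#' @return A one-row data.frame with columns \code{dataset, nFeature,
#'   nSample, nClass, oobAccuracy, ratio}.
#' @export
setMethod("computeIndicators", signature("VimDataset", "RandomForestFit"),
  function(data, model, ...) {
    data.frame(dataset = datasetName(data),
               nFeature = nFeatures(data),
               nSample = nSamples(data),
               nClass = nClasses(data),
               oobAccuracy = oobAccuracy(model, data),
               ratio = nFeatures(data) / nSamples(data),
               row.names = NULL)
  })

#' Correlation test between two numeric vectors
#'
#' Spearman (monotonic association, average-rank tie handling) or Pearson
#' (linear association) correlation with a two-sided p-value from the
#' t-approximation on n - 2 degrees of freedom; significance is flagged at
#' the 5 % level. For very small samples (n < 10) an exact permutation
#' p-value is available for the Spearman coefficient.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param coefficient "spearman" or "pearson".
#' @param exact use the exact permutation null for Spearman (only for
#'   n < 10; default FALSE, matching the t-approximation used at n = 19).
#' @return A one-row data.frame with columns \code{coefficient, estimate,
#'   p.value, n, significant}.
#' @examples
#' correlationTest(1:10, (1:10)^2, "spearman")
#' @export
correlationTest <- function(x, y, coefficient = c("spearman", "pearson"),
                            exact = FALSE) {
  coefficient <- match.arg(coefficient)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input; correlation undefined")
  if (exact && coefficient == "spearman" && length(x) < 10) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE))
  } else {
    ct <- stats::cor.test(x, y, method = coefficient,
                          exact = if (coefficient == "spearman") FALSE)
  }
  data.frame(coefficient = coefficient,
             estimate = unname(ct$estimate),
             p.value = ct$p.value,
             n = length(x),
             significant = ct$p.value < 0.05,
             row.names = NULL)
}

#' Correlate a dataset indicator with per-dataset stability means
#'
#' Aligns an indicator table (one row per dataset, as from
#' \code{\link{computeIndicators}}) with a stability table (one row per
#' dataset x index, columns \code{dataset, index, mean}) and tests the
#' association between the chosen indicator and the chosen stability index
#' across datasets. Subgroups (e.g. low-dimensional/large-sample vs
#' high-dimensional/small-sample) can be selected by dataset name.
#'
#' @param indicators data.frame with a \code{dataset} column and indicator
#'   columns.
#' @param stability data.frame with columns \code{dataset, index, mean}.
#' @param whichIndicator indicator column name (e.g. "ratio", "nFeature").
#' @param whichIndex stability index name ("spearman", "jaccard",
#'   "kuncheva", "mard").
#' @param coefficient "spearman" or "pearson".
#' @param subset optional character vector of dataset names to restrict to.
#' @return A one-row data.frame as from \code{\link{correlationTest}}, plus
#'   \code{indicator} and \code{index} columns.
#' @export
correlateStability <- function(indicators, stability, whichIndicator,
                               whichIndex,
                               coefficient = c("spearman", "pearson"),
                               subset = NULL) {
  coefficient <- match.arg(coefficient)
  if (!whichIndicator %in% colnames(indicators))
    stop("unknown indicator column: ", whichIndicator)
  st <- stability[stability$index == whichIndex, , drop = FALSE]
  if (!nrow(st)) stop("no stability rows for index ", whichIndex)
  if (!is.null(subset)) {
    indicators <- indicators[indicators$dataset %in% subset, , drop = FALSE]
    st <- st[st$dataset %in% subset, , drop = FALSE]
  }
  m <- match(indicators$dataset, st$dataset)
  if (anyNA(m) || nrow(st) != nrow(indicators))
    stop("indicator and stability tables are misaligned ",
         "(dataset names do not match one-to-one)")
  out <- correlationTest(indicators[[whichIndicator]], st$mean[m],
                         coefficient)
  cbind(data.frame(indicator = whichIndicator, index = whichIndex),
        out)
}

#' Characteristics of 19 published benchmark datasets
#'
#' Loads the bundled table of descriptors (#feature, #sample, #class, tuned
#' out-of-bag accuracy) for 19 publicly available classification benchmarks
#' from the UCI and GEMS repositories that are widely used in studies of
#' feature-ranking stability: nine low-dimensional/large-sample sets and ten
#' high-dimensional/small-sample gene-expression sets.
#'
#' @return A data.frame with columns \code{dataset, domain, nFeature,
#'   nSample, nClass, oobAccuracy, ratio}.
#' @examples
#' b <- benchmarkCharacteristics()
#' correlationTest(b$nFeature, b$nSample, "spearman")
#' @export
benchmarkCharacteristics <- function() {
  path <- system.file("extdata", "benchmark_characteristics.csv",
                      package = "vimstab", mustWork = TRUE)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  b$ratio <- b$nFeature / b$nSample
  b
}
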