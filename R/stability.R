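#' Truncate a ranking to its top features
#'
#' Returns the first min(cap, d) features of a ranking, order preserved.
#' Rankings over at most \code{cap} features pass through unchanged.
#'
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param cap maximum number of top features submitted to stability
#'   evaluation (default 100).
#' @return Character vector of feature ids.
#' @export
truncateRanking <- function(ranking, cap = 100) {
  stopifnot(is(ranking, "FeatureRanking"), cap >= 1)
  ids <- rankedFeatures(ranking)
  ids[seq_len(min(length(ids), cap))]
}

asRanking <- function(x) {
  if (is(x, "ImportanceScores")) rankFeatures(x) else x
}

checkPair <- function(g, h) {
  stopifnot(is(g, "FeatureRanking"), is(h, "FeatureRanking"))
  if (!setequal(rankedFeatures(g), rankedFeatures(h)))
    stop("rankings must be over the same feature set")
  invisible(length(rankedFeatures(g)))
}

#' Spearman rank-correlation stability of two feature rankings
#'
#' For rankings over d <= cap features this is the classical rank
#' correlation of the two position vectors,
#' 1 - 6 * sum((pos_g - pos_h)^2) / (d (d^2 - 1)): 1 for identical rankings,
#' -1 for exactly inverse orders. When d > cap the two top-\code{cap} sets
#' need not coincide; the index is then evaluated over the union of the two
#' top-\code{cap} sets, with each ranking re-ranked densely (1..|F|) within
#' that union ("union" mode, the default), or over their intersection
#' ("intersection" mode).
#'
#' @param g,h \linkS4class{FeatureRanking}s (or \linkS4class{ImportanceScores},
#'   ranked on the fly) over the same feature set.
#' @param cap top-feature cap (default 100).
#' @param truncated how to restrict the two rankings when d > cap.
#' @return Value in [-1, 1].
#' @export
spearmanStability <- function(g, h, cap = 100,
                              truncated = c("union", "intersection")) {
  g <- asRanking(g); h <- asRanking(h)
  d <- checkPair(g, h)
  truncated <- match.arg(truncated)
  if (d <= cap) {
    pg <- featurePositions(g)
    ph <- featurePositions(h)[names(pg)]
  } else {
    keep <- if (truncated == "union")
      union(truncateRanking(g, cap), truncateRanking(h, cap))
    else
      intersect(truncateRanking(g, cap), truncateRanking(h, cap))
    if (length(keep) < 2L)
      stop("fewer than 2 features survive truncation; cannot rank-correlate")
    pg <- rank(featurePositions(g)[keep])
    ph <- rank(featurePositions(h)[keep])
    d <- length(keep)
  }
  if (d < 2L) stop("rank correlation undefined for a single feature")
  1 - 6 * sum((pg - ph)^2) / (d * (d^2 - 1))
}

# r_j = |top-j(g) /\ top-j(h)| for j = 1..jmax, computed incrementally.
prefixIntersections <- function(g, h, jmax) {
  gi <- rankedFeatures(g)
  ph <- featurePositions(h)
  hi <- rankedFeatures(h)
  pg <- featurePositions(g)
  r <- integer(jmax)
  cur <- 0L
  for (j in seq_len(jmax)) {
    a <- gi[j]; b <- hi[j]
    if (a == b) cur <- cur + 1L
    else {
      if (ph[[a]] <= j) cur <- cur + 1L
      if (pg[[b]] <= j) cur <- cur + 1L
    }
    r[j] <- cur
  }
  r
}

#' Jaccard stability of two feature rankings
#'
#' Averages, over every prefix length j = 1..d'-1 with d' = min(d, cap), the
#' Jaccard similarity |top-j(g) /\ top-j(h)| / |top-j(g) \/ top-j(h)| of the
#' two top-j feature subsets. 1 for identical rankings.
#'
#' @inheritParams spearmanStability
#' @return Value in [0, 1].
#' @export
jaccardStability <- function(g, h, cap = 100) {
  g <- asRanking(g); h <- asRanking(h)
  d <- checkPair(g, h)
  dp <- min(d, cap)
  if (dp < 2L) stop("Jaccard stability undefined for a single feature")
  j <- seq_len(dp - 1L)
  r <- prefixIntersections(g, h, dp - 1L)
  mean(r / (2 * j - r))
}

#' Kuncheva chance-corrected stability of two feature rankings
#'
#' Averages over prefix lengths j = 1..d'-1 (d' = min(d, cap)) the
#' chance-corrected overlap (r_j - j^2/d) / (j - j^2/d), where r_j is the
#' size of the intersection of the two top-j subsets and the correction term
#' j^2/d is the overlap expected for independently drawn subsets. The
#' correction uses the full dimensionality d by default (the feature pool
#' overlap happens by chance in), overridable via \code{chanceDim}.
#' Identical rankings give 1; independent random rankings average 0.
#'
#' @inheritParams spearmanStability
#' @param chanceDim dimensionality used in the chance-correction term
#'   (default: the full feature count d).
#' @return Value <= 1.
#' @export
kunchevaStability <- function(g, h, cap = 100, chanceDim = NULL) {
  g <- asRanking(g); h <- asRanking(h)
  d <- checkPair(g, h)
  if (is.null(chanceDim)) chanceDim <- d
  dp <- min(d, cap)
  if (dp < 2L) stop("Kuncheva stability undefined for a single feature")
  j <- seq_len(dp - 1L)
  r <- prefixIntersections(g, h, dp - 1L)
  mean((r - j^2 / chanceDim) / (j - j^2 / chanceDim))
}

#' Mean absolute relative difference of two importance-score runs
#'
#' Compares the raw importance values of two runs feature by feature:
#' mean over the evaluation set F of |s_g - s_h| / (|s_g + s_h| / 2).
#' F is the full feature set when d <= cap, otherwise the union of the two
#' top-\code{cap} feature sets (so cap <= |F| <= 2 cap). Features whose two
#' scores sum to zero contribute 0; if such a pair also differs (possible for
#' permutation importance, which can be negative) the number of affected
#' features is reported in the \code{"zeroDenominator"} attribute. Identical
#' runs give 0.
#'
#' @param g,h \linkS4class{ImportanceScores} from the same method over the
#'   same feature set.
#' @param cap top-feature cap (default 100).
#' @return Value >= 0.
#' @export
mard <- function(g, h, cap = 100) {
  stopifnot(is(g, "ImportanceScores"), is(h, "ImportanceScores"))
  if (g@method != h@method)
    stop("cannot compare importance scores from different methods")
  sg <- scoreValues(g)
  sh <- scoreValues(h)
  if (!setequal(names(sg), names(sh)))
    stop("score vectors must be over the same feature set")
  sh <- sh[names(sg)]
  d <- length(sg)
  keep <- if (d <= cap) names(sg) else
    union(truncateRanking(rankFeatures(g), cap),
          truncateRanking(rankFeatures(h), cap))
  if (!length(keep)) stop("empty evaluation set")
  a <- sg[keep]; b <- sh[keep]
  denom <- abs(a + b) / 2
  num <- abs(a - b)
  zero <- denom == 0
  term <- ifelse(zero, 0, num / ifelse(zero, 1, denom))
  out <- mean(term)
  attr(out, "zeroDenominator") <- sum(zero & num > 0)
  out
}

indexFuns <- list(
  spearman = function(g, h, cap) spearmanStability(g, h, cap),
  jaccard  = function(g, h, cap) jaccardStability(g, h, cap),
  kuncheva = function(g, h, cap) kunchevaStability(g, h, cap),
  mard     = function(g, h, cap) as.numeric(mard(g, h, cap))
)

#' k-way stability across repeated importance runs
#'
#' Evaluates one pairwise stability index on all k(k-1)/2 unordered pairs of
#' runs and stores the pairwise values together with their mean and sample
#' variance. Rank-based indices (spearman, jaccard, kuncheva) are computed on
#' the rankings derived from the scores; mard is computed on the raw scores.
#'
#' @param runs list of k >= 2 \linkS4class{ImportanceScores} from the same
#'   method on the same dataset.
#' @param index one of "spearman", "jaccard", "kuncheva", "mard".
#' @param cap top-feature cap (default 100).
#' @param metadata optional list merged into the result's metadata.
#' @return A \linkS4class{StabilityResult}.
#' @export
kwayStability <- function(runs, index = c("spearman", "jaccard", "kuncheva",
                                          "mard"),
                          cap = 100, metadata = list()) {
  index <- match.arg(index)
  k <- length(runs)
  if (k < 2L) stop("need at least 2 runs")
  stopifnot(all(vapply(runs, is, logical(1), "ImportanceScores")))
  method <- unique(vapply(runs, importanceMethod, character(1)))
  if (length(method) != 1L) stop("all runs must use the same method")
  args <- if (index == "mard") runs else lapply(runs, rankFeatures)
  f <- indexFuns[[index]]
  values <- numeric(0)
  for (g in seq_len(k - 1L))
    for (h in seq(g + 1L, k))
      values <- c(values, f(args[[g]], args[[h]], cap))
  new("StabilityResult", index = index, values = values, k = as.integer(k),
      metadata = c(list(method = method, cap = cap), metadata))
}

#' @rdname stability-accessors
#' @name stability-accessors
#' @aliases pairwiseValues stabilityMean stabilityVariance nRuns
#' @param x a \linkS4class{StabilityResult}.
#' @param ... unused.
NULL

#' @rdname stability-accessors
setMethod("pairwiseValues", "StabilityResult", function(x, ...) x@values)
#' @rdname stability-accessors
setMethod("stabilityMean", "StabilityResult", function(x, ...) mean(x@values))
#' @rdname stability-accessors
setMethod("stabilityVariance", "StabilityResult",
          function(x, ...) stats::var(x@values))
#' @rdname stability-accessors
setMethod("nRuns", "StabilityResult", function(x) x@k)

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult [%s]: k = %d (%d pairs), mean %.4f, variance %.4f\n",
              object@index, object@k, length(object@values),
              mean(object@values), stats::var(object@values)))
})

#' Notched-box summary of a distribution of stability values
#'
#' Returns the statistics of a notched box plot: median, quartiles (type-7
#' quantiles), IQR, whisker ends (the most extreme values within 1.5 IQR of
#' the hinges), outliers beyond the whiskers, and the notch half-width
#' (3.14 / 2) * IQR / sqrt(n), so the full notch height is 3.14 * IQR /
#' sqrt(n). Non-overlapping notches of two boxes are strong evidence that
#' the medians differ.
#'
#' @param values numeric vector (at least one value).
#' @return A list with elements \code{n, median, q1, q3, iqr, whiskerLow,
#'   whiskerHigh, outliers, notchHalfWidth, notchLow, notchHigh}.
#' @export
boxplotSummary <- function(values) {
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  loLim <- q[1] - 1.5 * iqr
  hiLim <- q[3] + 1.5 * iqr
  inside <- values >= loLim & values <= hiLim
  notch <- (3.14 / 2) * iqr / sqrt(length(values))
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whiskerLow = min(values[inside]), whiskerHigh = max(values[inside]),
       outliers = values[!inside], notchHalfWidth = notch,
       notchLow = q[2] - notch, notchHigh = q[2] + notch)
}
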