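#' Fit a bagged CART forest
#'
#' Trains \code{ntree} classification trees, each on an independent bootstrap
#' sample of size n drawn with replacement, choosing each node split among
#' \code{mtry} uniformly sampled candidate features by the Gini criterion and
#' growing to purity by default. Bootstrap membership and per-node Gini
#' impurity decreases are stored on the fit, so out-of-bag sets and
#' mean-decrease-Gini importance are recoverable exactly. The fit is
#' bit-reproducible from \code{seed}.
#'
#' @param data a \linkS4class{VimDataset}.
#' @param ntree number of trees (>= 1).
#' @param mtry candidate split features per node; a positive integer <= d or
#'   one of the symbols understood by \code{\link{resolveMtry}}
#'   ("one", "dwdef", "def", "updef"). Default "def" = round(sqrt(d)).
#' @param nodesize minimum node size eligible for splitting; 1 (default)
#'   grows every tree to purity.
#' @param seed integer seed controlling bagging and feature sampling.
#' @return A \linkS4class{RandomForestFit}.
#' @examples
#' d <- generateDataset(nSample = 60, nFeature = 5, nClass = 2,
#'                      nInformative = 2, classSeparation = 2, seed = 1)
#' fit <- fitForest(d, ntree = 50, seed = 1)
#' oobAccuracy(fit, d)
#' @export
fitForest <- function(data, ntree = 500, mtry = "def", nodesize = 1,
                      seed = 1) {
  stopifnot(is(data, "VimDataset"))
  d <- nFeatures(data)
  mtry <- if (is.character(mtry)) resolveMtry(mtry, d) else as.integer(mtry)
  if (mtry > d) stop("mtry (", mtry, ") exceeds the number of features (",
                     d, ")")
  if (nClasses(data) < 2L) stop("response has a single class")
  config <- new("ForestConfig", ntree = as.integer(ntree),
                mtry = as.integer(mtry), nodesize = as.integer(nodesize),
                seed = as.integer(seed))
  y0 <- as.integer(classLabels(data)) - 1L
  set.seed(config@seed)
  raw <- rf_fit(featureMatrix(data), y0, nClasses(data), config@ntree,
                config@mtry, config@nodesize)
  new("RandomForestFit", trees = raw$trees, inbag = raw$inbag,
      config = config, classLevels = levels(classLabels(data)),
      featureIds = featureIds(data))
}

setMethod("show", "RandomForestFit", function(object) {
  cat("RandomForestFit: ", length(object@trees), " trees, ",
      length(object@featureIds), " features, mtry ", object@config@mtry,
      ", seed ", object@config@seed, "\n", sep = "")
})

#' Out-of-bag sample sets
#'
#' @param model a \linkS4class{RandomForestFit}.
#' @return A list with, for each tree, the integer indices of the samples
#'   absent from its bootstrap sample.
#' @export
setMethod("oobSamples", "RandomForestFit", function(model) {
  lapply(seq_len(ncol(model@inbag)), function(t) which(model@inbag[, t] == 0L))
})

#' Mean out-of-bag fraction of a fit
#'
#' Mean over trees of |OOB_t| / n; approaches (1 - 1/n)^n (about 0.368) as
#' the number of trees grows.
#'
#' @param model a \linkS4class{RandomForestFit}.
#' @export
oobFraction <- function(model) {
  mean(colMeans(model@inbag == 0L))
}

#' Out-of-bag fraction of plain bootstrap resampling
#'
#' Draws \code{nboot} bootstrap samples of size n with replacement from
#' 1..n and returns the per-replicate fraction of indices never drawn. The
#' mean approaches (1 - 1/n)^n, about 36.8\% for large n.
#'
#' @param n number of instances.
#' @param nboot number of bootstrap replicates.
#' @return Numeric vector of length \code{nboot} of out-of-bag fractions.
#' @examples
#' mean(bootstrapOobFraction(1000, 50))
#' @export
bootstrapOobFraction <- function(n, nboot = 500) {
  vapply(seq_len(nboot), function(b) {
    mean(tabulate(sample.int(n, n, replace = TRUE), nbins = n) == 0L)
  }, numeric(1))
}

#' Out-of-bag accuracy
#'
#' Each sample is predicted by majority vote over only those trees for which
#' it is out of bag (ties broken towards the first class level); the returned
#' value is the fraction of correct predictions among samples receiving at
#' least one vote. Samples in-bag for every tree are excluded from the
#' denominator.
#'
#' @param model a \linkS4class{RandomForestFit}.
#' @param data the \linkS4class{VimDataset} the model was fitted on.
#' @return Fraction in [0, 1].
#' @export
setMethod("oobAccuracy", signature("RandomForestFit", "VimDataset"),
  function(model, data, ...) {
    checkFit(model, data)
    votes <- rf_oob_votes(model@trees, featureMatrix(data), model@inbag,
                          nClasses(data))
    evaluable <- rowSums(votes) > 0L
    if (!any(evaluable))
      stop("no sample is out of bag for any tree; increase ntree")
    pred <- max.col(votes, ties.method = "first")
    mean(pred[evaluable] == as.integer(classLabels(data))[evaluable])
  })

checkFit <- function(model, data) {
  if (!identical(model@featureIds, featureIds(data)) ||
      nrow(model@inbag) != nSamples(data))
    stop("model was not fitted on this dataset (dimension/feature mismatch)")
  invisible(TRUE)
}

#' Mean decrease in accuracy (permutation importance)
#'
#' For each tree t and feature j, counts the correct out-of-bag predictions
#' before and after permuting feature j's values among the tree's OOB samples
#' only; the tree's contribution is (before - after) / |OOB_t| and the score
#' is the unscaled mean over trees. One fresh permutation is drawn per
#' (tree, feature used by that tree); features a tree never splits on
#' contribute exactly 0 for that tree. Trees with an empty OOB set are
#' skipped and the mean is taken over the remaining trees.
#'
#' @param model a \linkS4class{RandomForestFit}.
#' @param data the \linkS4class{VimDataset} the model was fitted on.
#' @param seed integer seed driving all permutations of this run.
#' @return An \linkS4class{ImportanceScores} with method "MDA". Scores may be
#'   negative.
#' @export
setMethod("mdaImportance", signature("RandomForestFit", "VimDataset"),
  function(model, data, seed = 1, ...) {
    checkFit(model, data)
    set.seed(as.integer(seed))
    vi <- rf_mda(model@trees, featureMatrix(data),
                 as.integer(classLabels(data)) - 1L, model@inbag)
    names(vi) <- model@featureIds
    new("ImportanceScores", method = "MDA", scores = vi,
        seed = as.integer(seed), config = model@config)
  })

#' Mean decrease in Gini impurity
#'
#' Sums, for each feature, the fraction-of-samples weighted Gini impurity
#' decreases of every node split on that feature, and averages over all
#' trees. Deterministic given the fitted model; features with no splits
#' score 0.
#'
#' @param model a \linkS4class{RandomForestFit}.
#' @return An \linkS4class{ImportanceScores} with method "MDG" (scores >= 0).
#' @export
setMethod("mdgImportance", "RandomForestFit", function(model, ...) {
  d <- length(model@featureIds)
  allVar <- unlist(lapply(model@trees, `[[`, "var"), use.names = FALSE)
  allDec <- unlist(lapply(model@trees, `[[`, "dec"), use.names = FALSE)
  sel <- allVar >= 0L
  vi <- numeric(d)
  if (any(sel)) {
    agg <- rowsum(allDec[sel], allVar[sel])
    vi[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  }
  vi <- vi / length(model@trees)
  names(vi) <- model@featureIds
  new("ImportanceScores", method = "MDG", scores = vi,
      seed = model@config@seed, config = model@config)
})

#' @rdname importanceScores-accessors
#' @name importanceScores-accessors
#' @aliases importanceMethod scoreValues
#' @param x an \linkS4class{ImportanceScores}.
NULL

#' @rdname importanceScores-accessors
setMethod("importanceMethod", "ImportanceScores", function(x) x@method)
#' @rdname importanceScores-accessors
setMethod("scoreValues", "ImportanceScores", function(x) x@scores)

setMethod("show", "ImportanceScores", function(object) {
  cat("ImportanceScores (", object@method, "), ", length(object@scores),
      " features, seed ", object@seed, "\n", sep = "")
  print(head(sort(object@scores, decreasing = TRUE), 5L))
})

#' Rank features by descending importance
#'
#' Orders the features by decreasing importance score; ties are broken by
#' ascending feature (column) position, making the ranking deterministic.
#'
#' @param scores an \linkS4class{ImportanceScores} or a named numeric vector.
#' @return A \linkS4class{FeatureRanking} carrying both the ordering and its
#'   inverse (feature -> rank position).
#' @export
setMethod("rankFeatures", "ImportanceScores", function(scores, ...) {
  rankFeatures(scores@scores)
})

#' @rdname rankFeatures
#' @export
setMethod("rankFeatures", "numeric", function(scores, ...) {
  if (is.null(names(scores))) names(scores) <- paste0("f", seq_along(scores))
  ord <- order(-scores, seq_along(scores))
  ids <- names(scores)[ord]
  pos <- integer(length(scores))
  pos[ord] <- seq_along(ord)
  names(pos) <- names(scores)
  new("FeatureRanking", featureIds = ids, positions = pos)
})

#' @rdname ranking-accessors
#' @name ranking-accessors
#' @aliases rankedFeatures featurePositions
#' @param x a \linkS4class{FeatureRanking}.
NULL

#' @rdname ranking-accessors
setMethod("rankedFeatures", "FeatureRanking", function(x) x@featureIds)
#' @rdname ranking-accessors
setMethod("featurePositions", "FeatureRanking", function(x) x@positions)

setMethod("show", "FeatureRanking", function(object) {
  k <- min(10L, length(object@featureIds))
  cat("FeatureRanking over ", length(object@featureIds), " features; top:\n  ",
      paste(object@featureIds[seq_len(k)], collapse = " > "),
      if (length(object@featureIds) > k) " > ..." else "", "\n", sep = "")
})
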