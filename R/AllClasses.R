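#' @useDynLib vimstab, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor.test quantile median var rnorm runif
#' @importFrom utils read.delim write.csv head
NULL

#' Tabular classification dataset
#'
#' Container for an n x d numeric feature matrix with a class label per
#' sample. Feature identity is positional: the i-th column is feature i, and
#' all rankings refer back to these positions via the column names.
#'
#' @slot X numeric matrix, samples in rows, features in columns (named).
#' @slot y factor of class labels, one per row of \code{X}.
#' @slot name single string identifying the dataset.
#' @export
setClass("VimDataset",
  representation(X = "matrix", y = "factor", name = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@X)) msg <- c(msg, "X must be a numeric matrix")
    if (nrow(object@X) < 2L) msg <- c(msg, "need at least 2 samples")
    if (ncol(object@X) < 1L) msg <- c(msg, "need at least 1 feature")
    if (length(object@y) != nrow(object@X))
      msg <- c(msg, "length(y) must equal nrow(X)")
    if (anyNA(object@X) || anyNA(object@y))
      msg <- c(msg, "missing values are not allowed")
    if (nlevels(droplevels(object@y)) < 2L)
      msg <- c(msg, "need at least 2 classes")
    if (is.null(colnames(object@X)) || anyDuplicated(colnames(object@X)))
      msg <- c(msg, "feature names must be present and unique")
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Forest configuration
#'
#' The two random-forest tuning parameters plus the minimum node size and the
#' seed controlling bagging and per-node feature sampling.
#'
#' @slot ntree number of trees.
#' @slot mtry number of candidate split features sampled at each node.
#' @slot nodesize minimum node size eligible for splitting (1 = grow to purity).
#' @slot seed integer seed for the fit.
#' @export
setClass("ForestConfig",
  representation(ntree = "integer", mtry = "integer", nodesize = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@ntree < 1L) msg <- c(msg, "ntree must be >= 1")
    if (object@mtry < 1L) msg <- c(msg, "mtry must be >= 1")
    if (object@nodesize < 1L) msg <- c(msg, "nodesize must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Fitted bagged forest
#'
#' A fitted ensemble of CART trees with exact per-tree bootstrap membership
#' (\code{inbag} counts) and, inside each tree record, the split feature and
#' the fraction-of-samples weighted Gini impurity decrease of every internal
#' node. The out-of-bag set of tree t is the set of samples with
#' \code{inbag[, t] == 0}.
#'
#' @slot trees list of tree records (vectors var/split/left/right/pred/dec).
#' @slot inbag integer matrix (n x ntree) of bootstrap multiplicities.
#' @slot config the \linkS4class{ForestConfig} used.
#' @slot classLevels levels of the response the trees were trained on.
#' @slot featureIds feature (column) names of the training data.
#' @export
setClass("RandomForestFit",
  representation(trees = "list", inbag = "matrix", config = "ForestConfig",
                 classLevels = "character", featureIds = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@trees) != ncol(object@inbag))
      msg <- c(msg, "one inbag column per tree required")
    if (any(colSums(object@inbag) != nrow(object@inbag)))
      msg <- c(msg, "each bootstrap sample must have size n")
    if (length(msg)) msg else TRUE
  })

#' Per-feature importance scores from one VIM run
#'
#' @slot method "MDA" (permutation importance on out-of-bag samples) or
#'   "MDG" (mean decrease in Gini impurity).
#' @slot scores named numeric vector, one score per feature.
#' @slot seed the run seed (permutation seed for MDA, fit seed echoed for MDG).
#' @slot config the \linkS4class{ForestConfig} of the underlying forest.
#' @export
setClass("ImportanceScores",
  representation(method = "character", scores = "numeric", seed = "integer",
                 config = "ForestConfig"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("MDA", "MDG"))
      msg <- c(msg, "method must be 'MDA' or 'MDG'")
    if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
      msg <- c(msg, "scores must be uniquely named by feature")
    if (object@method == "MDG" && any(object@scores < 0))
      msg <- c(msg, "MDG scores must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Feature ranking
#'
#' Features ordered by descending importance; ties are broken by ascending
#' feature (column) position so the ordering is deterministic.
#'
#' @slot featureIds feature names in rank order (best first).
#' @slot positions named integer vector: feature name -> 1-based rank.
#' @export
setClass("FeatureRanking",
  representation(featureIds = "character", positions = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@featureIds) != length(object@positions))
      msg <- c(msg, "positions must invert featureIds")
    else if (!identical(object@featureIds[object@positions[object@featureIds]],
                        object@featureIds))
      msg <- c(msg, "positions must be the exact inverse of the ordering")
    if (length(msg)) msg else TRUE
  })

#' Stability of one index across k runs
#'
#' Holds all k(k-1)/2 pairwise index values for one stability index; the mean
#' and variance are recomputed from the stored values on access.
#'
#' @slot index one of "spearman", "jaccard", "kuncheva", "mard".
#' @slot values numeric vector of the pairwise values, length k(k-1)/2.
#' @slot k number of runs compared.
#' @slot metadata list with method, cap and protocol details.
#' @export
setClass("StabilityResult",
  representation(index = "character", values = "numeric", k = "integer",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@index %in% c("spearman", "jaccard", "kuncheva", "mard"))
      msg <- c(msg, "unknown stability index")
    if (length(object@values) != object@k * (object@k - 1L) / 2L)
      msg <- c(msg, "need k(k-1)/2 pairwise values")
    if (length(msg)) msg else TRUE
  })

#' One stability experiment (one arm)
#'
#' @slot protocol experiment label, e.g. "intrinsic".
#' @slot method "MDA" or "MDG".
#' @slot results named list of \linkS4class{StabilityResult}, one per index.
#' @slot seeds list recording every seed used, keyed by run.
#' @slot params list of the protocol parameters (ntree, mtry, cap, ...).
#' @export
setClass("StabilityExperiment",
  representation(protocol = "character", method = "character",
                 results = "list", seeds = "list", params = "list"))

#' Paired stability experiment (variation arm + nested intrinsic arm)
#'
#' For the data-perturbation and parameter-variation protocols: the
#' \code{variation} slot holds the k-way stability across training sets or
#' grid settings, the \code{intrinsic} slot the repeated-run stability
#' computed under each setting and averaged over settings (element-wise over
#' the pairwise vectors, so its mean is the mean of per-setting means).
#'
#' @slot protocol "perturbation", "ntree_variation" or "mtry_variation".
#' @slot method "MDA" or "MDG".
#' @slot variation named list of \linkS4class{StabilityResult} per index.
#' @slot intrinsic named list of \linkS4class{StabilityResult} per index.
#' @slot perUnit data.frame of per-setting intrinsic means (setting x index).
#' @slot seeds list recording every seed used.
#' @slot params list of the protocol parameters.
#' @export
setClass("PairedStabilityExperiment",
  representation(protocol = "character", method = "character",
                 variation = "list", intrinsic = "list",
                 perUnit = "data.frame", seeds = "list", params = "list"))
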