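#' Resolve a symbolic mtry setting
#'
#' The forest's per-node candidate count is usually stated relative to its
#' default: "def" is round(sqrt(d)) (clamped to [1, d]), "dwdef" half of def,
#' "updef" one and a half of def (clamped to d), and "one" a single candidate.
#'
#' @param symbol one of "one", "dwdef", "def", "updef" (or a positive
#'   integer, returned clamped to [1, d]).
#' @param d total number of features.
#' @return Integer mtry value in [1, d].
#' @examples
#' vapply(c("one", "dwdef", "def", "updef"), resolveMtry, integer(1), d = 100)
#' @export
resolveMtry <- function(symbol, d) {
  stopifnot(d >= 1)
  if (is.numeric(symbol)) return(as.integer(max(1, min(d, symbol))))
  def <- max(1L, min(as.integer(d), as.integer(round(sqrt(d)))))
  switch(match.arg(symbol, c("one", "dwdef", "def", "updef")),
         one = 1L,
         dwdef = max(1L, as.integer(round(def / 2))),
         def = def,
         updef = min(as.integer(d), as.integer(round(1.5 * def))))
}

# Deterministic seed stream: hashes the master seed with a path of integer
# indices (protocol / arm / run) so arms and runs are independent but
# replayable. Kept inside 2^31 - 1; exact in double arithmetic.
childSeed <- function(master, ...) {
  m <- 2147483647
  s <- (as.numeric(master) %% m + 1)
  for (k in c(...)) s <- (s * 48271 + as.numeric(k) + 1) %% m
  as.integer(s)
}

vimMethods <- c(mda = "MDA", mdg = "MDG")

normMethod <- function(method) {
  method <- tolower(method)
  match.arg(method, c("mda", "mdg"))
}

# One importance run: fit a forest and compute the requested VIM.
vimRun <- function(data, method, ntree, mtry, nodesize, fitSeed, permSeed) {
  fit <- fitForest(data, ntree = ntree, mtry = mtry, nodesize = nodesize,
                   seed = fitSeed)
  if (method == "mda") mdaImportance(fit, data, seed = permSeed)
  else mdgImportance(fit)
}

allIndices <- c("spearman", "jaccard", "kuncheva", "mard")

kwayAll <- function(runs, cap, metadata) {
  res <- lapply(allIndices, function(ix)
    kwayStability(runs, ix, cap = cap, metadata = metadata))
  names(res) <- allIndices
  res
}

#' Intrinsic (repeated-run) stability
#'
#' Fits \code{kRuns} forests on the same full dataset under the same
#' configuration, differing only in the per-run seeds derived from
#' \code{seed}, computes the chosen importance measure for each run, and
#' evaluates the k-way stability of the resulting rankings (Spearman,
#' Jaccard, Kuncheva) and raw scores (MARD). This isolates the
#' self-consistence of the importance measure under its internal randomness
#' (bagging, per-node feature sampling and, for MDA, permutation), with no
#' data perturbation or parameter variation.
#'
#' @param data a \linkS4class{VimDataset}.
#' @param method "mda" or "mdg".
#' @param kRuns number of repeated runs (default 10, giving 45 pairs).
#' @param ntree,mtry,nodesize forest configuration (see
#'   \code{\link{fitForest}}).
#' @param cap top-feature cap for the stability indices.
#' @param seed master seed; per-run seeds are derived deterministically.
#' @return A \linkS4class{StabilityExperiment} with one
#'   \linkS4class{StabilityResult} per index.
#' @export
runIntrinsic <- function(data, method = c("mda", "mdg"), kRuns = 10,
                         ntree = 20000, mtry = "def", nodesize = 1,
                         cap = 100, seed = 1) {
  method <- normMethod(method)
  stopifnot(kRuns >= 2)
  seeds <- lapply(seq_len(kRuns), function(r)
    list(fit = childSeed(seed, 1, r, 1), perm = childSeed(seed, 1, r, 2)))
  runs <- lapply(seeds, function(s)
    vimRun(data, method, ntree, mtry, nodesize, s$fit, s$perm))
  meta <- list(protocol = "intrinsic", dataset = datasetName(data))
  new("StabilityExperiment", protocol = "intrinsic",
      method = vimMethods[[method]],
      results = kwayAll(runs, cap, meta),
      seeds = list(master = seed, runs = seeds),
      params = list(kRuns = kRuns, ntree = ntree, mtry = mtry,
                    nodesize = nodesize, cap = cap))
}

# Elementwise average of per-setting pairwise vectors -> one StabilityResult
# per index whose mean is the average of the per-setting means.
averageIntrinsicArm <- function(perSetting, cap, method, protocol) {
  res <- lapply(allIndices, function(ix) {
    npairs <- length(pairwiseValues(perSetting[[1]][[ix]]))
    mat <- matrix(vapply(perSetting, function(s) pairwiseValues(s[[ix]]),
                         numeric(npairs)), nrow = npairs)
    new("StabilityResult", index = ix, values = rowMeans(mat),
        k = perSetting[[1]][[ix]]@k,
        metadata = list(method = method, cap = cap, protocol = protocol,
                        nSettings = length(perSetting),
                        averagedOverSettings = TRUE))
  })
  names(res) <- allIndices
  res
}

perUnitTable <- function(perSetting, settingLabels) {
  do.call(rbind, lapply(seq_along(perSetting), function(i) {
    data.frame(setting = settingLabels[i], index = allIndices,
               mean = vapply(perSetting[[i]], stabilityMean, numeric(1)),
               row.names = NULL)
  }))
}

# Random fold assignment (optionally stratified by class), reproducible.
foldAssignment <- function(y, folds, seed, stratified = FALSE) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(folds), n))
  }
  fold
}

#' Data-perturbation stability with a nested intrinsic arm
#'
#' Partitions the data into \code{folds} random equal-sized subsets. The
#' perturbation arm runs the importance measure once per fold-complement
#' training set (\code{folds} runs) and evaluates k-way stability across
#' those runs — rankings now differ both through internal randomness and
#' through the differing training data. The intrinsic arm runs \code{kRuns}
#' repeated runs on each training set, evaluates stability per training set,
#' and averages over the training sets, so both arms are directly
#' comparable.
#'
#' @inheritParams runIntrinsic
#' @param folds number of cross-validation folds (default 10).
#' @param stratified stratify the partition by class (default FALSE; plain
#'   uniform random partition).
#' @return A \linkS4class{PairedStabilityExperiment}.
#' @export
runPerturbation <- function(data, method = c("mda", "mdg"), folds = 10,
                            kRuns = 10, ntree = 20000, mtry = "def",
                            nodesize = 1, cap = 100, seed = 1,
                            stratified = FALSE) {
  method <- normMethod(method)
  stopifnot(folds >= 2, nSamples(data) >= folds)
  partSeed <- childSeed(seed, 2, 0)
  fold <- foldAssignment(classLabels(data), folds, partSeed, stratified)

  for (f in seq_len(folds))
    if (nlevels(droplevels(classLabels(data)[fold != f])) < nClasses(data))
      stop("training set of fold ", f, " lost a class; ",
           "use stratified = TRUE or more samples")
  trainSets <- lapply(seq_len(folds), function(f) data[fold != f])

  pertSeeds <- lapply(seq_len(folds), function(f)
    list(fit = childSeed(seed, 2, f, 1), perm = childSeed(seed, 2, f, 2)))
  pertRuns <- lapply(seq_len(folds), function(f)
    vimRun(trainSets[[f]], method, ntree, mtry, nodesize,
           pertSeeds[[f]]$fit, pertSeeds[[f]]$perm))
  meta <- list(protocol = "perturbation", dataset = datasetName(data))
  variation <- kwayAll(pertRuns, cap, meta)

  intrSeeds <- list()
  perFold <- lapply(seq_len(folds), function(f) {
    seeds <- lapply(seq_len(kRuns), function(r)
      list(fit = childSeed(seed, 3, f, r, 1),
           perm = childSeed(seed, 3, f, r, 2)))
    intrSeeds[[f]] <<- seeds
    runs <- lapply(seeds, function(s)
      vimRun(trainSets[[f]], method, ntree, mtry, nodesize, s$fit, s$perm))
    kwayAll(runs, cap, c(meta, list(fold = f)))
  })

  new("PairedStabilityExperiment", protocol = "perturbation",
      method = vimMethods[[method]],
      variation = variation,
      intrinsic = averageIntrinsicArm(perFold, cap, vimMethods[[method]],
                                      "perturbation/intrinsic"),
      perUnit = perUnitTable(perFold, paste0("fold", seq_len(folds))),
      seeds = list(master = seed, partition = partSeed,
                   perturbation = pertSeeds, intrinsic = intrSeeds),
      params = list(folds = folds, kRuns = kRuns, ntree = ntree, mtry = mtry,
                    nodesize = nodesize, cap = cap, stratified = stratified))
}

variationProtocol <- function(data, method, protocol, settings, makeConfig,
                              kRuns, nodesize, cap, seed) {
  labels <- vapply(settings, function(s) as.character(s), character(1))
  varSeeds <- lapply(seq_along(settings), function(i)
    list(fit = childSeed(seed, 4, i, 1), perm = childSeed(seed, 4, i, 2)))
  varRuns <- lapply(seq_along(settings), function(i) {
    cf <- makeConfig(settings[[i]])
    vimRun(data, method, cf$ntree, cf$mtry, nodesize,
           varSeeds[[i]]$fit, varSeeds[[i]]$perm)
  })
  meta <- list(protocol = protocol, dataset = datasetName(data))
  variation <- kwayAll(varRuns, cap, meta)

  intrSeeds <- list()
  perSetting <- lapply(seq_along(settings), function(i) {
    cf <- makeConfig(settings[[i]])
    seeds <- lapply(seq_len(kRuns), function(r)
      list(fit = childSeed(seed, 5, i, r, 1),
           perm = childSeed(seed, 5, i, r, 2)))
    intrSeeds[[i]] <<- seeds
    runs <- lapply(seeds, function(s)
      vimRun(data, method, cf$ntree, cf$mtry, nodesize, s$fit, s$perm))
    kwayAll(runs, cap, c(meta, list(setting = labels[i])))
  })

  new("PairedStabilityExperiment", protocol = protocol,
      method = vimMethods[[method]],
      variation = variation,
      intrinsic = averageIntrinsicArm(perSetting, cap, vimMethods[[method]],
                                      paste0(protocol, "/intrinsic")),
      perUnit = perUnitTable(perSetting, labels),
      seeds = list(master = seed, variation = varSeeds,
                   intrinsic = intrSeeds),
      params = list(settings = labels, kRuns = kRuns, nodesize = nodesize,
                    cap = cap))
}

#' ntree-variation stability with a nested intrinsic arm
#'
#' The variation arm performs one importance run per forest size in
#' \code{ntreeGrid} (mtry held at \code{mtry}) and evaluates k-way stability
#' across the grid; the intrinsic arm performs \code{kRuns} repeated runs at
#' each grid point, evaluates stability per point, and averages over points.
#'
#' @inheritParams runIntrinsic
#' @param ntreeGrid forest sizes; the default is the ten-point grid
#'   50..50000. Tests and small studies typically pass a scaled-down grid.
#' @return A \linkS4class{PairedStabilityExperiment}.
#' @export
runNtreeVariation <- function(data, method = c("mda", "mdg"),
                              ntreeGrid = c(50, 100, 200, 500, 1000, 2000,
                                            5000, 10000, 20000, 50000),
                              mtry = "def", kRuns = 10, nodesize = 1,
                              cap = 100, seed = 1) {
  method <- normMethod(method)
  stopifnot(length(ntreeGrid) >= 2)
  variationProtocol(data, method, "ntree_variation", as.list(ntreeGrid),
                    function(nt) list(ntree = nt, mtry = mtry),
                    kRuns, nodesize, cap, seed)
}

#' mtry-variation stability with a nested intrinsic arm
#'
#' As \code{\link{runNtreeVariation}}, but varying mtry over the symbolic
#' grid ("one", "dwdef", "def", "updef" by default; see
#' \code{\link{resolveMtry}}) with ntree held fixed.
#'
#' @inheritParams runIntrinsic
#' @param mtryGrid mtry settings (symbols or integers).
#' @return A \linkS4class{PairedStabilityExperiment}.
#' @export
runMtryVariation <- function(data, method = c("mda", "mdg"),
                             mtryGrid = c("one", "dwdef", "def", "updef"),
                             ntree = 20000, kRuns = 10, nodesize = 1,
                             cap = 100, seed = 1) {
  method <- normMethod(method)
  stopifnot(length(mtryGrid) >= 2)
  variationProtocol(data, method, "mtry_variation", as.list(mtryGrid),
                    function(mt) list(ntree = ntree, mtry = mt),
                    kRuns, nodesize, cap, seed)
}

setMethod("show", "StabilityExperiment", function(object) {
  cat("StabilityExperiment [", object@protocol, ", ", object@method, "]\n",
      sep = "")
  for (ix in names(object@results))
    cat(sprintf("  %-9s mean %.4f variance %.4f\n", ix,
                stabilityMean(object@results[[ix]]),
                stabilityVariance(object@results[[ix]])))
})

setMethod("show", "PairedStabilityExperiment", function(object) {
  cat("PairedStabilityExperiment [", object@protocol, ", ", object@method,
      "]\n", sep = "")
  for (ix in names(object@variation))
    cat(sprintf("  %-9s variation %.4f | intrinsic %.4f\n", ix,
                stabilityMean(object@variation[[ix]]),
                stabilityMean(object@intrinsic[[ix]])))
})
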