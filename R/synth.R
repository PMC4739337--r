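#' Generate a synthetic classification dataset
#'
#' Draws Gaussian class-conditional data emulating the two regimes in which
#' importance-measure stability is typically studied: low-dimensional with
#' many samples, and gene-expression-like high-dimensional with few samples,
#' few informative features and many correlated or noise features.
#'
#' The classes are laid out along a single latent gradient: in informative
#' feature i (i = 1..nInformative), the centre of class c is
#' \code{classSeparation * separationDecay^(i-1) * (c - (C+1)/2)}, so
#' adjacent class centres differ by \code{classSeparation} standard
#' normal units in the first informative feature and the signal decays
#' geometrically across informative features (giving a resolvable importance
#' ordering when \code{separationDecay < 1}). Each informative feature can
#' carry \code{correlatedBlocks} redundant copies (the feature plus Gaussian
#' noise calibrated to a within-block correlation of \code{blockCor});
#' remaining features are pure noise. Class sizes are balanced to within one
#' sample. The whole draw is reproducible from \code{seed}.
#'
#' @param nSample number of samples (n >= 2).
#' @param nFeature total number of features d.
#' @param nClass number of classes C >= 2.
#' @param nInformative number of informative features (>= 0;
#'   nInformative * (1 + correlatedBlocks) must not exceed d).
#' @param classSeparation distance between adjacent class centres in the
#'   first informative feature, in units of the noise standard deviation.
#'   0 produces a dataset with no class signal.
#' @param separationDecay geometric decay of the separation across
#'   informative features (default 1: all equally informative).
#' @param correlatedBlocks redundant copies per informative feature.
#' @param blockCor within-block correlation of the redundant copies.
#' @param noiseSd standard deviation of the within-class noise.
#' @param seed integer seed.
#' @param name dataset identifier.
#' @return A \linkS4class{VimDataset}.
#' @examples
#' d <- generateDataset(nSample = 100, nFeature = 20, nClass = 3,
#'                      nInformative = 4, classSeparation = 1.5, seed = 7)
#' d
#' @export
generateDataset <- function(nSample, nFeature, nClass = 2, nInformative = 2,
                            classSeparation = 1, separationDecay = 1,
                            correlatedBlocks = 0, blockCor = 0.8,
                            noiseSd = 1, seed = 1, name = NULL) {
  stopifnot(nSample >= 2, nFeature >= 1, nClass >= 2,
            nInformative >= 0, classSeparation >= 0, noiseSd > 0,
            blockCor > 0, blockCor < 1)
  if (nInformative * (1 + correlatedBlocks) > nFeature)
    stop("nInformative * (1 + correlatedBlocks) exceeds nFeature")
  if (nSample < nClass)
    stop("need at least one sample per class")
  set.seed(as.integer(seed))

  # balanced labels up to rounding (first classes take the remainder)
  base <- nSample %/% nClass
  extra <- nSample %% nClass
  sizes <- rep(base, nClass) + c(rep(1L, extra), rep(0L, nClass - extra))
  y <- factor(rep(paste0("c", seq_len(nClass)), times = sizes),
              levels = paste0("c", seq_len(nClass)))

  X <- matrix(rnorm(nSample * nFeature, sd = noiseSd), nSample, nFeature)
  if (nInformative > 0) {
    gradient <- as.integer(y) - (nClass + 1) / 2
    sep <- classSeparation * separationDecay^(seq_len(nInformative) - 1)
    for (i in seq_len(nInformative))
      X[, i] <- X[, i] + sep[i] * gradient
    if (correlatedBlocks > 0) {
      tau <- noiseSd * sqrt(1 / blockCor^2 - 1)
      col <- nInformative
      for (i in seq_len(nInformative))
        for (b in seq_len(correlatedBlocks)) {
          col <- col + 1L
          X[, col] <- X[, i] + rnorm(nSample, sd = tau)
        }
    }
  }
  colnames(X) <- paste0("f", seq_len(nFeature))
  if (is.null(name))
    name <- sprintf("synth_n%d_d%d_c%d", nSample, nFeature, nClass)
  VimDataset(X, y, name)
}

# Regime parameter grids spanning the ranges of the two families of
# benchmark datasets the generator emulates.
regimeGrid <- function(regime, size) {
  f <- if (size == 1) 0.5 else (seq_len(size) - 1) / (size - 1)
  if (regime == "low_dim_large_n") {
    list(p = round(8 + f * (60 - 8)),
         n = round(8000 - f * (8000 - 200)),
         C = 2 + round(f * 8),
         nInf = pmax(2, round((8 + f * 52) / 2)))
  } else {
    list(p = round(2000 + f * (12600 - 2000)),
         n = round(203 - f * (203 - 30)),
         C = 2 + round(f * 9),
         nInf = rep(20, size))
  }
}

#' Generate a suite of datasets from one regime
#'
#' Produces a family of synthetic datasets spanning a regime's
#' dimensionality and sample-size ranges while holding the class separation
#' fixed, so the #feature/#sample ratio varies across the suite: the
#' low-dimensional/large-sample regime spans p in [8, 60] and n in
#' [200, 8000]; the high-dimensional/small-sample ("gene-expression-like")
#' regime spans p in [2000, 12600] and n in [30, 203] with few informative
#' features. A \code{scale} factor < 1 shrinks p and n proportionally
#' (never below feasibility) for quick studies.
#'
#' @param regime "low_dim_large_n" or "high_dim_small_n".
#' @param size number of datasets in the suite.
#' @param seed integer seed; each dataset gets a derived seed.
#' @param classSeparation,separationDecay,noiseSd forwarded to
#'   \code{\link{generateDataset}}.
#' @param scale proportional shrink factor for p and n (default 1).
#' @return A named list of \linkS4class{VimDataset}s.
#' @export
regimeSuite <- function(regime = c("low_dim_large_n", "high_dim_small_n"),
                        size = 9, seed = 1, classSeparation = 1.5,
                        separationDecay = 0.9, noiseSd = 1, scale = 1) {
  regime <- match.arg(regime)
  stopifnot(size >= 1, scale > 0)
  g <- regimeGrid(regime, size)
  out <- lapply(seq_len(size), function(i) {
    p <- max(4, round(g$p[i] * scale))
    n <- max(g$C[i] * 4, round(g$n[i] * scale))
    generateDataset(nSample = n, nFeature = p, nClass = g$C[i],
                    nInformative = min(p, g$nInf[i]),
                    classSeparation = classSeparation,
                    separationDecay = separationDecay,
                    noiseSd = noiseSd,
                    seed = childSeed(seed, 6, i),
                    name = sprintf("%s_%02d", regime, i))
  })
  names(out) <- vapply(out, datasetName, character(1))
  out
}

fixtureRegistry <- list(
  # shapes mirroring well-known benchmark datasets (see
  # benchmarkCharacteristics()); the content is synthetic
  yeast_like  = list(n = 1484, p = 8, C = 10, nInf = 8, sep = 2.5,
                     decay = 0.85),
  glass_like  = list(n = 240, p = 9, C = 6, nInf = 6, sep = 2, decay = 0.8),
  madelon_like = list(n = 2600, p = 500, C = 2, nInf = 10, sep = 1.5,
                      decay = 0.9),
  srbct_like  = list(n = 83, p = 2308, C = 4, nInf = 20, sep = 1.5,
                     decay = 0.95),
  dlbcl_like  = list(n = 77, p = 5469, C = 2, nInf = 20, sep = 1.5,
                     decay = 0.95)
)

#' Named synthetic fixtures shaped like familiar benchmarks
#'
#' A small registry of generator settings whose (n, d, C) shapes mirror
#' familiar public benchmarks — e.g. "yeast_like" (1484 x 8, 10 classes) or
#' "srbct_like" (83 x 2308, 4 classes). The data are synthetic Gaussian
#' draws; only the shape is borrowed.
#'
#' @param name one of \code{fixtureNames()}.
#' @param seed integer seed.
#' @return A \linkS4class{VimDataset}.
#' @export
fixtureDataset <- function(name, seed = 1) {
  if (!name %in% names(fixtureRegistry))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixtureRegistry), collapse = ", "))
  r <- fixtureRegistry[[name]]
  generateDataset(nSample = r$n, nFeature = r$p, nClass = r$C,
                  nInformative = r$nInf, classSeparation = r$sep,
                  separationDecay = r$decay, seed = seed, name = name)
}

#' @rdname fixtureDataset
#' @export
fixtureNames <- function() names(fixtureRegistry)
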