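# Independent brute-force re-implementations of the stability indices,
# written as literal double loops over prefix subsets / feature unions, used
# as oracles for the package's implementations.

mkRanking <- function(ids) {
  new("FeatureRanking", featureIds = ids,
      positions = stats::setNames(seq_along(ids), ids))
}

mkScores <- function(values, method = "MDA", seed = 0L) {
  cfg <- new("ForestConfig", ntree = 1L, mtry = 1L, nodesize = 1L, seed = 0L)
  new("ImportanceScores", method = method, scores = values,
      seed = as.integer(seed), config = cfg)
}

naivePositions <- function(ids) stats::setNames(seq_along(ids), ids)

naiveSpearman <- function(g, h, cap = 100) {
  d <- length(g)
  if (d > cap) {
    keep <- union(g[seq_len(cap)], h[seq_len(cap)])
    pg <- rank(naivePositions(g)[keep])
    ph <- rank(naivePositions(h)[keep])
    d <- length(keep)
  } else {
    pg <- naivePositions(g)
    ph <- naivePositions(h)[names(pg)]
  }
  1 - 6 * sum((pg - ph)^2) / (d * (d^2 - 1))
}

naiveJaccard <- function(g, h, cap = 100) {
  dp <- min(length(g), cap)
  terms <- vapply(seq_len(dp - 1), function(j) {
    length(intersect(g[seq_len(j)], h[seq_len(j)])) /
      length(union(g[seq_len(j)], h[seq_len(j)]))
  }, numeric(1))
  mean(terms)
}

naiveKuncheva <- function(g, h, cap = 100) {
  d <- length(g)
  dp <- min(d, cap)
  terms <- vapply(seq_len(dp - 1), function(j) {
    r <- length(intersect(g[seq_len(j)], h[seq_len(j)]))
    (r - j^2 / d) / (j - j^2 / d)
  }, numeric(1))
  mean(terms)
}

naiveMard <- function(sg, sh, cap = 100) {
  keep <- names(sg)
  if (length(sg) > cap) {
    topg <- names(sg)[order(-sg, seq_along(sg))][seq_len(cap)]
    toph <- names(sh)[order(-sh, seq_along(sh))][seq_len(cap)]
    keep <- union(topg, toph)
  }
  tot <- 0
  for (f in keep) {
    den <- abs(sg[[f]] + sh[[f]]) / 2
    tot <- tot + if (den == 0) 0 else abs(sg[[f]] - sh[[f]]) / den
  }
  tot / length(keep)
}

# a quickly separable two-class dataset for forest sanity checks
easyDataset <- function(n = 100, d = 5, seed = 1) {
  generateDataset(nSample = n, nFeature = d, nClass = 2, nInformative = 2,
                  classSeparation = 3, separationDecay = 0.6, seed = seed)
}
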