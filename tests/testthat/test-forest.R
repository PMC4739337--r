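test_that("out-of-bag sets are the complement of the bootstrap support", {
  # definition on a hand-picked bootstrap: draws (1,1,3,5,5) from n=5
  counts <- tabulate(c(1, 1, 3, 5, 5), nbins = 5)
  expect_equal(which(counts == 0), c(2, 4))

  d <- easyDataset(40, 4, seed = 2)
  fit <- fitForest(d, ntree = 20, seed = 3)
  expect_equal(colSums(fit@inbag), rep(40, 20), ignore_attr = TRUE)
  oob <- oobSamples(fit)
  for (t in seq_len(20))
    expect_equal(oob[[t]], which(fit@inbag[, t] == 0L))
})

test_that("fits and importance runs are bit-reproducible from the seed", {
  d <- easyDataset(60, 5, seed = 4)
  f1 <- fitForest(d, ntree = 40, seed = 11)
  f2 <- fitForest(d, ntree = 40, seed = 11)
  expect_identical(f1@inbag, f2@inbag)
  expect_identical(f1@trees, f2@trees)
  expect_identical(scoreValues(mdaImportance(f1, d, seed = 5)),
                   scoreValues(mdaImportance(f2, d, seed = 5)))
  expect_identical(scoreValues(mdgImportance(f1)),
                   scoreValues(mdgImportance(f2)))
  f3 <- fitForest(d, ntree = 40, seed = 12)
  expect_false(identical(f1@inbag, f3@inbag))
})

test_that("mean OOB fraction approaches (1 - 1/n)^n", {
  d <- generateDataset(1500, 3, nClass = 2, nInformative = 1,
                      classSeparation = 1, seed = 6)
  fit <- fitForest(d, ntree = 250, nodesize = 400, seed = 7)
  expect_lt(abs(oobFraction(fit) - (1 - 1 / 1500)^1500), 0.01)
  set.seed(8)
  expect_lt(abs(mean(bootstrapOobFraction(5000, 100)) - 0.368), 0.005)
})

test_that("OOB accuracy is exact on separable data and excludes unvoted samples", {
  d <- generateDataset(60, 3, nClass = 2, nInformative = 1,
                      classSeparation = 20, noiseSd = 0.1, seed = 10)
  fit <- fitForest(d, ntree = 150, seed = 1)
  expect_equal(oobAccuracy(fit, d), 1.0)

  # near-separable two-class data: accuracy at least 0.95
  d2 <- generateDataset(200, 5, nClass = 2, nInformative = 2,
                       classSeparation = 4, seed = 11)
  fit2 <- fitForest(d2, ntree = 500, seed = 2)
  expect_gte(oobAccuracy(fit2, d2), 0.95)
})

test_that("configuration errors are caught", {
  d <- easyDataset(30, 4, seed = 12)
  expect_error(fitForest(d, ntree = 10, mtry = 9, seed = 1), "mtry")
  X <- featureMatrix(d)
  expect_error(VimDataset(X, rep("a", nrow(X))), "class")
})

test_that("MDA is exactly zero for constant (never-split) features", {
  X <- cbind(f1 = rnorm(80) + rep(c(0, 4), each = 40), f2 = rep(1, 80),
             f3 = rnorm(80))
  d <- VimDataset(X, rep(c("a", "b"), each = 40))
  fit <- fitForest(d, ntree = 100, mtry = 2, seed = 13)
  mda <- scoreValues(mdaImportance(fit, d, seed = 14))
  mdg <- scoreValues(mdgImportance(fit))
  expect_identical(mda[["f2"]], 0)
  expect_identical(mdg[["f2"]], 0)
  expect_gt(mda[["f1"]], 0)
})

test_that("MDG satisfies the per-tree conservation identity", {
  d <- generateDataset(120, 8, nClass = 3, nInformative = 3,
                      classSeparation = 1.5, seed = 15)
  fit <- fitForest(d, ntree = 60, seed = 16)
  mdg <- scoreValues(mdgImportance(fit))
  perTree <- vapply(fit@trees, function(t) sum(t$dec[t$var >= 0L]),
                    numeric(1))
  expect_equal(sum(mdg), mean(perTree), tolerance = 1e-10)
})

test_that("a single perfectly separating feature dominates both measures", {
  set.seed(17)
  top <- replicate(20, {
    seed <- sample.int(1e6, 1)
    d <- generateDataset(80, 5, nClass = 2, nInformative = 1,
                        classSeparation = 5, seed = seed)
    fit <- fitForest(d, ntree = 500, seed = seed + 1)
    c(rankedFeatures(rankFeatures(mdaImportance(fit, d, seed + 2)))[1],
      rankedFeatures(rankFeatures(mdgImportance(fit)))[1])
  })
  expect_gte(sum(top[1, ] == "f1"), 19)
  expect_gte(sum(top[2, ] == "f1"), 19)
})

test_that("importance agrees with the reference forest implementation", {
  skip_if_not_installed("randomForest")
  d <- generateDataset(150, 10, nClass = 2, nInformative = 4,
                      classSeparation = 2, separationDecay = 0.7, seed = 18)
  fit <- fitForest(d, ntree = 500, seed = 19)
  ourMdg <- scoreValues(mdgImportance(fit))
  ourMda <- scoreValues(mdaImportance(fit, d, seed = 20))
  rf <- randomForest::randomForest(featureMatrix(d), classLabels(d),
                                   ntree = 500, importance = TRUE)
  imp <- randomForest::importance(rf, scale = FALSE)
  expect_gt(cor(ourMdg, imp[, "MeanDecreaseGini"], method = "spearman"), 0.8)
  expect_gt(cor(ourMda, imp[, "MeanDecreaseAccuracy"], method = "spearman"),
            0.8)
  expect_lt(abs(oobAccuracy(fit, d) - (1 - rf$err.rate[500, "OOB"])), 0.05)
})

test_that("feature ranking sorts by score with positional tie-breaks", {
  r <- rankFeatures(c(x1 = 0.5, x2 = 0.9, x3 = 0.2))
  expect_equal(rankedFeatures(r), c("x2", "x1", "x3"))
  expect_equal(featurePositions(r), c(x1 = 2L, x2 = 1L, x3 = 3L))

  tied <- rankFeatures(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(rankedFeatures(tied), c("a", "b", "c", "d"))

  set.seed(21)
  for (i in 1:5) {
    s <- stats::setNames(rnorm(20), paste0("f", 1:20))
    expect_equal(rankedFeatures(rankFeatures(s)),
                 names(s)[order(-s, seq_along(s))])
  }
})
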