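test_that("symbolic mtry settings resolve and clamp correctly", {
  expect_equal(vapply(c("one", "dwdef", "def", "updef"), resolveMtry,
                      integer(1), d = 100),
               c(one = 1L, dwdef = 5L, def = 10L, updef = 15L))
  expect_equal(resolveMtry("def", 2), 1L)
  expect_equal(resolveMtry("dwdef", 2), 1L)
  expect_equal(resolveMtry("updef", 2), 2L)
  expect_equal(vapply(c("one", "dwdef", "def", "updef"), resolveMtry,
                      integer(1), d = 1),
               c(one = 1L, dwdef = 1L, def = 1L, updef = 1L))
  expect_equal(resolveMtry(7, 5), 5L)
})

test_that("intrinsic protocol yields k(k-1)/2 pairs and is replayable", {
  d <- easyDataset(60, 6, seed = 30)
  ex <- runIntrinsic(d, "mdg", kRuns = 4, ntree = 30, seed = 31)
  for (ix in c("spearman", "jaccard", "kuncheva", "mard"))
    expect_equal(length(pairwiseValues(ex@results[[ix]])), 6)
  expect_equal(ex@method, "MDG")

  ex2 <- runIntrinsic(d, "mdg", kRuns = 4, ntree = 30, seed = 31)
  for (ix in names(ex@results))
    expect_identical(pairwiseValues(ex@results[[ix]]),
                     pairwiseValues(ex2@results[[ix]]))

  # the stored seed ledger replays a run bit-exactly
  s <- ex@seeds$runs[[2]]
  fit <- fitForest(d, ntree = 30, seed = s$fit)
  expect_true(is(mdgImportance(fit), "ImportanceScores"))
  expect_identical(scoreValues(mdgImportance(fit)),
                   scoreValues(mdgImportance(
                     fitForest(d, ntree = 30, seed = s$fit))))
})

test_that("identical runs give perfect rank stability and zero MARD", {
  d <- easyDataset(50, 5, seed = 32)
  fit <- fitForest(d, ntree = 40, seed = 33)
  run <- mdgImportance(fit)
  for (ix in c("spearman", "jaccard", "kuncheva"))
    expect_equal(pairwiseValues(kwayStability(list(run, run), ix)), 1)
  expect_equal(pairwiseValues(kwayStability(list(run, run), "mard")), 0)
})

test_that("mtry symbols resolving to the same value reproduce the same fit", {
  d <- generateDataset(40, 1, nClass = 2, nInformative = 1,
                      classSeparation = 2, seed = 34)
  f1 <- fitForest(d, ntree = 25, mtry = "one", seed = 35)
  f2 <- fitForest(d, ntree = 25, mtry = 1, seed = 35)
  expect_identical(scoreValues(mdgImportance(f1)),
                   scoreValues(mdgImportance(f2)))
})

test_that("perturbation protocol pairs folds and nests the intrinsic arm", {
  d <- generateDataset(80, 6, nClass = 2, nInformative = 2,
                      classSeparation = 2, seed = 36)
  px <- runPerturbation(d, "mdg", folds = 5, kRuns = 3, ntree = 25,
                        seed = 37)
  expect_equal(length(pairwiseValues(px@variation$spearman)), 10) # 5 choose 2
  expect_equal(length(pairwiseValues(px@intrinsic$spearman)), 3)  # 3 choose 2

  # averaging order: per-fold stability means, then average over folds
  for (ix in c("spearman", "jaccard", "kuncheva", "mard")) {
    perFold <- px@perUnit$mean[px@perUnit$index == ix]
    expect_equal(length(perFold), 5)
    expect_equal(stabilityMean(px@intrinsic[[ix]]), mean(perFold),
                 tolerance = 1e-12)
  }

  px2 <- runPerturbation(d, "mdg", folds = 5, kRuns = 3, ntree = 25,
                         seed = 37)
  expect_identical(pairwiseValues(px2@variation$mard),
                   pairwiseValues(px@variation$mard))
})

test_that("a fold that loses a class is reported by name", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  d <- VimDataset(X, c(rep("maj", 9), "min"))
  expect_error(runPerturbation(d, "mdg", folds = 5, kRuns = 2, ntree = 10,
                               seed = 38), "fold [0-9]+ lost a class")
})

test_that("parameter-variation protocols cover the grid with paired arms", {
  d <- easyDataset(60, 6, seed = 39)
  nx <- runNtreeVariation(d, "mdg", ntreeGrid = c(20, 50, 100), kRuns = 3,
                          seed = 40)
  expect_equal(length(pairwiseValues(nx@variation$spearman)), 3) # 3 choose 2
  expect_equal(length(pairwiseValues(nx@intrinsic$spearman)), 3) # 3 choose 2
  expect_equal(sort(unique(nx@perUnit$setting)), c("100", "20", "50"))

  mx <- runMtryVariation(d, "mdg", mtryGrid = c("one", "def"), ntree = 30,
                         kRuns = 3, seed = 41)
  expect_equal(length(pairwiseValues(mx@variation$jaccard)), 1)
  expect_equal(mx@params$settings, c("one", "def"))
})

test_that("the derived seed stream is deterministic and in integer range", {
  a <- vimstab:::childSeed(1, 2, 3)
  expect_identical(a, vimstab:::childSeed(1, 2, 3))
  expect_false(a == vimstab:::childSeed(1, 3, 2))
  s <- vapply(1:500, function(i) vimstab:::childSeed(42, i), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_gt(length(unique(s)), 495)
})
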