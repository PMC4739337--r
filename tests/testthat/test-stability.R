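test_that("truncation keeps the leading features in order", {
  r <- mkRanking(paste0("f", 1:8))
  expect_equal(truncateRanking(r, 100), paste0("f", 1:8))
  expect_equal(truncateRanking(r, 3), c("f1", "f2", "f3"))
  expect_equal(truncateRanking(r, 1), "f1")
})

test_that("Spearman stability matches hand-computed values", {
  g <- mkRanking(c("x1", "x2", "x3"))
  expect_equal(spearmanStability(g, g), 1.0)
  expect_equal(spearmanStability(g, mkRanking(c("x1", "x3", "x2"))), 0.5)
  fwd <- mkRanking(paste0("f", 1:7))
  rev <- mkRanking(paste0("f", 7:1))
  expect_equal(spearmanStability(fwd, rev), -1.0)
  expect_error(spearmanStability(mkRanking("a"), mkRanking("a")), "single")
})

test_that("Spearman under truncation re-ranks within the top-set union", {
  set.seed(1)
  ids <- paste0("f", 1:50)
  g <- mkRanking(sample(ids))
  h <- mkRanking(sample(ids))
  u <- spearmanStability(g, h, cap = 10)
  expect_equal(u, naiveSpearman(rankedFeatures(g), rankedFeatures(h),
                                cap = 10), tolerance = 1e-12)
  i <- spearmanStability(g, h, cap = 10, truncated = "intersection")
  expect_true(u >= -1 && u <= 1 && i >= -1 && i <= 1)
  expect_equal(spearmanStability(g, g, cap = 10), 1.0)
})

test_that("Jaccard stability matches hand-computed prefix averages", {
  g <- mkRanking(c("x1", "x2", "x3"))
  expect_equal(jaccardStability(g, g), 1.0)
  # prefixes j=1: {x1}/{x1} = 1; j=2: {x1,x2} vs {x1,x3} = 1/3
  expect_equal(jaccardStability(g, mkRanking(c("x1", "x3", "x2"))),
               (1 + 1 / 3) / 2, tolerance = 1e-12)
  # disjoint top-3 prefixes at every j (d = 6 > 2 * cap)
  g6 <- mkRanking(c("a", "b", "c", "d", "e", "f"))
  h6 <- mkRanking(c("d", "e", "f", "a", "b", "c"))
  expect_equal(jaccardStability(g6, h6, cap = 3), 0.0)
})

test_that("Kuncheva stability matches hand computation and corrects chance", {
  g <- mkRanking(c("x1", "x2", "x3"))
  expect_equal(kunchevaStability(g, g), 1.0)
  # j=1 term 1; j=2 term (1 - 4/3)/(2 - 4/3) = -0.5
  expect_equal(kunchevaStability(g, mkRanking(c("x1", "x3", "x2"))),
               0.25, tolerance = 1e-12)
  # independent random rankings average ~0 (chance-corrected)
  set.seed(2)
  ids <- paste0("f", 1:60)
  vals <- replicate(400, kunchevaStability(mkRanking(sample(ids)),
                                           mkRanking(sample(ids)), cap = 30))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("MARD matches hand-computed values and the union rule", {
  g <- mkScores(c(f1 = 0.2, f2 = 0.1))
  h <- mkScores(c(f1 = 0.1, f2 = 0.1))
  expect_equal(as.numeric(mard(g, h)), (0.1 / 0.15 + 0) / 2,
               tolerance = 1e-12)
  expect_equal(as.numeric(mard(g, g)), 0.0)
  # terms with zero score sum contribute zero
  a <- mkScores(c(f1 = 0.3, f2 = 0.1, f3 = 0))
  b <- mkScores(c(f1 = 0.3, f2 = -0.1, f3 = 0))
  m <- mard(a, b)
  expect_equal(as.numeric(m), 0 / 3, tolerance = 1e-12)
  expect_equal(attr(m, "zeroDenominator"), 1L)
  # union size stays between cap and 2*cap when d > cap
  set.seed(3)
  sg <- stats::setNames(rnorm(250), paste0("f", 1:250))
  sh <- stats::setNames(rnorm(250), paste0("f", 1:250))
  ug <- truncateRanking(rankFeatures(sg), 100)
  uh <- truncateRanking(rankFeatures(sh), 100)
  expect_true(length(union(ug, uh)) >= 100 && length(union(ug, uh)) <= 200)
  expect_equal(as.numeric(mard(mkScores(sg), mkScores(sh))),
               naiveMard(sg, sh), tolerance = 1e-12)
  expect_error(mard(a, mkScores(c(f1 = 1, f2 = 0, f3 = 0), "MDG")),
               "different methods")
})

test_that("pairwise indices are symmetric, bounded and relabel-invariant", {
  set.seed(4)
  for (d in c(5, 30, 150)) {
    ids <- paste0("f", seq_len(d))
    for (rep in 1:5) {
      g <- mkRanking(sample(ids))
      h <- mkRanking(sample(ids))
      sp <- spearmanStability(g, h, cap = 20)
      ja <- jaccardStability(g, h, cap = 20)
      ku <- kunchevaStability(g, h, cap = 20)
      expect_identical(sp, spearmanStability(h, g, cap = 20))
      expect_identical(ja, jaccardStability(h, g, cap = 20))
      expect_identical(ku, kunchevaStability(h, g, cap = 20))
      expect_true(sp >= -1 && sp <= 1)
      expect_true(ja >= 0 && ja <= 1)
      expect_lte(ku, 1)
      expect_identical(spearmanStability(g, g, cap = 20), 1)
      expect_identical(jaccardStability(g, g, cap = 20), 1)
      expect_identical(kunchevaStability(g, g, cap = 20), 1)

      # consistent relabeling of both rankings changes nothing
      relab <- stats::setNames(paste0("g", sample(d)), ids)
      g2 <- mkRanking(unname(relab[rankedFeatures(g)]))
      h2 <- mkRanking(unname(relab[rankedFeatures(h)]))
      expect_identical(sp, spearmanStability(g2, h2, cap = 20))
      expect_identical(ja, jaccardStability(g2, h2, cap = 20))
      expect_identical(ku, kunchevaStability(g2, h2, cap = 20))
    }
  }
})

test_that("k-way stability stores all pairs and reduces correctly", {
  set.seed(5)
  runs <- lapply(1:3, function(i)
    mkScores(stats::setNames(rnorm(12), paste0("f", 1:12))))
  res <- kwayStability(runs, "spearman")
  expect_equal(length(pairwiseValues(res)), 3)
  expect_equal(stabilityMean(res), mean(pairwiseValues(res)))
  expect_equal(stabilityVariance(res), var(pairwiseValues(res)))
  expect_equal(nRuns(res), 3)

  same <- kwayStability(list(runs[[1]], runs[[1]], runs[[1]]), "jaccard")
  expect_equal(pairwiseValues(same), rep(1, 3))
  expect_equal(stabilityVariance(same), 0)
  expect_equal(pairwiseValues(
    kwayStability(list(runs[[1]], runs[[1]]), "mard")), 0)
  expect_error(kwayStability(runs[1], "spearman"), "at least 2")
})

test_that("box summary reports quartiles, whiskers and the notch rule", {
  x <- as.numeric(1:100)
  s <- boxplotSummary(x)
  expect_equal(s$iqr, unname(diff(quantile(x, c(0.25, 0.75)))))
  expect_equal(s$notchHigh - s$notchLow, 3.14 * s$iqr / sqrt(100),
               tolerance = 1e-12)
  expect_equal(s$median, 50.5)

  const <- boxplotSummary(rep(0.7, 9))
  expect_equal(const$iqr, 0)
  expect_equal(length(const$outliers), 0)
  expect_equal(const$notchHigh, const$notchLow)

  set.seed(6)
  y <- c(rnorm(50), 8, -9)
  sy <- boxplotSummary(y)
  expect_gte(sy$whiskerLow, sy$q1 - 1.5 * sy$iqr)
  expect_lte(sy$whiskerHigh, sy$q3 + 1.5 * sy$iqr)
  expect_true(all(c(8, -9) %in% sy$outliers))
  expect_true(all(c(sy$whiskerLow, sy$whiskerHigh) %in% y))
  expect_error(boxplotSummary(numeric(0)), "empty")
})
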