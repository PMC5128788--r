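test_that("exhaustive smoothed TAC equals the brute-force ordering average", {
  ct <- toyTable()
  m <- counts(ct)
  # independent enumeration: all 3! orderings, union richness of first k
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  brute <- sapply(1:3, function(k) {
    mean(sapply(perms, function(p) {
      sum(rowSums(m[, p[seq_len(k)], drop = FALSE]) > 0)
    }))
  })
  tac <- smoothedTAC(ct, a = 0, exhaustive = TRUE)
  expect_equal(tac@mean, brute, tolerance = 1e-12)
  expect_identical(tac@nPerm, 6L)
})

test_that("Monte-Carlo richness TAC agrees with the analytic expectation", {
  set.seed(42)
  ct <- makeStudy(communitySpec(80, "lognormal", sigma = 1.5, seed = 5),
                  nSamples = 8, depthPerSample = 150, seed = 6)
  nPerm <- 200
  tac <- smoothedTAC(ct, a = 0, nPerm = nPerm, seed = 9)
  ana <- expectedTAC(ct)
  se <- tac@sd / sqrt(nPerm)
  for (k in seq_along(tac@steps)) {
    expect_lte(abs(tac@mean[k] - ana@mean[k]), 3 * se[k] + 1e-9)
  }
  # final point is the pooled richness exactly, for both routes
  pooledS <- observedRichness(poolSamples(ct))
  expect_equal(tac@mean[length(tac@mean)], pooledS)
  expect_equal(ana@mean[length(ana@mean)], pooledS, tolerance = 1e-9)
})

test_that("TACs are deterministic under a seed and flat for copied samples", {
  ct <- toyTable()
  t1 <- smoothedTAC(ct, 1, nPerm = 25, seed = 4)
  t2 <- smoothedTAC(ct, 1, nPerm = 25, seed = 4)
  expect_identical(t1@mean, t2@mean)
  expect_identical(t1@sd, t2@sd)
  t3 <- smoothedTAC(ct, 1, nPerm = 25, seed = 5)
  expect_false(identical(t1@mean, t3@mean))
  # identical samples: pooling copies preserves proportions, curve is flat
  one <- c(9, 3, 1, 1)
  flat <- communityTable(matrix(rep(one, 4), ncol = 4,
                                dimnames = list(paste0("t", 1:4),
                                                paste0("s", 1:4))))
  for (a in c(0, 1, 2)) {
    tac <- smoothedTAC(flat, a, nPerm = 10, seed = 1)
    expect_equal(tac@mean, rep(hillNumber(one, a), 4), tolerance = 1e-12)
    expect_equal(tac@sd, rep(0, 4), tolerance = 1e-12)
  }
  # richness TAC never exceeds the pooled richness and is non-decreasing
  set.seed(8)
  ct2 <- communityTable(matrix(rpois(60, 1.2) + rbinom(60, 1, 0.3), 12,
                               dimnames = list(paste0("t", 1:12),
                                               paste0("s", 1:5))))
  tac0 <- smoothedTAC(ct2, 0, nPerm = 40, seed = 2)
  expect_true(all(diff(tac0@mean) >= -1e-12))
  expect_true(all(tac0@mean <= observedRichness(poolSamples(ct2)) + 1e-12))
  expect_error(smoothedTAC(communityTable(matrix(1:3, 3, 1)), 0),
               "2 samples")
})

test_that("read subsampling is exact at the boundaries and deterministic", {
  v <- abundanceVector(c(50, 30, 20, 0, 1))
  expect_identical(counts(subsampleReads(v, totalReads(v), seed = 1)),
                   counts(v))
  one <- subsampleReads(v, 1, seed = 3)
  expect_equal(totalReads(one), 1)
  expect_equal(sum(counts(one) > 0), 1)
  s1 <- subsampleReads(v, 40, seed = 7)
  s2 <- subsampleReads(v, 40, seed = 7)
  expect_identical(counts(s1), counts(s2))
  expect_equal(totalReads(s1), 40)
  expect_true(all(counts(s1) <= counts(v)))
  expect_error(subsampleReads(v, 102, seed = 1), "102.*101")
  # with-replacement option permits depth > N
  big <- subsampleReads(v, 200, seed = 2, replace = TRUE)
  expect_equal(totalReads(big), 200)
})

test_that("mean subsampled richness matches hypergeometric rarefaction", {
  set.seed(10)
  x <- c(rpois(40, 3), rep(1, 10), rep(2, 5))
  x[x == 0] <- 1
  v <- abundanceVector(x)
  d <- floor(totalReads(v) / 3)
  nDraw <- 300
  sObs <- vapply(seq_len(nDraw), function(i) {
    observedRichness(subsampleReads(v, d, seed = 100 + i))
  }, numeric(1))
  exp3 <- expectedRichness(v, d)
  # vegan::rarefy is the independent closed-form oracle
  expect_equal(exp3, as.numeric(vegan::rarefy(x, d)), tolerance = 1e-8)
  se <- sd(sObs) / sqrt(nDraw)
  expect_lte(abs(mean(sObs) - exp3), 3 * se)
})

test_that("the stability criterion matches its closed-form evaluation", {
  expect_equal(stabilityScore(1:10, rep(5, 10)),
               list(reached = TRUE, atStep = 1, index = 1L))
  expect_false(stabilityScore(1:10, 10 * (1:10))$reached)
  # saturating curve C(x) = S (1 - exp(-x / tau))
  S <- 100; tau <- 15
  x <- seq(5, 150, by = 5)
  C <- S * (1 - exp(-x / tau))
  got <- stabilityScore(x, C, windowFrac = 0.1, tol = 0.02)
  # independent evaluation of the declared criterion on the analytic curve
  eligible <- x <= max(x) - 0.1 * (max(x) - min(x))
  ok <- vapply(seq_along(x), function(j) {
    max(abs(C[j:length(C)] - C[j])) / C[j] <= 0.02
  }, logical(1))
  firstJ <- which(eligible & ok)[1]
  expect_true(got$reached)
  expect_equal(got$atStep, x[firstJ])
  expect_error(stabilityScore(1:4, 1:5), "length")
  expect_error(stabilityScore(1:2, 1:2), "3 steps")
})

test_that("depth analysis reproduces full-depth values and orders stability", {
  v <- abundanceVector(c(40, 25, 10, 5, 5, 3, 3, 2, 2, 2, 1, 1, 1))
  N <- totalReads(v)
  da <- depthAnalysis(v, depths = c(20, 50, N), orders = c(0, 2),
                      reps = 3, seed = 5)
  expect_equal(dim(da@values), c(3, 3, 2))
  # at depth N every replicate is exactly the full-data value
  expect_equal(unname(da@values[, 3, 1]), rep(sum(counts(v) > 0), 3))
  expect_equal(unname(da@values[, 3, 2]),
               rep(hillNumber(unname(counts(v)), 2), 3), tolerance = 1e-12)
  # a uniform community with depth >> S stabilizes at the smallest depth
  u <- abundanceVector(rep(500, 10))
  du <- depthAnalysis(u, depths = c(600, 1200, 2500, 5000),
                      orders = c(0, 1, 2), reps = 4, seed = 2)
  expect_equal(unname(stabilityDepth(du)), rep(600, 3))
  # determinism
  da2 <- depthAnalysis(v, depths = c(20, 50, N), orders = c(0, 2),
                       reps = 3, seed = 5)
  expect_identical(da@values, da2@values)
  expect_error(depthAnalysis(v, depths = c(10, 2 * N), reps = 3, seed = 1),
               "exceeds")
  expect_error(depthAnalysis(v, depths = c(10, 20), reps = 1, seed = 1),
               "reps")
})

test_that("the default depth grid spans 25k-400k clipped to the data", {
  g <- defaultDepthGrid(1e6)
  expect_equal(length(g), 8)
  expect_equal(g[1], 25000)
  expect_equal(g[8], 400000)
  g2 <- defaultDepthGrid(60000)
  expect_lte(max(g2), 60000)
  expect_equal(g2[1], 25000)
  g3 <- defaultDepthGrid(900)
  expect_true(all(g3 <= 900))
})
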