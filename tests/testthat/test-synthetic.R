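test_that("true community abundances follow the requested TAD", {
  expect_equal(makeCommunity(communitySpec(10, "uniform")), rep(0.1, 10))
  # zipf(1): weights 1, 1/2, 1/3 normalize to 6/11, 3/11, 2/11
  expect_equal(makeCommunity(communitySpec(3, "zipf", gamma = 1)),
               c(6, 3, 2) / 11, tolerance = 1e-14)
  p <- makeCommunity(communitySpec(1e4, "lognormal", mu = 0, sigma = 2,
                                   seed = 3))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_lt(p[1], 1)
  expect_true(all(diff(p) <= 0))
  # deterministic under the spec seed
  expect_identical(p, makeCommunity(communitySpec(1e4, "lognormal", mu = 0,
                                                  sigma = 2, seed = 3)))
  expect_error(communitySpec(10, "lognormal", sigma = -1), "sigma")
  expect_error(communitySpec(10, "zipf", gamma = 0), "gamma")
  expect_error(communitySpec(0, "uniform"), "positive integer")
})

test_that("sequencing draws are multinomial with the right moments", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  v <- sampleReads(p, 1, seed = 2)
  expect_equal(totalReads(v), 1)
  expect_equal(sum(counts(v) > 0), 1)
  big <- sampleReads(p, 1e5, seed = 4)
  expect_equal(totalReads(big), 1e5)
  # per-taxon frequencies within 3 binomial standard errors
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(counts(big) / 1e5 - p) <= 3 * se + 1e-12))
  expect_identical(counts(sampleReads(p, 100, seed = 9)),
                   counts(sampleReads(p, 100, seed = 9)))
  expect_error(sampleReads(c(0.5, 0.4), 10), "sum to 1")
  # heavy-tailed hyperdiverse community is undersampled at depth ~ S
  pp <- makeCommunity(communitySpec(1e4, "lognormal", sigma = 2, seed = 6))
  v2 <- sampleReads(pp, 1e4, seed = 6)
  expect_lt(observedRichness(v2), 1e4)
  # expected observed richness bound: sum of inclusion probabilities
  expInc <- sum(1 - (1 - pp)^1e4)
  expect_lt(expInc, 1e4)
  # Var(S_obs) <= sum q(1-q) (inclusion indicators are negatively correlated)
  expect_lte(abs(observedRichness(v2) - expInc),
             3 * sqrt(sum((1 - (1 - pp)^1e4) * (1 - pp)^1e4)))
})

test_that("studies have exact per-sample depths and honest pooled diversity", {
  spec <- communitySpec(150, "lognormal", sigma = 1.5, seed = 11)
  ct <- makeStudy(spec, nSamples = 6, depthPerSample = 2500, seed = 12)
  expect_equal(dim(counts(ct)), c(150, 6))
  expect_equal(unname(sampleSums(ct)), rep(2500, 6))
  # same seed, same study
  ct2 <- makeStudy(spec, nSamples = 6, depthPerSample = 2500, seed = 12)
  expect_identical(counts(ct), counts(ct2))
  # pooled reciprocal Simpson near the closed-form truth at large depth
  p <- makeCommunity(spec)
  trueN2 <- 1 / sum(p^2)
  pooled <- poolSamples(ct)
  expect_lt(abs(hillNumber(pooled, 2) - trueN2) / trueN2, 0.02)
  # overdispersion jitters per-sample composition but preserves depth
  ct3 <- makeStudy(spec, nSamples = 4, depthPerSample = 1000,
                   overdispersion = 0.01, seed = 13)
  expect_equal(unname(sampleSums(ct3)), rep(1000, 4))
  expect_error(makeStudy(spec, nSamples = 2, depthPerSample = 100,
                         overdispersion = -1), "overdispersion")
})

test_that("study presets encode the deep/shallow design contrast", {
  am <- studyPreset("amazon")
  tx <- studyPreset("texas")
  expect_identical(am$spec@tad, "lognormal")
  expect_identical(tx$spec@tad, "zipf")
  expect_equal(am$nSamples, 66L)
  expect_equal(tx$nSamples, 36L)
  expect_gt(am$nSamples * am$depthPerSample, 10 * tx$nSamples *
              tx$depthPerSample)
})
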