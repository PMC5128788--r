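test_that("uniform and single-taxon communities give the exact limits", {
  for (a in c(0, 0.5, 1, 1.3, 2, 3)) {
    expect_equal(hillNumber(c(1, 1, 1, 1), a), 4)
    expect_equal(hillNumber(c(7), a), 1)
  }
})

test_that("orders 1 and 2 match independent entropy/Simpson formulas", {
  x <- c(8, 4, 2, 1, 1)
  p <- x / sum(x)
  expect_equal(hillNumber(x, 2), 1 / sum(p^2), tolerance = 1e-12)
  expect_equal(hillNumber(x, 1), exp(-sum(p * log(p))), tolerance = 1e-12)
  # and against vegan's implementations
  expect_equal(hillNumber(x, 1), exp(vegan::diversity(x, "shannon")),
               tolerance = 1e-12)
  expect_equal(hillNumber(x, 2), vegan::diversity(x, "invsimpson"),
               tolerance = 1e-12)
})

test_that("profiles are monotone, bounded and continuous at a = 1", {
  orders <- seq(0, 3, by = 0.25)
  for (seed in 1:100) {
    x <- randCounts(seed)
    prof <- hillProfile(x, orders)
    v <- prof@values
    expect_true(all(diff(v) <= 1e-10 * pmax(1, v[-length(v)])))
    expect_true(all(v >= 1 - 1e-12))
    expect_true(all(v <= sum(x > 0) + 1e-9))
    n1 <- hillNumber(x, 1)
    expect_equal(hillNumber(x, 1 - 1e-8), n1, tolerance = 1e-6)
    expect_equal(hillNumber(x, 1 + 1e-8), n1, tolerance = 1e-6)
  }
})

test_that("diversity is invariant to depth replication and taxon order", {
  for (seed in 1:20) {
    x <- randCounts(seed)
    for (a in c(0, 0.5, 1, 2)) {
      expect_equal(hillNumber(2 * x, a), hillNumber(x, a),
                   tolerance = 1e-12)
      expect_equal(hillNumber(rev(x), a), hillNumber(x, a),
                   tolerance = 1e-12)
    }
    expect_equal(chao1(sample(x)), suppressMessages(chao1(x)))
    expect_equal(goodsCoverage(sample(x)), goodsCoverage(x))
  }
})

test_that("chao1 follows the F1/F2 formula with a bias-corrected fallback", {
  expect_equal(chao1(c(1, 1, 2, 2, 5)), 6)         # 5 + 2^2 / (2*2)
  expect_message(c0 <- chao1(c(3, 4, 5)), "bias-corrected")
  expect_equal(c0, 3)                               # no rare taxa
  expect_message(c1 <- chao1(c(1, 1, 1)), "bias-corrected")
  expect_equal(c1, 6)                               # 3 + 3*2/2
  for (seed in 1:20) {
    x <- randCounts(seed)
    expect_gte(suppressMessages(chao1(x)), sum(x > 0))
  }
})

test_that("Good's coverage is 1 - F1/N with the right extremes", {
  expect_equal(goodsCoverage(c(1, 2, 3)), 5 / 6)
  expect_equal(goodsCoverage(c(2, 3, 4)), 1)
  expect_equal(goodsCoverage(c(1, 1, 1, 1)), 0)
  for (seed in 1:20) {
    cv <- goodsCoverage(randCounts(seed))
    expect_gte(cv, 0); expect_lte(cv, 1)
  }
})

test_that("frequency counts tally abundances and satisfy conservation", {
  fc <- frequencyCounts(c(1, 1, 2, 5))
  expect_equal(fc, c("1" = 2, "2" = 1, "5" = 1))
  expect_equal(frequencyCounts(c(0, 0, 3)), c("3" = 1))
  for (seed in 1:20) {
    x <- randCounts(seed)
    fc <- frequencyCounts(x)
    k <- as.numeric(names(fc))
    expect_equal(sum(k * fc), sum(x))
    expect_equal(sum(fc), sum(x > 0))
  }
})

test_that("degenerate inputs are rejected across the estimator surface", {
  expect_error(hillNumber(c(0, 0), 1), "zero total")
  expect_error(hillNumber(c(1, 2), -0.5), "must be >= 0")
  expect_error(chao1(numeric(0)), "non-empty")
  expect_error(goodsCoverage(c(0, 0)), "zero total")
  expect_error(hillProfile(c(1, 2), c(2, 1)), "ascending")
})

test_that("the per-sample diversity table carries the documented columns", {
  ct <- toyTable()
  d <- diversityTable(ct)
  expect_identical(names(d), c("sample", "S_obs", "N_1", "N_2", "chao1",
                               "coverage", "F_1", "F_2", "N"))
  expect_identical(d$sample, c("A", "B", "C", "pooled"))
  pool <- counts(poolSamples(ct))
  expect_equal(d$N[4], sum(pool))
  expect_equal(d$S_obs[4], sum(pool > 0))
  expect_equal(d$N_2[4], hillNumber(unname(pool), 2))
})
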