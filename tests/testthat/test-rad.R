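test_that("log-normal loglik matches a term-by-term density sum", {
  x <- c(3, 7, 1, 12, 5, 2, 9, 30, 4, 6)
  f <- fitLognormal(abundanceVector(x))
  mu <- radParams(f)[["mu"]]; sigma <- radParams(f)[["sigma"]]
  # independent brute-force evaluation of the continuous log-normal density
  ll <- sum(log(1 / (x * sigma * sqrt(2 * pi)) *
                  exp(-(log(x) - mu)^2 / (2 * sigma^2))))
  expect_equal(radLogLik(f), ll, tolerance = 1e-10)
  expect_equal(radAIC(f), 2 * 2 - 2 * ll, tolerance = 1e-10)
  # ML closed form is a maximum: nudging either parameter lowers loglik
  llAt <- function(m, s) sum(dlnorm(x, m, s, log = TRUE))
  expect_lt(llAt(mu + 0.05, sigma), ll)
  expect_lt(llAt(mu, sigma + 0.05), ll)
})

test_that("zipf loglik matches dmultinom and sits at the optimum", {
  x <- c(40, 20, 10, 6, 4)
  f <- fitZipf(abundanceVector(x))
  g <- radParams(f)[["gamma"]]
  pr <- (1:5)^(-g) / sum((1:5)^(-g))
  expect_equal(radLogLik(f),
               dmultinom(sort(x, decreasing = TRUE), prob = pr, log = TRUE),
               tolerance = 1e-10)
  llAt <- function(gg) {
    p <- (1:5)^(-gg) / sum((1:5)^(-gg))
    dmultinom(sort(x, decreasing = TRUE), prob = p, log = TRUE)
  }
  expect_lte(llAt(g + 0.05), radLogLik(f) + 1e-9)
  expect_lte(llAt(g - 0.05), radLogLik(f) + 1e-9)
  expect_equal(radParams(f)[["p1"]], pr[1], tolerance = 1e-10)
})

test_that("degenerate communities are flagged, not fatal", {
  eq <- fitLognormal(abundanceVector(c(4, 4, 4, 4)))
  expect_true(isDegenerate(eq))
  expect_equal(radParams(eq)[["mu"]], log(4))
  un <- fitZipf(abundanceVector(c(5, 5, 5, 5, 5)))
  expect_true(isDegenerate(un))
  expect_lt(radParams(un)[["gamma"]], 1e-3)
  expect_error(fitLognormal(abundanceVector(c(3, 5))), "3 observed taxa")
})

test_that("generating parameters are recovered on synthetic communities", {
  set.seed(21)
  x <- round(exp(rnorm(3000, 3, 1)))
  x <- x[x >= 1]
  f <- fitLognormal(abundanceVector(x))
  expect_lt(abs(radParams(f)[["mu"]] - 3), 0.05)
  expect_lt(abs(radParams(f)[["sigma"]] - 1), 0.05)
  v <- sampleReads(makeCommunity(communitySpec(500, "zipf", gamma = 1.2)),
                   1e5, seed = 8)
  fz <- fitZipf(v)
  expect_lt(abs(radParams(fz)[["gamma"]] - 1.2), 0.05)
})

test_that("model selection recovers the generating family and flags ties", {
  vL <- sampleReads(makeCommunity(communitySpec(400, "lognormal", sigma = 1.5,
                                                seed = 31)), 5e4, seed = 31)
  bestL <- selectModel(list(fitLognormal(vL), fitZipf(vL)))
  expect_identical(bestL@model, "lognormal")
  vZ <- sampleReads(makeCommunity(communitySpec(400, "zipf", gamma = 1.2)),
                    5e4, seed = 32)
  bestZ <- selectModel(list(fitLognormal(vZ), fitZipf(vZ)))
  expect_identical(bestZ@model, "zipf")
  sel <- attr(bestZ, "selection")
  expect_false(any(sel$tie))
  # identical AICs (same fit twice) set the tie flag
  fz <- fitZipf(vZ)
  expect_true(attr(selectModel(list(fz, fz)), "selection")$tie[1])
  # incomparable fits are rejected
  f1 <- fitZipf(abundanceVector(c(9, 5, 3, 2)))
  f2 <- fitZipf(abundanceVector(c(9, 5, 3)))
  expect_error(selectModel(list(f1, f2)), "different numbers of taxa")
  f3 <- fitZipf(abundanceVector(c(10, 4, 3, 2)))
  expect_error(selectModel(list(f1, f3)), "different count vectors")
})

test_that("every fit satisfies the AIC identity", {
  for (seed in c(3, 4, 5)) {
    v <- sampleReads(makeCommunity(communitySpec(100, "lognormal",
                                                 sigma = 1.2, seed = seed)),
                     5000, seed = seed)
    for (f in list(fitLognormal(v), fitZipf(v)))
      expect_equal(radAIC(f), 2 * f@nPar - 2 * radLogLik(f),
                   tolerance = 1e-10)
  }
})

test_that("the deviation test is deterministic, bounded and powered", {
  v <- sampleReads(makeCommunity(communitySpec(300, "lognormal", mu = 3,
                                               sigma = 1, seed = 41)),
                   2e4, seed = 41)
  d1 <- deviationTest(v, nBoot = 199, seed = 9)
  d2 <- deviationTest(v, nBoot = 199, seed = 9)
  expect_identical(d1@D, d2@D)
  expect_identical(d1@pValue, d2@pValue)
  S <- observedRichness(v)
  expect_gte(d1@D, 1 / (2 * S))  # attainable sup-norm floor
  expect_lte(d1@D, 1)
  expect_gt(d1@pValue, 0)        # +1 correction: never exactly 0
  expect_gte(d1@pValue, 1 / 200)
  # a heavy-tailed Zipf community is firmly rejected against log-normal
  vz <- sampleReads(makeCommunity(communitySpec(800, "zipf", gamma = 1.2)),
                    5e4, seed = 42)
  expect_lte(deviationTest(vz, nBoot = 199, seed = 10)@pValue, 0.01)
  expect_error(deviationTest(v, nBoot = 50), ">= 99")
})
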