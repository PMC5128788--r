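# Taxon-abundance distribution (TAD) models: maximum-likelihood log-normal
# and Zipf fits, AIC-based model selection, and a parametric-bootstrap
# deviation test against the log-normal model.
#
# Conventions: the Zipf model is a rank model (expected relative abundance
# p_1 * r^-gamma at rank r, multinomial read likelihood); the log-normal is
# a distribution of log-abundances with counts treated as continuous (no
# Poisson compounding, no veil-line truncation). Because those two native
# likelihoods live on different scales (per-taxon density vs per-read
# multinomial), selectModel() compares models on a common multinomial
# footing derived from each fit's implied rank proportions.

.positiveSorted <- function(v, op) {
  stopifnot(is(v, "AbundanceVector"))
  x <- v@counts[v@counts > 0]
  if (length(x) < 3L)
    stop(op, " needs at least 3 observed taxa (got ", length(x), ")",
         call. = FALSE)
  sort(x, decreasing = TRUE)
}

# sup-norm distance between the ecdf of y and Normal(mu, sigma), both sides
# of every jump
.ksStat <- function(y, mu, sigma) {
  y <- sort(y)
  n <- length(y)
  Fy <- pnorm(y, mean = mu, sd = sigma)
  i <- seq_len(n)
  max(pmax(i / n - Fy, Fy - (i - 1) / n))
}

#' Fit a log-normal taxon-abundance distribution
#'
#' Maximum-likelihood fit of a log-normal to the positive counts, treating
#' abundances as continuous: mu and sigma are the ML mean and sd of
#' log-abundance (sigma uses the 1/S ML normalization). A community in
#' which every taxon has the same count drives sigma to its 0 boundary; the
#' fit is then flagged degenerate rather than failing.
#'
#' @param v an \linkS4class{AbundanceVector} with >= 3 observed taxa.
#' @return A \linkS4class{RADFitResult} (model \code{"lognormal"}, 2
#'   parameters).
#' @examples
#' v <- makeCommunity(communitySpec(200, "lognormal", mu = 3, sigma = 1,
#'                                  seed = 1))
#' fitLognormal(sampleReads(v, 5e4, seed = 1))
#' @export
fitLognormal <- function(v) {
  x <- .positiveSorted(v, "fitLognormal")
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  degenerate <- sigma < 1e-8
  if (degenerate)
    sigma <- 1e-8
  ll <- sum(dlnorm(x, meanlog = mu, sdlog = sigma, log = TRUE))
  new("RADFitResult", model = "lognormal",
      params = c(mu = mu, sigma = sigma),
      logLik = ll, aic = 2 * 2 - 2 * ll, nPar = 2L,
      nTaxa = length(x), rankCounts = x, degenerate = degenerate)
}

# normalized Zipf rank proportions r^-gamma / H(gamma, S)
.zipfRankProbs <- function(S, gamma) {
  w <- seq_len(S)^(-gamma)
  w / sum(w)
}

# rank proportions implied by a log-normal RAD: expected log-abundance at
# rank r is mu + sigma * z_r with z_r the normal quantile of rank r's
# plotting position; mu cancels under normalization
.lognormalRankProbs <- function(S, sigma) {
  z <- qnorm((S - seq_len(S) + 0.5) / S)
  w <- exp(sigma * z - max(sigma * z))
  w / sum(w)
}

.multinomLogLik <- function(rankCounts, probs) {
  N <- sum(rankCounts)
  lgamma(N + 1) - sum(lgamma(rankCounts + 1)) +
    sum(rankCounts * log(probs))
}

#' Fit a Zipf rank-abundance model
#'
#' Models expected relative abundance at rank r as p_1 * r^-gamma and fits
#' gamma by maximizing the multinomial likelihood of the rank-ordered
#' counts; p_1 is the normalization 1 / sum(r^-gamma) and is reported with
#' the fit. A uniform community drives gamma to its 0 boundary and is
#' flagged degenerate.
#'
#' @param v an \linkS4class{AbundanceVector} with >= 3 observed taxa.
#' @return A \linkS4class{RADFitResult} (model \code{"zipf"}, 1 free
#'   parameter).
#' @examples
#' v <- makeCommunity(communitySpec(200, "zipf", gamma = 1.2))
#' fitZipf(sampleReads(v, 5e4, seed = 1))
#' @export
fitZipf <- function(v) {
  x <- .positiveSorted(v, "fitZipf")
  S <- length(x)
  negll <- function(gamma) -.multinomLogLik(x, .zipfRankProbs(S, gamma))
  opt <- optimize(negll, interval = c(1e-8, 20), tol = 1e-9)
  gamma <- opt$minimum
  degenerate <- gamma < 1e-4
  if (degenerate)
    gamma <- max(gamma, 1e-8)
  ll <- -negll(gamma)
  new("RADFitResult", model = "zipf",
      params = c(gamma = gamma, p1 = .zipfRankProbs(S, gamma)[1L]),
      logLik = ll, aic = 2 * 1 - 2 * ll, nPar = 1L,
      nTaxa = S, rankCounts = x, degenerate = degenerate)
}

# AIC of a fit on the common multinomial-rank footing used for selection
.commonAIC <- function(fit) {
  probs <- switch(fit@model,
                  zipf = .zipfRankProbs(fit@nTaxa, fit@params[["gamma"]]),
                  lognormal = .lognormalRankProbs(fit@nTaxa,
                                                  fit@params[["sigma"]]))
  2 * fit@nPar - 2 * .multinomLogLik(fit@rankCounts, probs)
}

#' Select the best-fitting taxon-abundance model
#'
#' Compares fits of different model families to the same community and
#' returns the one with minimal AIC. Because the families' native
#' likelihoods are not on a common scale, the comparison uses the
#' multinomial likelihood of the rank-ordered counts under each fitted
#' model's implied rank proportions (see the package vignette). Ties are
#' broken toward fewer parameters, then lexicographic model name, and are
#' flagged.
#'
#' @param fits list of \linkS4class{RADFitResult} objects fitted to the same
#'   abundance vector.
#' @return The winning \linkS4class{RADFitResult}, with an attribute
#'   \code{"selection"}: a data.frame of model, nPar, common-scale AIC and a
#'   \code{tie} flag.
#' @examples
#' v <- sampleReads(makeCommunity(communitySpec(300, "zipf", gamma = 1.2)),
#'                  5e4, seed = 2)
#' best <- selectModel(list(fitLognormal(v), fitZipf(v)))
#' attr(best, "selection")
#' @export
selectModel <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("'fits' must be a list of >= 2 RADFitResult objects", call. = FALSE)
  if (!all(vapply(fits, is, logical(1), "RADFitResult")))
    stop("'fits' must contain RADFitResult objects", call. = FALSE)
  nTaxa <- vapply(fits, function(f) f@nTaxa, integer(1))
  if (length(unique(nTaxa)) != 1L)
    stop("fits cover different numbers of taxa (", paste(nTaxa,
         collapse = ", "), "): not comparable", call. = FALSE)
  rc <- lapply(fits, function(f) f@rankCounts)
  if (!all(vapply(rc[-1L], identical, logical(1), rc[[1L]])))
    stop("fits were made on different count vectors: not comparable",
         call. = FALSE)
  aics <- vapply(fits, .commonAIC, numeric(1))
  npars <- vapply(fits, function(f) f@nPar, integer(1))
  models <- vapply(fits, function(f) f@model, character(1))
  ord <- order(aics, npars, models)
  tie <- sum(abs(aics - min(aics)) < 1e-9) > 1L
  best <- fits[[ord[1L]]]
  attr(best, "selection") <- data.frame(model = models, nPar = npars,
                                        aic = aics, tie = tie,
                                        stringsAsFactors = FALSE)
  best
}

#' Deviation test against the log-normal model
#'
#' Tests whether the observed abundances deviate from a fitted log-normal:
#' D is the sup-norm distance between the empirical CDF of log observed
#' abundances and the fitted log-normal CDF. Because (mu, sigma) are
#' estimated from the same data, the p-value comes from a parametric
#' bootstrap in which every replicate is re-drawn from the fitted model
#' (counts re-discretized by rounding, zeros dropped, mirroring how integer
#' read counts arise) and the model refitted before recomputing D*
#' (Lilliefors-type correction). p = (1 + #\{D* >= D\}) / (nBoot + 1), so it
#' is never exactly 0.
#'
#' @param v an \linkS4class{AbundanceVector} with >= 3 observed taxa.
#' @param nBoot number of bootstrap replicates (>= 99, default 999).
#' @param seed integer seed; same seed, same p-value.
#' @return A \linkS4class{DeviationResult}.
#' @examples
#' v <- sampleReads(makeCommunity(communitySpec(300, "lognormal", mu = 3,
#'                                              sigma = 1, seed = 3)),
#'                  5e4, seed = 3)
#' deviationTest(v, nBoot = 199, seed = 1)
#' @export
deviationTest <- function(v, nBoot = 999L, seed = 1L) {
  if (nBoot < 99L)
    stop("'nBoot' must be >= 99", call. = FALSE)
  fit <- fitLognormal(v)
  x <- fit@rankCounts
  S <- length(x)
  D <- .ksStat(log(x), fit@params[["mu"]], fit@params[["sigma"]])
  Dstar <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      xs <- numeric(0)
      for (try in 1:100) {
        xs <- round(exp(rnorm(S, fit@params[["mu"]], fit@params[["sigma"]])))
        xs <- xs[xs >= 1]
        if (length(xs) >= 3L) break
      }
      lx <- log(xs)
      mu <- mean(lx)
      sigma <- max(sqrt(mean((lx - mu)^2)), 1e-12)
      .ksStat(lx, mu, sigma)
    }, numeric(1))
  })
  p <- (1 + sum(Dstar >= D)) / (nBoot + 1)
  new("DeviationResult", D = D, pValue = p, nBoot = as.integer(nBoot))
}
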