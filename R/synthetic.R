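# Synthetic community generator.
#
# Emulates the statistical structure the pipeline assumes: hyperdiverse
# communities with log-normal or Zipf taxon-abundance distributions, a large
# rare tail (many singletons/doubletons once sampled), multi-sample studies
# of tens of samples, and total read depths of roughly 25,000-400,000.
# Sequencing error (artifactual singletons) is deliberately not modeled.

#' True relative abundances of a synthetic community
#'
#' Log-normal communities draw per-taxon weights exp(Normal(mu, sigma)) under
#' the spec's seed; Zipf (rank r weight r^-gamma) and uniform communities are
#' deterministic. Abundances are returned sorted decreasing and normalized
#' to sum to 1 (within 1e-12).
#'
#' @param spec a \linkS4class{CommunitySpec}.
#' @return Numeric vector of length \code{S} of true relative abundances.
#' @examples
#' makeCommunity(communitySpec(3, "zipf", gamma = 1))  # 6/11, 3/11, 2/11
#' @export
makeCommunity <- function(spec) {
  stopifnot(is(spec, "CommunitySpec"))
  w <- switch(spec@tad,
    uniform = rep(1, spec@S),
    zipf = seq_len(spec@S)^(-spec@gamma),
    lognormal = withSeed(spec@seed, exp(rnorm(spec@S, spec@mu, spec@sigma)))
  )
  p <- sort(w, decreasing = TRUE)
  p / sum(p)
}

#' Sample reads from a community (sequencing as multinomial sampling)
#'
#' Draws \code{depth} reads with replacement from the true relative
#' abundances — the idealization of sampling-by-sequencing, under which deep
#' but incomplete observation of a heavy-tailed community yields the
#' characteristic singleton-rich count vectors.
#'
#' @param probs true relative abundances, summing to 1 within 1e-8.
#' @param depth number of reads (>= 1).
#' @param seed integer seed.
#' @return An \linkS4class{AbundanceVector} of length \code{length(probs)}
#'   summing to \code{depth} (zero-count taxa retained).
#' @examples
#' v <- sampleReads(makeCommunity(communitySpec(100, "zipf")), 1000, seed = 1)
#' observedRichness(v)
#' @export
sampleReads <- function(probs, depth, seed = 1L) {
  if (!is.numeric(probs) || length(probs) == 0L || any(probs < 0))
    stop("'probs' must be non-negative relative abundances", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("'probs' must sum to 1 (got ", format(sum(probs)), ")",
         call. = FALSE)
  if (length(depth) != 1L || depth < 1 || depth != floor(depth))
    stop("'depth' must be a single integer >= 1", call. = FALSE)
  cnt <- withSeed(seed, as.numeric(rmultinom(1L, depth, probs)))
  abundanceVector(cnt)
}

#' Simulate a multi-sample study
#'
#' Draws \code{nSamples} samples of \code{depthPerSample} reads each from a
#' single true community. With \code{overdispersion} > 0, each sample's
#' proportions are first jittered by a Dirichlet draw with concentration
#' \code{probs / overdispersion} (concentration inversely proportional to
#' the overdispersion), emulating between-sample compositional variability;
#' at 0 all samples share the true proportions exactly.
#'
#' @param spec a \linkS4class{CommunitySpec}.
#' @param nSamples number of samples (>= 1).
#' @param depthPerSample reads per sample.
#' @param overdispersion non-negative Dirichlet jitter (default 0).
#' @param seed integer master seed.
#' @return A \linkS4class{CommunityTable} (taxa x samples), every column
#'   summing to \code{depthPerSample}.
#' @examples
#' ct <- makeStudy(communitySpec(100, "lognormal", sigma = 2, seed = 1),
#'                 nSamples = 5, depthPerSample = 500, seed = 1)
#' sampleSums(ct)
#' @export
makeStudy <- function(spec, nSamples, depthPerSample, overdispersion = 0,
                      seed = 1L) {
  stopifnot(is(spec, "CommunitySpec"))
  if (nSamples < 1L || nSamples != floor(nSamples))
    stop("'nSamples' must be a positive integer", call. = FALSE)
  if (overdispersion < 0)
    stop("'overdispersion' must be >= 0", call. = FALSE)
  probs <- makeCommunity(spec)
  m <- withSeed(seed, {
    out <- matrix(0, nrow = spec@S, ncol = nSamples)
    for (j in seq_len(nSamples)) {
      pj <- probs
      if (overdispersion > 0) {
        g <- rgamma(spec@S, shape = probs / overdispersion, rate = 1)
        if (sum(g) <= 0) g <- probs
        pj <- g / sum(g)
      }
      out[, j] <- rmultinom(1L, depthPerSample, pj)
    }
    out
  })
  communityTable(m,
                 taxonIds = sprintf("OTU%05d", seq_len(spec@S)),
                 sampleIds = sprintf("S%02d", seq_len(nSamples)))
}

#' Study presets emulating deep and shallow soil surveys
#'
#' Two ready-made study designs reproducing the qualitative contrast the
#' pipeline is built around, with true generative parameters chosen as
#' plausible for hyperdiverse soil communities (the real ones are unknown):
#' \describe{
#'   \item{\code{"amazon"}}{deep sampling of a log-normal community:
#'     S = 5000, sigma = 2, 66 samples x 6000 reads (~400,000 total).}
#'   \item{\code{"texas"}}{shallow sampling of a Zipf community:
#'     S = 5000, gamma = 1.1, 36 samples x 860 reads (~31,000 total).}
#' }
#'
#' @param name \code{"amazon"} or \code{"texas"}.
#' @param seed integer seed stored in the spec.
#' @return list(spec = \linkS4class{CommunitySpec}, nSamples,
#'   depthPerSample).
#' @examples
#' p <- studyPreset("texas")
#' p$nSamples
#' @export
studyPreset <- function(name = c("amazon", "texas"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    amazon = list(
      spec = communitySpec(5000L, "lognormal", mu = 0, sigma = 2,
                           seed = seed),
      nSamples = 66L, depthPerSample = 6000L),
    texas = list(
      spec = communitySpec(5000L, "zipf", gamma = 1.1, seed = seed),
      nSamples = 36L, depthPerSample = 860L)
  )
}
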