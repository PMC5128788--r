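# Smoothed taxa-accumulation curves, read subsampling and the
# asymptote-stability criterion.
#
# TACs pool raw counts over the first k samples of a random ordering and
# evaluate the Hill number of the pooled vector (gamma diversity of the
# accumulated pool), then average over orderings. Averaging per-sample
# diversities instead would not rise toward a study-wide asymptote.

#' Smoothed taxa-accumulation curve for one Hill order
#'
#' For each k = 1..n_samples, the mean (and sd) over random sample orderings
#' of the Hill number of the first k samples pooled. Smoothing is
#' Monte-Carlo over orderings; \code{exhaustive = TRUE} enumerates all
#' orderings instead (small tables only). For order 0 an analytic
#' expectation is also available via [expectedTAC()].
#'
#' @param table a \linkS4class{CommunityTable} with >= 2 samples.
#' @param a Hill order (single value >= 0).
#' @param nPerm number of random orderings (default 100).
#' @param seed integer seed; identical seeds give identical curves.
#' @param exhaustive enumerate all orderings (requires <= 8 samples).
#' @return An \linkS4class{AccumulationCurve} with steps 1..n_samples.
#' @examples
#' ct <- makeStudy(communitySpec(40, "zipf", gamma = 1), nSamples = 4,
#'                 depthPerSample = 100, seed = 1)
#' smoothedTAC(ct, a = 0, nPerm = 20, seed = 1)
#' @export
smoothedTAC <- function(table, a, nPerm = 100L, seed = 1L,
                        exhaustive = FALSE) {
  stopifnot(is(table, "CommunityTable"))
  m <- counts(table)
  nSamp <- ncol(m)
  if (nSamp < 2L)
    stop("smoothedTAC needs >= 2 samples; for a single sample use ",
         "depthAnalysis on its reads instead", call. = FALSE)
  if (!exhaustive && (length(nPerm) != 1L || nPerm < 1))
    stop("'nPerm' must be >= 1", call. = FALSE)
  perms <- if (exhaustive) {
    allPermutations(nSamp)
  } else {
    withSeed(seed, t(replicate(nPerm, sample.int(nSamp))))
  }
  vals <- matrix(NA_real_, nrow(perms), nSamp)
  for (p in seq_len(nrow(perms))) {
    pooled <- .rowCumsum(m[, perms[p, ], drop = FALSE])
    for (k in seq_len(nSamp))
      vals[p, k] <- .hillNumberCore(pooled[, k], a)
  }
  new("AccumulationCurve", order = as.numeric(a),
      steps = as.numeric(seq_len(nSamp)),
      mean = colMeans(vals),
      sd = apply(vals, 2L, sd),
      nPerm = nrow(perms))
}

# cumulative sums across columns (taxa x samples -> taxa x k pools)
.rowCumsum <- function(m) {
  t(apply(m, 1L, cumsum))
}

#' Analytic sample-based rarefaction expectation (order 0)
#'
#' The closed-form expected richness after pooling k of the m samples drawn
#' uniformly without replacement:
#' \deqn{E[S(k)] = \sum_i 1 - \binom{m - m_i}{k} / \binom{m}{k}}
#' with \eqn{m_i} the number of samples in which taxon i occurs. This is the
#' exact expectation of the Monte-Carlo smoothed order-0 TAC and serves as
#' its cross-check.
#'
#' @param table a \linkS4class{CommunityTable} with >= 2 samples.
#' @return An \linkS4class{AccumulationCurve} (order 0, sd = 0, analytic).
#' @export
expectedTAC <- function(table) {
  stopifnot(is(table, "CommunityTable"))
  m <- counts(table)
  nSamp <- ncol(m)
  if (nSamp < 2L)
    stop("expectedTAC needs >= 2 samples", call. = FALSE)
  incidence <- rowSums(m > 0)
  ks <- seq_len(nSamp)
  means <- vapply(ks, function(k) {
    # log-scale binomial ratio; choose(m - mi, k) = 0 when m - mi < k
    logRatio <- lchoose(nSamp - incidence, k) - lchoose(nSamp, k)
    sum(1 - exp(logRatio))
  }, numeric(1))
  new("AccumulationCurve", order = 0, steps = as.numeric(ks), mean = means,
      sd = rep(0, nSamp), nPerm = 0L)
}

#' Subsample reads without replacement
#'
#' Draws \code{depth} reads from the pooled reads of \code{v} without
#' replacement (multivariate hypergeometric on the counts), emulating a
#' shallower sequencing run of the same library. With
#' \code{replace = TRUE} a multinomial draw on the observed proportions is
#' used instead, which also permits depths above N (never the default).
#'
#' @param v an \linkS4class{AbundanceVector}.
#' @param depth number of reads to draw (0 < depth <= N unless
#'   \code{replace}).
#' @param seed integer seed; same seed, same draw.
#' @param replace draw with replacement (multinomial) instead.
#' @return An \linkS4class{AbundanceVector} summing to \code{depth} exactly,
#'   same taxon universe as \code{v}.
#' @examples
#' v <- abundanceVector(c(50, 30, 20))
#' totalReads(subsampleReads(v, 40, seed = 7))
#' @export
subsampleReads <- function(v, depth, seed = 1L, replace = FALSE) {
  stopifnot(is(v, "AbundanceVector"))
  N <- totalReads(v)
  if (length(depth) != 1L || depth <= 0 || depth != floor(depth))
    stop("'depth' must be a single positive integer", call. = FALSE)
  if (!replace && depth > N)
    stop("requested depth ", depth, " exceeds available reads ", N,
         " (set replace = TRUE for with-replacement draws)", call. = FALSE)
  counts <- v@counts
  if (replace) {
    out <- withSeed(seed, as.numeric(rmultinom(1L, depth, counts / N)))
    return(abundanceVector(out, taxonIds = v@taxonIds))
  }
  if (depth == N)
    return(v)
  out <- withSeed(seed, {
    drawn <- numeric(length(counts))
    remaining <- N
    need <- depth
    for (i in seq_along(counts)) {
      if (need == 0) break
      ci <- counts[i]
      remaining <- remaining - ci
      # conditional one-margin hypergeometric given reads left to place
      x <- rhyper(1L, ci, remaining, need)
      drawn[i] <- x
      need <- need - x
    }
    drawn
  })
  abundanceVector(out, taxonIds = v@taxonIds)
}

#' Expected richness under hypergeometric rarefaction
#'
#' Closed-form expectation of observed richness in a without-replacement
#' subsample of \code{depth} reads:
#' \deqn{E[S_{obs}(d)] = \sum_i 1 - \binom{N - n_i}{d} / \binom{N}{d}.}
#'
#' @param v an \linkS4class{AbundanceVector}.
#' @param depth subsample size, 0 < depth <= N.
#' @return Expected number of taxa observed.
#' @export
expectedRichness <- function(v, depth) {
  stopifnot(is(v, "AbundanceVector"))
  N <- totalReads(v)
  if (depth <= 0 || depth > N)
    stop("'depth' must lie in (0, N]", call. = FALSE)
  n <- v@counts[v@counts > 0]
  sum(1 - exp(lchoose(N - n, depth) - lchoose(N, depth)))
}

#' Default sequencing-depth grid
#'
#' Eight log-spaced depths spanning 25,000 to 400,000 reads (the depth range
#' probed by the subsampling analysis), clipped to the available total N and
#' de-duplicated.
#'
#' @param N total available reads.
#' @param nDepths number of grid points (default 8).
#' @param from,to grid end points before clipping.
#' @return Ascending integer-valued depth vector, max <= N.
#' @export
defaultDepthGrid <- function(N, nDepths = 8L, from = 25000, to = 400000) {
  to <- min(to, N)
  from <- min(from, to)
  grid <- unique(round(exp(seq(log(from), log(to), length.out = nDepths))))
  grid[grid >= 1 & grid <= N]
}

#' Diversity stability across sequencing depths
#'
#' Subsamples \code{v} at each depth \code{reps} times (without
#' replacement), computes the Hill number of every subsample at each order,
#' and locates the smallest depth at which the mean curve satisfies the
#' stability criterion of [stabilityScore()]. Higher orders down-weight the
#' rare tail and are expected to stabilize at shallower depths.
#'
#' @param v an \linkS4class{AbundanceVector}.
#' @param depths ascending depths, max <= N (default [defaultDepthGrid()]).
#' @param orders Hill orders (default \code{c(0, 1, 2)}).
#' @param reps replicate subsamples per depth (>= 2, default 10).
#' @param seed integer master seed.
#' @param windowFrac,tol stability criterion parameters (see
#'   [stabilityScore()]).
#' @return A \linkS4class{DepthAnalysisResult}.
#' @export
depthAnalysis <- function(v, depths = defaultDepthGrid(totalReads(v)),
                          orders = c(0, 1, 2), reps = 10L, seed = 1L,
                          windowFrac = 0.1, tol = 0.02) {
  stopifnot(is(v, "AbundanceVector"))
  N <- totalReads(v)
  if (length(depths) < 1L || any(diff(depths) <= 0))
    stop("'depths' must be ascending", call. = FALSE)
  if (max(depths) > N)
    stop("max depth ", max(depths), " exceeds available reads ", N,
         call. = FALSE)
  if (reps < 2L)
    stop("'reps' must be >= 2", call. = FALSE)
  vals <- array(NA_real_, dim = c(reps, length(depths), length(orders)),
                dimnames = list(NULL, paste0("d", depths),
                                paste0("a", orders)))
  for (di in seq_along(depths)) {
    for (r in seq_len(reps)) {
      sub <- subsampleReads(v, depths[di],
                            seed = deriveSeed(seed, di * 1000L + r))
      for (oi in seq_along(orders))
        vals[r, di, oi] <- .hillNumberCore(sub@counts, orders[oi])
    }
  }
  stab <- if (length(depths) < 3L) {
    warning("fewer than 3 depths: stability not assessed")
    rep(NA_real_, length(orders))
  } else {
    vapply(seq_along(orders), function(oi) {
      meanCurve <- apply(vals[, , oi, drop = FALSE], 2L, mean)
      sc <- stabilityScore(depths, meanCurve,
                           windowFrac = windowFrac, tol = tol)
      if (sc$reached) sc$atStep else NA_real_
    }, numeric(1))
  }
  new("DepthAnalysisResult", depths = as.numeric(depths),
      orders = as.numeric(orders), values = vals,
      stabilityDepth = stab, reps = as.integer(reps))
}

#' Asymptote-stability criterion for an accumulation curve
#'
#' Declares a curve stable at the first step s such that (i) the tail of the
#' curve from s onward spans at least \code{windowFrac} of the full step
#' range, and (ii) the maximum relative change of the curve between s and
#' every later step is at most \code{tol}. The attainment threshold is a
#' declared convention: "asymptote reached" is not a standard formalized
#' quantity, and these defaults (2\% relative change supported by at least
#' the final 10\% of the range) are tuned to separate saturating from still-
#' rising Hill curves.
#'
#' @param steps strictly increasing numeric vector (length >= 3).
#' @param means curve values at \code{steps}, same length.
#' @param windowFrac minimal fraction of the step range the stable tail must
#'   span (0 < windowFrac < 1, default 0.1).
#' @param tol maximal relative change over the stable tail (default 0.02).
#' @return list(reached = logical, atStep = step value or NA,
#'   index = index or NA).
#' @examples
#' stabilityScore(1:10, rep(5, 10))             # flat: first eligible step
#' stabilityScore(1:10, 1:10 * 10)$reached      # steep: FALSE
#' @export
stabilityScore <- function(steps, means, windowFrac = 0.1, tol = 0.02) {
  if (length(steps) != length(means))
    stop("'steps' and 'means' differ in length", call. = FALSE)
  if (length(steps) < 3L)
    stop("need >= 3 steps to assess stability", call. = FALSE)
  if (any(diff(steps) <= 0))
    stop("'steps' must be strictly increasing", call. = FALSE)
  if (windowFrac <= 0 || windowFrac >= 1)
    stop("'windowFrac' must lie in (0, 1)", call. = FALSE)
  if (tol <= 0)
    stop("'tol' must be > 0", call. = FALSE)
  range <- steps[length(steps)] - steps[1L]
  lastEligible <- max(which(steps <= steps[length(steps)] -
                              windowFrac * range))
  for (j in seq_len(lastEligible)) {
    tail <- means[j:length(means)]
    ref <- abs(means[j])
    if (ref == 0) ref <- .Machine$double.eps
    if (max(abs(tail - means[j])) / ref <= tol)
      return(list(reached = TRUE, atStep = steps[j], index = j))
  }
  list(reached = FALSE, atStep = NA_real_, index = NA_integer_)
}
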