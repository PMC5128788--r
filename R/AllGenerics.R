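#' @importFrom BiocGenerics counts
NULL

#' Hill number (effective number of taxa) of order a
#'
#' The reciprocal generalized-mean proportional abundance
#' \deqn{N_a = \left(\sum_{p_i > 0} p_i^a\right)^{1/(1-a)}}{
#'   N_a = (sum p_i^a)^(1/(1-a))}
#' with the continuity limit \eqn{N_1 = \exp(-\sum p_i \log p_i)} at a = 1
#' and \eqn{N_0 = S_{obs}} (observed richness) at a = 0. Order a tunes the
#' weight of rare taxa: a = 0 counts every observed taxon equally, a = 1 is
#' the exponential Shannon index, a = 2 the reciprocal Simpson index.
#'
#' @param x an \linkS4class{AbundanceVector} or a numeric vector of
#'   non-negative counts.
#' @param a single order, a >= 0. Orders below 1 are supported but carry
#'   rapidly growing sampling uncertainty in undersampled communities.
#' @return A single Hill number in [1, S_obs].
#' @examples
#' hillNumber(c(8, 4, 2, 1, 1), 2)
#' hillNumber(c(1, 1, 1, 1), 0.5)  # uniform: N_a = S for every a
#' @export
setGeneric("hillNumber", function(x, a) standardGeneric("hillNumber"))

#' Hill diversity profile over a grid of orders
#'
#' Evaluates [hillNumber()] over ascending orders; the resulting profile is
#' non-increasing in a and bounded by [1, S_obs].
#'
#' @param x an \linkS4class{AbundanceVector} or numeric count vector.
#' @param orders ascending numeric vector of orders, all >= 0. Default
#'   \code{c(0, 1, 2)}: richness, exponential Shannon, reciprocal Simpson.
#' @return A \linkS4class{HillProfile}.
#' @examples
#' hillProfile(c(100, 1, 1), c(0, 1, 2))
#' @export
setGeneric("hillProfile",
           function(x, orders = c(0, 1, 2)) standardGeneric("hillProfile"))

#' Chao1 richness estimator
#'
#' Estimates total richness from rare-taxon frequencies: S_obs +
#' F1^2 / (2 F2), where F1 and F2 are the singleton and doubleton counts.
#' When F2 = 0 the bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1))
#' is used (reported via a message).
#'
#' @param x an \linkS4class{AbundanceVector} or numeric count vector.
#' @return Estimated richness, always >= S_obs.
#' @examples
#' chao1(c(1, 1, 2, 2, 5))  # 5 + 4/4 = 6
#' @export
setGeneric("chao1", function(x) standardGeneric("chao1"))

#' Good's coverage (sampling completeness)
#'
#' 1 - F1/N: the estimated probability that one more read belongs to an
#' already-observed taxon.
#'
#' @param x an \linkS4class{AbundanceVector} or numeric count vector.
#' @return Coverage in [0, 1].
#' @examples
#' goodsCoverage(c(1, 2, 3))  # 1 - 1/6
#' @export
setGeneric("goodsCoverage", function(x) standardGeneric("goodsCoverage"))

#' Abundance-frequency counts F_k
#'
#' Tallies how many taxa were observed exactly k times. Zero counts are
#' excluded. The identities sum(k * F_k) = N and sum(F_k) = S_obs hold.
#'
#' @param x an \linkS4class{AbundanceVector} or numeric count vector.
#' @return Named numeric vector, names the observed abundances k, values F_k.
#' @examples
#' frequencyCounts(c(1, 1, 2, 5))
#' @export
setGeneric("frequencyCounts", function(x) standardGeneric("frequencyCounts"))

#' Pool samples of a count table into one abundance vector
#'
#' Sums counts per taxon over a subset of samples. Taxa that end up with a
#' pooled count of zero are retained with count 0, so the taxon universe is
#' stable under pooling.
#'
#' @param x a \linkS4class{CommunityTable}.
#' @param samples character vector of sample ids (default: all samples).
#' @return An \linkS4class{AbundanceVector}.
#' @examples
#' ct <- communityTable(matrix(c(5, 1, 0, 2), 2,
#'                             dimnames = list(c("a", "b"), c("x", "y"))))
#' counts(poolSamples(ct))
#' @export
setGeneric("poolSamples",
           function(x, samples = sampleIds(x)) standardGeneric("poolSamples"))

#' @rdname accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("observedRichness", function(x) standardGeneric("observedRichness"))

#' @rdname accessors
#' @export
setGeneric("sampleSums", function(x) standardGeneric("sampleSums"))
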