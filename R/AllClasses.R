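#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats optimize pnorm qnorm rgamma rhyper rmultinom rnorm
#'   sd setNames dlnorm
#' @importFrom utils write.csv packageVersion
NULL

#' CommunityTable: an OTU count table for one study
#'
#' An integer count matrix of taxa (rows) by samples (columns), stored as a
#' \linkS4class{SummarizedExperiment} with a single \code{"counts"} assay.
#' It is the unit of a multi-sample diversity study: taxa-accumulation
#' curves, pooling and per-sample diversity summaries all start from it.
#'
#' Validity requires non-negative integral counts, unique taxon and sample
#' identifiers, and at least one positive count overall. Zero-sum samples
#' are tolerated here (I/O is faithful) but rejected by analysis operations.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso [communityTable()], [readShared()], [poolSamples()]
#' @export
setClass("CommunityTable", contains = "SummarizedExperiment")

setValidity("CommunityTable", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("counts" %in% a))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(m)))
    return("duplicate taxon ids")
  if (anyDuplicated(colnames(m)))
    return("duplicate sample ids")
  if (anyNA(m))
    return("counts contain missing values")
  if (any(m < 0))
    return("counts contain negative values")
  if (any(m != floor(m)))
    return("counts contain non-integer values")
  if (sum(m) <= 0)
    return("no taxon has a positive count in any sample")
  TRUE
})

#' Construct a CommunityTable from a count matrix
#'
#' @param counts numeric matrix of non-negative integer counts. If
#'   \code{taxaAreRows = FALSE} the matrix is transposed first.
#' @param taxonIds,sampleIds optional character vectors of unique labels;
#'   default to the matrix dimnames, or \code{OTU0001...}/\code{S1...}.
#' @param taxaAreRows logical; are taxa the rows of \code{counts}?
#' @return A \linkS4class{CommunityTable}.
#' @examples
#' ct <- communityTable(matrix(c(5, 1, 0, 0, 2, 3), nrow = 3,
#'                             dimnames = list(paste0("OTU", 1:3),
#'                                             c("A", "B"))))
#' sampleSums(ct)
#' @export
communityTable <- function(counts, taxonIds = NULL, sampleIds = NULL,
                           taxaAreRows = TRUE) {
  if (!is.matrix(counts))
    counts <- as.matrix(counts)
  if (!taxaAreRows)
    counts <- t(counts)
  storage.mode(counts) <- "double"
  if (!is.null(taxonIds)) rownames(counts) <- as.character(taxonIds)
  if (!is.null(sampleIds)) colnames(counts) <- as.character(sampleIds)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OTU%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts))
  new("CommunityTable", se)
}

#' AbundanceVector: pooled per-taxon read counts for one community
#'
#' One point of analysis: a vector of non-negative integer counts, one per
#' taxon. Derived quantities (total reads N, observed richness, frequency
#' counts F_k) feed every diversity estimator.
#'
#' @slot counts numeric vector of non-negative integer counts.
#' @slot taxonIds character vector of taxon labels (same length).
#' @seealso [abundanceVector()], [hillNumber()], [chao1()]
#' @export
setClass("AbundanceVector",
         representation(counts = "numeric", taxonIds = "character"))

setValidity("AbundanceVector", function(object) {
  x <- object@counts
  if (length(x) == 0L) return("empty counts")
  if (anyNA(x)) return("counts contain missing values")
  if (any(x < 0)) return("counts contain negative values")
  if (any(x != floor(x))) return("counts contain non-integer values")
  if (length(object@taxonIds) != length(x))
    return("taxonIds and counts differ in length")
  TRUE
})

#' Construct an AbundanceVector
#'
#' @param counts numeric vector of non-negative integer per-taxon counts.
#' @param taxonIds optional taxon labels; default \code{OTU0001...}.
#' @return An \linkS4class{AbundanceVector}.
#' @examples
#' v <- abundanceVector(c(8, 4, 2, 1, 1))
#' hillNumber(v, 2)
#' @export
abundanceVector <- function(counts, taxonIds = NULL) {
  counts <- checkCounts(counts)
  if (is.null(taxonIds)) {
    taxonIds <- names(counts)
    if (is.null(taxonIds))
      taxonIds <- sprintf("OTU%04d", seq_along(counts))
  }
  new("AbundanceVector", counts = unname(counts),
      taxonIds = as.character(taxonIds))
}

#' HillProfile: a diversity profile over orders
#'
#' Hill numbers N_a evaluated on one community over a grid of orders a.
#' Values are effective numbers of taxa: non-increasing in a and bounded by
#' [1, S_obs].
#'
#' @slot orders numeric vector of orders a >= 0, ascending.
#' @slot values numeric vector of Hill numbers, same length.
#' @slot sObs observed richness of the underlying community.
#' @seealso [hillProfile()]
#' @export
setClass("HillProfile",
         representation(orders = "numeric", values = "numeric",
                        sObs = "numeric"))

setValidity("HillProfile", function(object) {
  o <- object@orders; v <- object@values
  if (length(o) != length(v)) return("orders and values differ in length")
  if (any(o < 0)) return("orders must be >= 0")
  if (is.unsorted(o, strictly = FALSE)) return("orders must be ascending")
  tol <- 1e-8
  if (any(diff(v) > tol * pmax(1, v[-length(v)])))
    return("values must be non-increasing in order")
  if (any(v < 1 - 1e-9)) return("values below 1")
  if (any(v > object@sObs * (1 + 1e-9)))
    return("values above observed richness")
  TRUE
})

#' AccumulationCurve: diversity as sampling effort accumulates
#'
#' Mean and across-permutation spread of a Hill number of one order as
#' samples (or reads) accumulate, as produced by [smoothedTAC()] or
#' [expectedTAC()].
#'
#' @slot order numeric Hill order a.
#' @slot steps strictly increasing accumulation sizes.
#' @slot mean per-step mean diversity.
#' @slot sd per-step across-permutation standard deviation.
#' @slot nPerm number of random orderings averaged (0 for analytic curves).
#' @export
setClass("AccumulationCurve",
         representation(order = "numeric", steps = "numeric",
                        mean = "numeric", sd = "numeric", nPerm = "integer"))

setValidity("AccumulationCurve", function(object) {
  s <- object@steps
  if (length(s) != length(object@mean) || length(s) != length(object@sd))
    return("steps, mean and sd must have equal length")
  if (any(diff(s) <= 0)) return("steps must be strictly increasing")
  if (any(object@sd < 0)) return("sd must be non-negative")
  if (object@order == 0 &&
      any(diff(object@mean) < -1e-9 * pmax(1, object@mean[-length(s)])))
    return("richness accumulation mean must be non-decreasing")
  TRUE
})

#' DepthAnalysisResult: diversity across sequencing depths
#'
#' Replicate Hill numbers computed on random read subsamples over a grid of
#' depths, with the smallest depth at which each order's mean curve meets
#' the stability criterion (NA when not reached).
#'
#' @slot depths integer-valued vector of subsampling depths (ascending).
#' @slot orders Hill orders analysed.
#' @slot values 3-d array, replicates x depths x orders.
#' @slot stabilityDepth named numeric, per order; NA = not reached.
#' @slot reps number of replicate subsamples per depth.
#' @seealso [depthAnalysis()], [stabilityScore()]
#' @export
setClass("DepthAnalysisResult",
         representation(depths = "numeric", orders = "numeric",
                        values = "array", stabilityDepth = "numeric",
                        reps = "integer"))

setValidity("DepthAnalysisResult", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-d array")
  if (d[2] != length(object@depths)) return("depth dimension mismatch")
  if (d[3] != length(object@orders)) return("order dimension mismatch")
  if (d[1] != object@reps) return("replicate dimension mismatch")
  if (any(diff(object@depths) <= 0)) return("depths must be ascending")
  if (length(object@stabilityDepth) != length(object@orders))
    return("stabilityDepth must have one entry per order")
  TRUE
})

#' RADFitResult: a fitted taxon-abundance distribution model
#'
#' Maximum-likelihood fit of a rank-abundance / taxon-abundance model to one
#' community. The log-likelihood is model-native: a continuous log-normal
#' density over taxa for \code{"lognormal"}, a multinomial read likelihood
#' over ranks for \code{"zipf"} (see the package vignette for why model
#' selection uses a common multinomial footing instead).
#'
#' @slot model \code{"lognormal"} or \code{"zipf"}.
#' @slot params named numeric parameter vector (\code{mu}, \code{sigma} for
#'   log-normal; \code{gamma}, \code{p1} for Zipf, \code{p1} the fitted
#'   relative abundance at rank 1).
#' @slot logLik model-native maximized log-likelihood.
#' @slot aic 2 * nPar - 2 * logLik.
#' @slot nPar number of free parameters.
#' @slot nTaxa number of observed taxa used in the fit.
#' @slot rankCounts the rank-ordered (decreasing) positive counts fitted.
#' @slot degenerate TRUE when the fit hit a boundary (e.g. sigma ~ 0).
#' @seealso [fitLognormal()], [fitZipf()], [selectModel()]
#' @export
setClass("RADFitResult",
         representation(model = "character", params = "numeric",
                        logLik = "numeric", aic = "numeric",
                        nPar = "integer", nTaxa = "integer",
                        rankCounts = "numeric", degenerate = "logical"))

setValidity("RADFitResult", function(object) {
  if (!object@model %in% c("lognormal", "zipf"))
    return("model must be 'lognormal' or 'zipf'")
  if (object@model == "lognormal" && object@params[["sigma"]] <= 0)
    return("sigma must be > 0")
  if (object@model == "zipf" && object@params[["gamma"]] <= 0)
    return("gamma must be > 0")
  if (abs(object@aic - (2 * object@nPar - 2 * object@logLik)) >
      1e-8 * max(1, abs(object@aic)))
    return("aic must equal 2*nPar - 2*logLik")
  if (object@nTaxa != length(object@rankCounts))
    return("nTaxa must match rankCounts length")
  TRUE
})

#' DeviationResult: bootstrap goodness-of-fit against a TAD model
#'
#' Sup-norm discrepancy D between the empirical CDF of log observed
#' abundances and a fitted log-normal CDF, with a parametric-bootstrap
#' p-value (the model is refitted on every replicate, so the statistic is
#' Lilliefors-corrected for estimated parameters).
#'
#' @slot D maximum CDF discrepancy, in [0, 1].
#' @slot pValue bootstrap p-value, (1 + #\{D* >= D\}) / (nBoot + 1).
#' @slot nBoot number of bootstrap replicates.
#' @seealso [deviationTest()]
#' @export
setClass("DeviationResult",
         representation(D = "numeric", pValue = "numeric", nBoot = "integer"))

setValidity("DeviationResult", function(object) {
  if (object@D < 0 || object@D > 1) return("D must lie in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' CommunitySpec: parameters of a synthetic community
#'
#' Describes a true community for the generator: number of taxa and the
#' taxon-abundance distribution family with its parameters.
#'
#' @slot S number of true taxa (>= 1).
#' @slot tad \code{"lognormal"}, \code{"zipf"} or \code{"uniform"}.
#' @slot mu,sigma log-normal parameters of log-abundance (sigma > 0).
#' @slot gamma Zipf rank exponent (> 0).
#' @slot seed integer seed used when the family is stochastic.
#' @seealso [communitySpec()], [makeCommunity()], [makeStudy()]
#' @export
setClass("CommunitySpec",
         representation(S = "integer", tad = "character", mu = "numeric",
                        sigma = "numeric", gamma = "numeric",
                        seed = "integer"))

setValidity("CommunitySpec", function(object) {
  if (object@S < 1L) return("S must be >= 1")
  if (!object@tad %in% c("lognormal", "zipf", "uniform"))
    return("tad must be 'lognormal', 'zipf' or 'uniform'")
  if (object@tad == "lognormal" && object@sigma <= 0)
    return("sigma must be > 0")
  if (object@tad == "zipf" && object@gamma <= 0)
    return("gamma must be > 0")
  TRUE
})

#' Construct a CommunitySpec
#'
#' @param S integer number of true taxa.
#' @param tad abundance-distribution family: \code{"lognormal"},
#'   \code{"zipf"} or \code{"uniform"}.
#' @param mu,sigma log-normal mean and sd of log-abundance.
#' @param gamma Zipf exponent.
#' @param seed integer seed for stochastic families.
#' @return A \linkS4class{CommunitySpec}.
#' @examples
#' communitySpec(100, "zipf", gamma = 1.1)
#' @export
communitySpec <- function(S, tad = c("lognormal", "zipf", "uniform"),
                          mu = 0, sigma = 2, gamma = 1.1, seed = 1L) {
  tad <- match.arg(tad)
  if (length(S) != 1L || !is.numeric(S) || is.na(S) || S < 1 || S != floor(S))
    stop("'S' must be a single positive integer", call. = FALSE)
  new("CommunitySpec", S = as.integer(S), tad = tad, mu = as.numeric(mu),
      sigma = as.numeric(sigma), gamma = as.numeric(gamma),
      seed = checkSeed(seed))
}
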