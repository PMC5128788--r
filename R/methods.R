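#' Accessors for hilltac objects
#'
#' \code{counts} returns the raw count matrix/vector; \code{taxonIds} and
#' \code{sampleIds} the label vectors; \code{totalReads} the total read
#' count(s); \code{observedRichness} the number of taxa with positive count;
#' \code{sampleSums} per-sample read totals.
#'
#' @param x a \linkS4class{CommunityTable} or \linkS4class{AbundanceVector}.
#' @param object same as \code{x} (for \code{counts}).
#' @param ... unused.
#' @return Matrices, vectors or scalars as described above.
#' @name accessors
#' @aliases counts counts,CommunityTable-method counts,AbundanceVector-method
#' @examples
#' v <- abundanceVector(c(3, 0, 1))
#' totalReads(v); observedRichness(v)
NULL

#' @rdname accessors
#' @export
setMethod("counts", "CommunityTable", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname accessors
#' @export
setMethod("counts", "AbundanceVector", function(object, ...) {
  setNames(object@counts, object@taxonIds)
})

#' @rdname accessors
#' @export
setMethod("taxonIds", "CommunityTable", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("taxonIds", "AbundanceVector", function(x) x@taxonIds)

#' @rdname accessors
#' @export
setMethod("sampleIds", "CommunityTable", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleSums", "CommunityTable", function(x) colSums(counts(x)))

#' @rdname accessors
#' @export
setMethod("totalReads", "CommunityTable", function(x) sum(counts(x)))

#' @rdname accessors
#' @export
setMethod("totalReads", "AbundanceVector", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("observedRichness", "AbundanceVector",
          function(x) sum(x@counts > 0))

#' @rdname accessors
#' @export
setMethod("observedRichness", "CommunityTable",
          function(x) sum(rowSums(counts(x)) > 0))

setMethod("show", "AbundanceVector", function(object) {
  cat("AbundanceVector:", length(object@counts), "taxa,",
      format(totalReads(object), big.mark = ","), "reads,",
      observedRichness(object), "observed\n")
})

setMethod("show", "HillProfile", function(object) {
  cat("HillProfile over", length(object@orders), "orders (S_obs =",
      object@sObs, ")\n")
  print(setNames(round(object@values, 4),
                 paste0("N_", format(object@orders))))
})

setMethod("show", "AccumulationCurve", function(object) {
  cat("AccumulationCurve (order a =", object@order, ",",
      length(object@steps), "steps,",
      if (object@nPerm > 0L) paste(object@nPerm, "orderings")
      else "analytic", ")\n")
  cat("  final:", format(object@mean[length(object@mean)], digits = 6), "\n")
})

setMethod("show", "DepthAnalysisResult", function(object) {
  cat("DepthAnalysisResult:", length(object@depths), "depths x",
      length(object@orders), "orders x", object@reps, "replicates\n")
  sd <- object@stabilityDepth
  lab <- ifelse(is.na(sd), "not reached", format(sd, big.mark = ","))
  cat("  stability depth:",
      paste(paste0("a=", format(object@orders), ": ", lab),
            collapse = "; "), "\n")
})

setMethod("show", "RADFitResult", function(object) {
  cat("RADFitResult:", object@model, "fit to", object@nTaxa, "taxa",
      if (object@degenerate) "(degenerate)" else "", "\n")
  cat("  params:", paste(names(object@params), "=",
                         format(object@params, digits = 4),
                         collapse = ", "), "\n")
  cat("  logLik:", format(object@logLik, digits = 8),
      " AIC:", format(object@aic, digits = 8), "\n")
})

setMethod("show", "DeviationResult", function(object) {
  cat("DeviationResult: D =", format(object@D, digits = 4),
      ", p =", format(object@pValue, digits = 4),
      "(", object@nBoot, "bootstrap replicates )\n")
})

setMethod("show", "CommunitySpec", function(object) {
  par <- switch(object@tad,
                lognormal = paste0("mu=", object@mu, ", sigma=", object@sigma),
                zipf = paste0("gamma=", object@gamma),
                uniform = "")
  cat("CommunitySpec:", object@S, "taxa,", object@tad,
      if (nzchar(par)) paste0("(", par, ")") else "", "\n")
})

#' Plain data.frame views of result objects
#'
#' @param x a \linkS4class{HillProfile} or \linkS4class{AccumulationCurve}.
#' @param row.names,optional,... ignored (S3 contract).
#' @return A base data.frame (order/value, or step/mean/sd).
#' @name result-coercion
NULL

#' @rdname result-coercion
#' @export
as.data.frame.HillProfile <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(order = x@orders, value = x@values)
}

#' @rdname result-coercion
#' @export
as.data.frame.AccumulationCurve <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(step = x@steps, mean = x@mean, sd = x@sd)
}

#' Stability depths of a depth analysis
#'
#' @param x a \linkS4class{DepthAnalysisResult}.
#' @return Named numeric vector (one per order, name \code{a=<order>});
#'   NA means the stability criterion was not reached.
#' @export
stabilityDepth <- function(x) {
  stopifnot(is(x, "DepthAnalysisResult"))
  setNames(x@stabilityDepth, paste0("a=", format(x@orders)))
}

#' Parameters, log-likelihood and AIC of a RAD fit
#'
#' @param x a \linkS4class{RADFitResult}.
#' @return \code{radParams}: named numeric vector; \code{radAIC},
#'   \code{radLogLik}: scalars; \code{isDegenerate}: logical.
#' @name rad-accessors
#' @export
radParams <- function(x) { stopifnot(is(x, "RADFitResult")); x@params }

#' @rdname rad-accessors
#' @export
radAIC <- function(x) { stopifnot(is(x, "RADFitResult")); x@aic }

#' @rdname rad-accessors
#' @export
radLogLik <- function(x) { stopifnot(is(x, "RADFitResult")); x@logLik }

#' @rdname rad-accessors
#' @export
isDegenerate <- function(x) { stopifnot(is(x, "RADFitResult")); x@degenerate }
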