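# Hill numbers and classical richness/coverage estimators.
#
# All estimators operate on the positive counts only; zero-count taxa carry
# no information about the realized community and are excluded from every
# sum (including at a = 0, where N_0 is *observed* richness).

# guard band around the a = 1 singularity of 1/(1-a)
.HILL_LIMIT_BAND <- 1e-6

.positiveProportions <- function(counts, what = "abundance vector") {
  counts <- checkCounts(counts)
  N <- sum(counts)
  if (N <= 0)
    stop(what, " has zero total count", call. = FALSE)
  counts[counts > 0] / N
}

.hillNumberCore <- function(counts, a) {
  if (length(a) != 1L || !is.numeric(a) || is.na(a))
    stop("'a' must be a single numeric order", call. = FALSE)
  if (a < 0)
    stop("'a' must be >= 0 (negative orders are not defined here)",
         call. = FALSE)
  p <- .positiveProportions(counts)
  if (a == 0)
    return(as.numeric(length(p)))
  if (abs(a - 1) < .HILL_LIMIT_BAND)
    return(exp(-sum(p * log(p))))
  sum(p^a)^(1 / (1 - a))
}

#' @rdname hillNumber
#' @export
setMethod("hillNumber", "AbundanceVector", function(x, a) {
  .hillNumberCore(x@counts, a)
})

#' @rdname hillNumber
#' @export
setMethod("hillNumber", "numeric", function(x, a) .hillNumberCore(x, a))

.hillProfileCore <- function(counts, orders) {
  if (length(orders) == 0L || any(is.na(orders)))
    stop("'orders' must be a non-empty numeric vector", call. = FALSE)
  if (is.unsorted(orders, strictly = FALSE))
    stop("'orders' must be sorted ascending", call. = FALSE)
  values <- vapply(orders, function(a) .hillNumberCore(counts, a),
                   numeric(1))
  new("HillProfile", orders = as.numeric(orders), values = values,
      sObs = sum(counts > 0))
}

#' @rdname hillProfile
#' @export
setMethod("hillProfile", "AbundanceVector", function(x, orders) {
  .hillProfileCore(x@counts, orders)
})

#' @rdname hillProfile
#' @export
setMethod("hillProfile", "numeric", function(x, orders) {
  .hillProfileCore(checkCounts(x), orders)
})

.chao1Core <- function(counts) {
  counts <- checkCounts(counts)
  if (sum(counts) <= 0)
    stop("abundance vector has zero total count", call. = FALSE)
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    sObs + f1^2 / (2 * f2)
  } else {
    # no doubletons: classic ratio is undefined, use the bias-corrected form
    message("chao1: F2 = 0, using bias-corrected estimator")
    sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' @rdname chao1
#' @export
setMethod("chao1", "AbundanceVector", function(x) .chao1Core(x@counts))

#' @rdname chao1
#' @export
setMethod("chao1", "numeric", function(x) .chao1Core(x))

.goodsCoverageCore <- function(counts) {
  counts <- checkCounts(counts)
  N <- sum(counts)
  if (N <= 0)
    stop("abundance vector has zero total count", call. = FALSE)
  1 - sum(counts == 1) / N
}

#' @rdname goodsCoverage
#' @export
setMethod("goodsCoverage", "AbundanceVector",
          function(x) .goodsCoverageCore(x@counts))

#' @rdname goodsCoverage
#' @export
setMethod("goodsCoverage", "numeric", function(x) .goodsCoverageCore(x))

.frequencyCountsCore <- function(counts) {
  counts <- checkCounts(counts)
  if (sum(counts) <= 0)
    stop("abundance vector has zero total count", call. = FALSE)
  pos <- counts[counts > 0]
  tab <- table(pos)
  setNames(as.numeric(tab), names(tab))
}

#' @rdname frequencyCounts
#' @export
setMethod("frequencyCounts", "AbundanceVector",
          function(x) .frequencyCountsCore(x@counts))

#' @rdname frequencyCounts
#' @export
setMethod("frequencyCounts", "numeric", function(x) .frequencyCountsCore(x))

#' Per-sample (and pooled) diversity summary of a count table
#'
#' One row per sample, plus an optional pooled row: observed richness,
#' exponential Shannon (N_1), reciprocal Simpson (N_2), Chao1, Good's
#' coverage, singleton/doubleton counts and total reads. Zero-sum samples
#' are rejected (read them faithfully, but they carry no diversity signal).
#'
#' @param table a \linkS4class{CommunityTable}.
#' @param pooled also include a row for all samples pooled (default TRUE).
#' @return data.frame with columns \code{sample, S_obs, N_1, N_2, chao1,
#'   coverage, F_1, F_2, N}.
#' @examples
#' ct <- makeStudy(communitySpec(50, "zipf", gamma = 1), nSamples = 3,
#'                 depthPerSample = 200, seed = 1)
#' diversityTable(ct)
#' @export
diversityTable <- function(table, pooled = TRUE) {
  stopifnot(is(table, "CommunityTable"))
  m <- counts(table)
  if (any(colSums(m) == 0))
    stop("zero-sum sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "),
         " — remove before analysis", call. = FALSE)
  oneRow <- function(cnt, id) {
    data.frame(sample = id,
               S_obs = sum(cnt > 0),
               N_1 = .hillNumberCore(cnt, 1),
               N_2 = .hillNumberCore(cnt, 2),
               chao1 = suppressMessages(.chao1Core(cnt)),
               coverage = .goodsCoverageCore(cnt),
               F_1 = sum(cnt == 1),
               F_2 = sum(cnt == 2),
               N = sum(cnt),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(colnames(m), function(s) oneRow(m[, s], s))
  if (pooled)
    rows <- c(rows, list(oneRow(rowSums(m), "pooled")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
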