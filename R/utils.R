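#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the random number generator seeded to \code{seed},
#' then restores the caller's RNG state, so seeded operations never perturb
#' the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  seed <- checkSeed(seed)
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# derive a stream-specific sub-seed from a master seed; stays < 2^31
deriveSeed <- function(seed, stream) {
  seed <- checkSeed(seed)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

checkSeed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != floor(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  as.integer(seed %% 2147483647)
}

checkCounts <- function(counts, what = "counts") {
  if (!is.numeric(counts) || length(counts) == 0L)
    stop("'", what, "' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(counts))
    stop("'", what, "' contains missing values", call. = FALSE)
  if (any(counts < 0))
    stop("'", what, "' contains negative values", call. = FALSE)
  if (any(counts != floor(counts)))
    stop("'", what, "' contains non-integer values", call. = FALSE)
  as.numeric(counts)
}

# all permutations of seq_len(n); guarded to small n (exhaustive TAC only)
allPermutations <- function(n) {
  if (n > 8L)
    stop("exhaustive enumeration limited to 8 samples (", n,
         "! orderings requested)", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[[k]] <- block
  }
  do.call(rbind, out)
}
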