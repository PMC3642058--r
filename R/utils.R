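#' @importFrom stats rnorm rpois median quantile sd pnorm pt dnorm runif
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are deterministic
#' without clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# +1 for "+" strand (downstream = increasing coordinate), -1 for "-".
strand_dir <- function(strand) {
  ifelse(strand == "-", -1L, 1L)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# Running median with truncated windows at the edges.  `half` is the window
# half-width in grid units; interior uses stats::runmed (O(n log k)), the two
# edges are recomputed with the truncated window directly.
running_median <- function(x, half) {
  n <- length(x)
  if (n == 0L) return(x)
  if (half < 1L) return(x)
  k <- 2L * half + 1L
  if (n <= k) {
    return(vapply(seq_len(n), function(i)
      median(x[max(1L, i - half):min(n, i + half)]), numeric(1)))
  }
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  for (i in seq_len(half)) {
    out[i] <- median(x[1L:(i + half)])
    j <- n - i + 1L
    out[j] <- median(x[(j - half):n])
  }
  out
}
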