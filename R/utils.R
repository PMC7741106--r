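# internal helpers shared across modules

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# running mean with shrinking windows at the edges (no NA padding)
#' @keywords internal
#' @noRd
running_mean <- function(x, halfwidth) {
  n <- length(x)
  h <- as.integer(max(0L, halfwidth))
  if (h == 0L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# row-wise (first dimension) running mean of a matrix, shrinking at edges;
# implemented as a banded averaging matrix so BLAS does the work
#' @keywords internal
#' @noRd
running_mean_rows <- function(m, halfwidth) {
  nr <- nrow(m)
  h <- min(as.integer(max(0L, halfwidth)), nr - 1L)
  if (h == 0L) return(m)
  W <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    lo <- max(1L, i - h); hi <- min(nr, i + h)
    W[i, lo:hi] <- 1 / (hi - lo + 1L)
  }
  W %*% m
}

#' @keywords internal
#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
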