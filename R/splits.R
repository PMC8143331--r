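#' Split a participant's trials into two halves
#'
#' Produces the trial-index assignment for the three split strategies used
#' in split-half reliability estimation: `"first_second"` assigns the first
#' `ceiling(n/2)` trials to half A and the rest to half B; `"odd_even"`
#' assigns odd 1-based trial indices to A and even ones to B; `"random"`
#' draws a uniformly random balanced partition (for odd `n` the extra trial
#' lands in either half with probability 1/2). Halves always partition the
#' trials and differ in size by at most one.
#'
#' @param n Number of trials (at least 2).
#' @param strategy One of `"first_second"`, `"odd_even"`, `"random"`.
#' @return A logical vector of length `n`, `TRUE` for half A. Class
#'   `"wcst_split"`.
#' @examples
#' split_half(7, "first_second")
#' split_half(5, "odd_even")
#' @export
split_half <- function(n, strategy = c("first_second", "odd_even", "random")) {
  strategy <- match.arg(strategy)
  n <- as.integer(n)
  if (n < 2L) stop("a test split needs at least 2 trials")
  a <- switch(strategy,
    first_second = seq_len(n) <= ceiling(n / 2),
    odd_even = seq_len(n) %% 2L == 1L,
    random = {
      size_a <- n %/% 2L + if (n %% 2L == 1L) rbinom(1L, 1L, 0.5) else 0L
      x <- logical(n)
      x[sample.int(n, size_a)] <- TRUE
      x
    })
  structure(a, class = "wcst_split", strategy = strategy)
}

#' Spearman-Brown correction
#'
#' Projects a half-test correlation to full test length:
#' `r_sb = 2 * r / (1 + r)`. The correction is strictly increasing on
#' (-1, 1], maps 0 to 0 and 1 to 1, and is undefined at a correlation of
#' exactly -1 (returned as `NA`). Negative input correlations yield negative corrected
#' coefficients; no truncation is applied.
#'
#' @param r Pearson correlation(s) between test halves, in (-1, 1].
#' @return Corrected coefficient(s), same length as `r`.
#' @examples
#' spearman_brown(1 / 3) # 0.5
#' @export
spearman_brown <- function(r) {
  if (any(r < -1 | r > 1, na.rm = TRUE))
    stop("'r' must be a correlation in [-1, 1]")
  out <- 2 * r / (1 + r)
  out[!is.na(r) & r == -1] <- NA_real_
  out
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous window of the sorted sample that contains at
#' least `mass` of the values: with `k = ceiling(mass * n)`, the window of
#' `k` consecutive order statistics with the smallest width. Ties are
#' broken by the leftmost window. For unimodal samples this interval is
#' never wider than the equal-tailed interval of the same mass.
#'
#' @param samples Numeric vector (at least 20 values, `NA` not allowed).
#' @param mass Probability mass to cover (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4)) # close to c(-1.96, 1.96)
#' @export
hdi <- function(samples, mass = 0.95) {
  if (anyNA(samples)) stop("'samples' must not contain NA")
  n <- length(samples)
  if (n < 20L) stop("at least 20 samples are required")
  if (mass <= 0 || mass > 1) stop("'mass' must be in (0, 1]")
  k <- ceiling(mass * n)
  x <- sort(samples)
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  width <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(width) # leftmost minimal window
  c(lower = x[i], upper = x[i + k - 1L])
}
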