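#' Available performance measures
#'
#' Names the per-participant measures whose split-half reliability can be
#' estimated: error counts (`pe`, `sle`, `ie`), mean RT per trial type over
#' valid trials (`rt_switch`, `rt_repeat`, `rt_inference`; inference trials
#' contribute to both the switch and the inference mean), and optionally
#' the conditional error probabilities (`p_pe` = PE per switch trial,
#' `p_sle` = SLE per repeat trial, `p_ie` = IE per inference trial).
#'
#' @param include_probs Also list the conditional error probabilities.
#' @return Character vector of measure names.
#' @export
wcst_measures <- function(include_probs = FALSE) {
  m <- c("pe", "sle", "ie", "rt_switch", "rt_repeat", "rt_inference")
  if (include_probs) m <- c(m, "p_pe", "p_sle", "p_ie")
  m
}

# per-trial numerator/denominator columns realizing each measure; a half
# score is sum(num)/sum(den) over the trials of the half (den NULL: raw sum)
.measure_columns <- function(flags, measures) {
  col <- function(name) {
    switch(name,
      pe = list(num = as.numeric(flags$pe), den = NULL),
      sle = list(num = as.numeric(flags$sle), den = NULL),
      ie = list(num = as.numeric(flags$ie), den = NULL),
      rt_switch = {
        sel <- flags$rt_valid & flags$label == "switch"
        list(num = ifelse(sel, flags$rt_ms, 0), den = as.numeric(sel))
      },
      rt_repeat = {
        sel <- flags$rt_valid & flags$label == "repeat"
        list(num = ifelse(sel, flags$rt_ms, 0), den = as.numeric(sel))
      },
      rt_inference = {
        sel <- flags$rt_valid & flags$is_inference
        list(num = ifelse(sel, flags$rt_ms, 0), den = as.numeric(sel))
      },
      p_pe = list(num = as.numeric(flags$pe),
                  den = as.numeric(flags$label == "switch")),
      p_sle = list(num = as.numeric(flags$sle),
                   den = as.numeric(flags$label == "repeat")),
      p_ie = list(num = as.numeric(flags$ie),
                  den = as.numeric(flags$is_inference)),
      stop("unknown measure: ", name))
  }
  setNames(lapply(measures, col), measures)
}

#' Half-test scores under a split
#'
#' Recomputes each measure separately on the two halves of every
#' participant's experimental trials, using the globally precomputed trial
#' labels, error flags and RT validity mask ([trial_flags()]): error-count
#' measures are raw counts of flagged trials inside a half, RT measures are
#' means of valid RTs of the type inside a half, conditional probabilities
#' are flagged-trial counts divided by type counts inside a half. A half
#' with an undefined score (no eligible trials) yields `NA`.
#'
#' @param flags A [trial_flags()] data frame.
#' @param assignment Logical vector aligned with `flags`, `TRUE` for the
#'   trials of half A (e.g. stacked [split_half()] assignments; see
#'   [cohort_split()]).
#' @param measures Character vector of measure names ([wcst_measures()]).
#' @return List with matrices `a` and `b` (participants x measures) and
#'   `participant_id`.
#' @export
half_scores <- function(flags, assignment,
                        measures = wcst_measures()) {
  stopifnot(length(assignment) == nrow(flags))
  ids <- unique(flags$participant_id)
  f <- factor(flags$participant_id, levels = ids)
  cols <- .measure_columns(flags, measures)
  score <- function(w) {
    vapply(cols, function(cl) {
      num <- rowsum(cl$num * w, f)[, 1L]
      if (is.null(cl$den)) num
      else {
        den <- rowsum(cl$den * w, f)[, 1L]
        ifelse(den > 0, num / den, NA_real_)
      }
    }, numeric(length(ids)))
  }
  a <- score(as.numeric(assignment))
  b <- score(as.numeric(!assignment))
  if (length(ids) == 1L) { # vapply dropped to vector
    a <- matrix(a, 1L, dimnames = list(NULL, measures))
    b <- matrix(b, 1L, dimnames = list(NULL, measures))
  }
  rownames(a) <- rownames(b) <- ids
  list(a = a, b = b, participant_id = ids)
}

#' Stack a split strategy over all participants of a cohort
#'
#' Applies [split_half()] to each participant's experimental trial count
#' and concatenates the assignments in trial order; random splits are drawn
#' independently per participant.
#'
#' @param flags A [trial_flags()] data frame.
#' @param strategy Split strategy, see [split_half()].
#' @return Logical assignment vector aligned with `flags`.
#' @export
cohort_split <- function(flags, strategy = "first_second") {
  ids <- unique(flags$participant_id)
  f <- factor(flags$participant_id, levels = ids)
  unsplit(lapply(split(seq_len(nrow(flags)), f),
                 function(i) as.logical(split_half(length(i), strategy))),
          f)
}

# Pearson correlation between half scores with pairwise deletion;
# zero variance in either vector leaves r undefined (NA)
.half_correlation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, n_pairs = n))
  if (.sd(a[ok]) == 0 || .sd(b[ok]) == 0)
    return(list(r = NA_real_, n_pairs = n))
  list(r = cor(a[ok], b[ok]), n_pairs = n)
}

#' Split-half reliability under a systematic split
#'
#' Correlates half-test scores across participants under the first/second
#' or odd/even split and applies the Spearman-Brown correction
#' `r_sb = 2r / (1 + r)`. Participants with an undefined score in either
#' half are dropped pairwise per measure. A zero-variance half-score vector
#' leaves the estimate undefined (`NA`), flagged rather than silently
#' propagated.
#'
#' @param cohort A trial-log data frame (already screened; see
#'   [screen_participants()]).
#' @param strategy `"first_second"` or `"odd_even"`.
#' @param measures Measure names ([wcst_measures()]).
#' @param filter A [wcst_filter()].
#' @param flags Optional precomputed [trial_flags()].
#' @return Data frame, one row per measure: `measure`, `strategy`, `r`,
#'   `r_sb`, `n_pairs`.
#' @export
reliability_estimate <- function(cohort,
                                 strategy = c("first_second", "odd_even"),
                                 measures = wcst_measures(),
                                 filter = wcst_filter(), flags = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(flags)) flags <- trial_flags(cohort, filter)
  hs <- half_scores(flags, cohort_split(flags, strategy), measures)
  if (length(hs$participant_id) < 3L)
    stop("reliability estimation needs at least 3 participants")
  est <- lapply(measures, function(m)
    .half_correlation(hs$a[, m], hs$b[, m]))
  data.frame(
    measure = measures, strategy = strategy,
    r = vapply(est, `[[`, numeric(1), "r"),
    r_sb = spearman_brown(vapply(est, `[[`, numeric(1), "r")),
    n_pairs = vapply(est, `[[`, integer(1), "n_pairs"),
    stringsAsFactors = FALSE
  )
}

# balanced random assignments for one participant: n trials x S samples
.random_assignments <- function(n, S) {
  ord <- apply(matrix(runif(n * S), n, S), 2L, order)
  size_a <- n %/% 2L + if (n %% 2L == 1L) rbinom(S, 1L, 0.5) else rep(0L, S)
  A <- matrix(FALSE, n, S)
  cols <- rep(seq_len(S), times = size_a)
  rows <- ord[cbind(sequence(size_a), cols)]
  A[cbind(rows, cols)] <- TRUE
  A
}

#' Sampling-based split-half reliability
#'
#' Draws `n_samples` random balanced test splits (independently per
#' participant in every iteration), computes the Spearman-Brown-corrected
#' split-half coefficient for each measure and split, and summarizes each
#' measure's sampled distribution by its median and the narrowest interval
#' containing `hdi_mass` of the sampled values ([hdi()]). Iterations with
#' an undefined correlation (fewer than 3 complete pairs or zero variance)
#' are excluded from the summary and counted in `n_undefined`.
#'
#' @param cohort A trial-log data frame (already screened).
#' @param measures Measure names ([wcst_measures()]).
#' @param n_samples Number of random splits (default 1000).
#' @param hdi_mass Mass of the highest density interval (default 0.95).
#' @param filter A [wcst_filter()].
#' @param flags Optional precomputed [trial_flags()].
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return List of class `"wcst_sampled"`: `samples` (matrix, `n_samples` x
#'   measures, of `r_sb` values), `summary` (data frame with `median`,
#'   `hdi_lower`, `hdi_upper`, `n_undefined` per measure), `n_samples`,
#'   `hdi_mass`.
#' @export
sample_reliability <- function(cohort, measures = wcst_measures(),
                               n_samples = 1000L, hdi_mass = 0.95,
                               filter = wcst_filter(), flags = NULL,
                               seed = NULL) {
  if (is.null(flags)) flags <- trial_flags(cohort, filter)
  ids <- unique(flags$participant_id)
  P <- length(ids)
  if (P < 3L) stop("reliability estimation needs at least 3 participants")
  S <- as.integer(n_samples)
  cols <- .measure_columns(flags, measures)
  K <- length(cols)
  f <- factor(flags$participant_id, levels = ids)
  idx <- split(seq_len(nrow(flags)), f)

  # per-trial weight matrix: numerators and denominators side by side
  W <- do.call(cbind, lapply(cols, function(cl)
    if (is.null(cl$den)) cbind(cl$num) else cbind(cl$num, cl$den)))
  has_den <- vapply(cols, function(cl) !is.null(cl$den), logical(1))
  ncol_m <- ifelse(has_den, 2L, 1L)
  col_start <- cumsum(c(1L, ncol_m[-K]))

  .with_seed(seed, {
    totals <- rowsum(W, f)                       # P x sum(ncol_m)
    sums_a <- array(NA_real_, c(P, S, ncol(W)))
    for (p in seq_len(P)) {
      A <- .random_assignments(length(idx[[p]]), S)
      sums_a[p, , ] <- crossprod(A, W[idx[[p]], , drop = FALSE])
    }
    r <- matrix(NA_real_, S, K, dimnames = list(NULL, measures))
    n_pairs <- matrix(NA_integer_, S, K)
    for (k in seq_len(K)) {
      j <- col_start[k]
      num_a <- matrix(sums_a[, , j], P, S)
      num_b <- matrix(totals[, j], P, S) - num_a
      if (has_den[k]) {
        den_a <- matrix(sums_a[, , j + 1L], P, S)
        den_b <- matrix(totals[, j + 1L], P, S) - den_a
        sa <- ifelse(den_a > 0, num_a / den_a, NA_real_)
        sb <- ifelse(den_b > 0, num_b / den_b, NA_real_)
      } else {
        sa <- num_a
        sb <- num_b
      }
      for (s in seq_len(S)) {
        hc <- .half_correlation(sa[, s], sb[, s])
        r[s, k] <- hc$r
        n_pairs[s, k] <- hc$n_pairs
      }
    }
    r_sb <- spearman_brown(r)
    summ <- do.call(rbind, lapply(seq_len(K), function(k) {
      v <- r_sb[, k]
      v <- v[is.finite(v)]
      if (length(v) >= 20L) {
        h <- hdi(v, hdi_mass)
        data.frame(measure = measures[k], median = median(v),
                   hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
                   n_undefined = S - length(v), stringsAsFactors = FALSE)
      } else {
        data.frame(measure = measures[k], median = NA_real_,
                   hdi_lower = NA_real_, hdi_upper = NA_real_,
                   n_undefined = S - length(v), stringsAsFactors = FALSE)
      }
    }))
    structure(list(samples = r_sb, summary = summ, n_samples = S,
                   hdi_mass = hdi_mass,
                   n_pairs = round(colMeans(n_pairs))),
              class = "wcst_sampled")
  })
}

#' @export
print.wcst_sampled <- function(x, ...) {
  cat(sprintf("Sampled split-half reliability (%d random splits, %.0f%% HDI)\n",
              x$n_samples, 100 * x$hdi_mass))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
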