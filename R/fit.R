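#' Full-test scores of each measure
#'
#' Evaluates every measure on all of a participant's experimental trials
#' (counts of PE/SLE/IE, mean valid RT per trial type, optional conditional
#' error probabilities).
#'
#' @param flags A [trial_flags()] data frame.
#' @param measures Measure names ([wcst_measures()]).
#' @return Numeric matrix, participants x measures; undefined scores are
#'   `NA`.
#' @export
measure_scores <- function(flags, measures = wcst_measures()) {
  ids <- unique(flags$participant_id)
  f <- factor(flags$participant_id, levels = ids)
  cols <- .measure_columns(flags, measures)
  out <- vapply(cols, function(cl) {
    num <- rowsum(cl$num, f)[, 1L]
    if (is.null(cl$den)) num
    else {
      den <- rowsum(cl$den, f)[, 1L]
      ifelse(den > 0, num / den, NA_real_)
    }
  }, numeric(length(ids)))
  out <- matrix(out, nrow = length(ids),
                dimnames = list(ids, measures))
  out
}

#' Split-half reliability analysis of a cWCST cohort
#'
#' The package's main fitting function. Applies the cohort-level validity
#' screen, precomputes trial labels, error flags and the RT validity mask,
#' and estimates the split-half reliability of each measure under the
#' first/second and odd/even systematic splits and under `n_samples`
#' random balanced splits, Spearman-Brown corrected, with the sampled
#' distribution summarized by its median and highest density interval.
#'
#' @param cohort A trial-log data frame (e.g. from [generate_cohort()] or
#'   [read_trial_logs()]).
#' @param measures Measure names ([wcst_measures()]).
#' @param n_samples Number of random splits (default 1000).
#' @param hdi_mass HDI mass (default 0.95).
#' @param filter A [wcst_filter()].
#' @param screen Apply [screen_participants()] before analysis?
#' @param seed Optional integer seed for the random splits.
#' @return An object of class `"wcst_reliability"` with components
#'   `table` (one row per measure: full-test mean and SD, first/second and
#'   odd/even `r_sb`, random-split median and HDI bounds), `samples`
#'   (matrix of sampled `r_sb`), `systematic` (the per-strategy estimates
#'   with raw `r` and `n_pairs`), `screening`, `scores`, `rt`,
#'   `n_included`, `n_excluded`, `call`. Methods: `print`, `summary`,
#'   `coef`, `plot`.
#' @examples
#' cohort <- simulate(wcst_population(n_participants = 40), seed = 7)
#' fit <- wcst_reliability(cohort, n_samples = 200, seed = 1)
#' fit
#' coef(fit)
#' @export
wcst_reliability <- function(cohort, measures = wcst_measures(),
                             n_samples = 1000L, hdi_mass = 0.95,
                             filter = wcst_filter(), screen = TRUE,
                             seed = NULL) {
  prep <- .analysable_cohort(cohort, filter, screen)
  cohort <- prep$cohort
  screening <- prep$screening
  n_excluded <- prep$n_excluded
  flags <- trial_flags(cohort, filter)
  scores <- score_errors(cohort)
  rt <- rt_summary(cohort, flags, filter)
  full <- measure_scores(flags, measures)

  sys_fs <- reliability_estimate(cohort, "first_second", measures, filter, flags)
  sys_oe <- reliability_estimate(cohort, "odd_even", measures, filter, flags)
  sampled <- sample_reliability(cohort, measures, n_samples, hdi_mass,
                                filter, flags, seed = seed)

  tab <- data.frame(
    measure = measures,
    mean = colMeans(full, na.rm = TRUE),
    sd = apply(full, 2L, sd, na.rm = TRUE),
    r_sb_first_second = sys_fs$r_sb,
    r_sb_odd_even = sys_oe$r_sb,
    r_sb_random_median = sampled$summary$median,
    hdi_lower = sampled$summary$hdi_lower,
    hdi_upper = sampled$summary$hdi_upper,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, samples = sampled$samples,
                 sampled = sampled,
                 systematic = rbind(sys_fs, sys_oe),
                 screening = screening, scores = scores, rt = rt,
                 n_included = length(unique(cohort$participant_id)),
                 n_excluded = n_excluded,
                 n_samples = sampled$n_samples, hdi_mass = hdi_mass,
                 measures = measures, call = match.call()),
            class = "wcst_reliability")
}

#' @export
print.wcst_reliability <- function(x, digits = 4, ...) {
  cat("Split-half reliability of cWCST measures\n")
  cat(sprintf("  %d participants analysed (%d excluded by validity screen); %d random splits\n",
              x$n_included, x$n_excluded, x$n_samples))
  print(x$table, row.names = FALSE, digits = digits)
  invisible(x)
}

#' @export
summary.wcst_reliability <- function(object, ...) {
  structure(list(fit = object), class = "summary.wcst_reliability")
}

#' @export
print.summary.wcst_reliability <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nError scores (per participant):\n")
  sc <- fit$scores
  for (v in c("n_trials", "n_switch", "n_repeat", "n_inference",
              "pe", "sle", "ie"))
    cat(sprintf("  %-12s mean %7.2f  sd %6.2f\n", v, mean(sc[[v]]),
                sd(sc[[v]])))
  cat("\nValid trials and mean RT (ms) per trial type:\n")
  rt <- fit$rt
  for (ty in c("switch", "repeat", "inference"))
    cat(sprintf("  %-10s n %6.2f (sd %5.2f)   RT %7.0f (sd %5.0f)\n", ty,
                mean(rt[[paste0("n_", ty)]]), sd(rt[[paste0("n_", ty)]]),
                mean(rt[[paste0("rt_", ty)]], na.rm = TRUE),
                sd(rt[[paste0("rt_", ty)]], na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.wcst_reliability <- function(object, ...) {
  m <- as.matrix(object$table[, c("r_sb_first_second", "r_sb_odd_even",
                                  "r_sb_random_median")])
  rownames(m) <- object$table$measure
  colnames(m) <- c("first_second", "odd_even", "random_median")
  m
}

#' @export
plot.wcst_reliability <- function(x, measures = x$measures, breaks = 30,
                                  ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(measures)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in measures) {
    v <- x$samples[, m]
    v <- v[is.finite(v)]
    graphics::hist(v, breaks = breaks, main = m,
                   xlab = expression(r[SB]), col = "grey80", border = "white")
    i <- match(m, x$table$measure)
    graphics::abline(v = x$table$r_sb_random_median[i], lwd = 2)
    graphics::abline(v = c(x$table$hdi_lower[i], x$table$hdi_upper[i]),
                     lty = 2)
  }
  invisible(x)
}
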