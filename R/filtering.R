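#' Filtering configuration
#'
#' Thresholds for the trial-level response-time exclusions and the
#' cohort-level participant validity screen. Trials faster than
#' `rt_floor_ms` (strictly) or slower than the participant's own mean RT
#' plus `rt_ceiling_sd` individual standard deviations are excluded from RT
#' analysis, as are trials on which a PE, SLE or IE was committed. A
#' participant is screened out when any category's application count lies
#' more than `validity_sd` cohort standard deviations from the cohort mean
#' count of that category.
#'
#' Standard deviations are sample standard deviations (denominator n - 1)
#' throughout, the convention in psychological research; set
#' `sd_denominator = "population"` for the n denominator.
#'
#' @param rt_floor_ms RT floor in milliseconds (default 100; exclusion is
#'   strict, an RT of exactly the floor is kept).
#' @param rt_ceiling_sd Individual SDs above the individual mean defining
#'   the RT ceiling (default 3).
#' @param validity_sd Cohort SDs defining the validity screen (default 3).
#' @param sd_denominator `"sample"` or `"population"`.
#' @return A list of class `"wcst_filter"`.
#' @export
wcst_filter <- function(rt_floor_ms = 100, rt_ceiling_sd = 3,
                        validity_sd = 3,
                        sd_denominator = c("sample", "population")) {
  if (rt_floor_ms <= 0 || rt_ceiling_sd <= 0 || validity_sd <= 0)
    stop("all filter thresholds must be positive")
  structure(list(rt_floor_ms = rt_floor_ms, rt_ceiling_sd = rt_ceiling_sd,
                 validity_sd = validity_sd,
                 sd_denominator = match.arg(sd_denominator)),
            class = "wcst_filter")
}

.sd <- function(x, denominator = "sample") {
  if (identical(denominator, "population")) {
    n <- sum(!is.na(x))
    sqrt(sum((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE) / n)
  } else sd(x, na.rm = TRUE)
}

#' Cohort-level participant validity screen
#'
#' Flags participants whose category application counts are extreme
#' relative to the cohort: for each category (color, shape, number, other)
#' the cohort mean and standard deviation of the per-participant
#' application counts are computed across all participants, and a
#' participant is excluded when any of their counts deviates from the
#' cohort mean by strictly more than `validity_sd` standard deviations. The
#' screen is a single pass: cohort statistics are not recomputed after
#' exclusion, so re-screening the included subset against the original
#' statistics changes nothing.
#'
#' @param cohort A trial-log data frame with at least 2 participants.
#' @param filter A [wcst_filter()].
#' @return Data frame, one row per participant: category counts, `excluded`
#'   flag and a `reason` string; cohort means and SDs are attached as
#'   attributes `cohort_mean` and `cohort_sd`.
#' @export
screen_participants <- function(cohort, filter = wcst_filter()) {
  counts <- category_counts(cohort)
  if (nrow(counts) < 2L)
    stop("validity screening needs at least 2 participants")
  m <- vapply(counts[.applied_levels], mean, numeric(1))
  s <- vapply(counts[.applied_levels], .sd, numeric(1),
              denominator = filter$sd_denominator)
  dev <- abs(sweep(as.matrix(counts[.applied_levels]), 2L, m))
  lim <- filter$validity_sd * s
  flag <- sweep(dev, 2L, lim) > 0
  excluded <- rowSums(flag) > 0L
  reason <- apply(flag, 1L, function(r)
    if (any(r)) paste0("category count beyond +/-", filter$validity_sd,
                       " SD: ", paste(.applied_levels[r], collapse = ", "))
    else "")
  out <- counts
  out$excluded <- excluded
  out$reason <- reason
  attr(out, "cohort_mean") <- m
  attr(out, "cohort_sd") <- s
  out
}

# Restrict a cohort to analysable participants: the single-pass validity
# screen, plus removal of participants with fewer than 2 experimental
# trials (their logs cannot be split into halves and their RT cutoff is
# undefined; such records only arise from degenerate simulated agents that
# never leave the practice block).
.analysable_cohort <- function(cohort, filter = wcst_filter(),
                               screen = TRUE) {
  screening <- NULL
  excluded_ids <- character()
  if (screen) {
    screening <- screen_participants(cohort, filter)
    excluded_ids <- screening$participant_id[screening$excluded]
  }
  ex <- experimental_trials(cohort)
  cnt <- table(ex$participant_id)
  too_few <- setdiff(
    unique(cohort$participant_id),
    names(cnt)[cnt >= 2L]
  )
  if (!is.null(screening) && length(too_few)) {
    i <- screening$participant_id %in% too_few
    screening$excluded[i] <- TRUE
    screening$reason[i] <- "fewer than 2 experimental trials"
  }
  drop <- union(excluded_ids, too_few)
  out <- cohort[!cohort$participant_id %in% drop, , drop = FALSE]
  if (length(unique(out$participant_id)) == 0L)
    stop("all participants were screened out")
  list(cohort = out, screening = screening, n_excluded = length(drop))
}

#' Individual RT cutoffs
#'
#' The ceiling for each participant is their mean RT plus `rt_ceiling_sd`
#' individual standard deviations, computed over all of their experimental
#' trials before any exclusion (error trials included).
#'
#' @param cohort A trial-log data frame.
#' @param filter A [wcst_filter()].
#' @return Data frame: `participant_id`, `mean_rt`, `sd_rt`, `cutoff_ms`.
#' @export
rt_cutoffs <- function(cohort, filter = wcst_filter()) {
  ex <- experimental_trials(cohort)
  ids <- unique(ex$participant_id)
  f <- factor(ex$participant_id, levels = ids)
  n <- as.integer(table(f))
  if (any(n < 2L))
    stop("RT cutoff undefined: a participant has fewer than 2 experimental trials")
  mu <- as.numeric(tapply(ex$rt_ms, f, mean))
  s <- as.numeric(tapply(ex$rt_ms, f, .sd, denominator = filter$sd_denominator))
  data.frame(participant_id = ids, mean_rt = mu, sd_rt = s,
             cutoff_ms = mu + filter$rt_ceiling_sd * s,
             stringsAsFactors = FALSE)
}

#' Trial-level RT validity mask
#'
#' A trial enters RT analysis when its RT is at least `rt_floor_ms`
#' (exclusion below the floor is strict), at most the participant's
#' individual cutoff (mean + `rt_ceiling_sd` SD over all their experimental
#' trials before exclusion), and no PE, SLE or IE was committed on it.
#'
#' @param cohort A trial-log data frame.
#' @param labels Optional [classify_trials()] result.
#' @param filter A [wcst_filter()].
#' @return Logical vector aligned with `experimental_trials(cohort)`.
#' @export
valid_rt_mask <- function(cohort, labels = NULL, filter = wcst_filter()) {
  ex <- experimental_trials(cohort)
  if (is.null(labels)) labels <- classify_trials(cohort)
  flags <- .error_flags(ex, labels)
  cut <- rt_cutoffs(cohort, filter)
  ceiling_ms <- cut$cutoff_ms[match(ex$participant_id, cut$participant_id)]
  ex$rt_ms >= filter$rt_floor_ms & ex$rt_ms <= ceiling_ms &
    !(flags$pe | flags$sle | flags$ie)
}

#' Per-trial analysis flags
#'
#' One-stop precomputation for reliability analysis: for every experimental
#' trial, the trial-type label, the inference flag, the PE/SLE/IE flags and
#' the RT validity mask. Half-test scores are recomputed from these global
#' flags, restricted to the trials inside a given half.
#'
#' @param cohort A trial-log data frame.
#' @param filter A [wcst_filter()].
#' @return Data frame aligned with `experimental_trials(cohort)`:
#'   `participant_id`, `trial`, `label`, `is_inference`, `pe`, `sle`, `ie`,
#'   `rt_ms`, `rt_valid`.
#' @export
trial_flags <- function(cohort, filter = wcst_filter()) {
  ex <- experimental_trials(cohort)
  labels <- classify_trials(cohort)
  flags <- .error_flags(ex, labels)
  data.frame(
    participant_id = ex$participant_id,
    trial = ex$trial_index,
    label = labels$label,
    is_inference = labels$is_inference,
    pe = flags$pe, sle = flags$sle, ie = flags$ie,
    rt_ms = ex$rt_ms,
    rt_valid = valid_rt_mask(cohort, labels, filter),
    stringsAsFactors = FALSE
  )
}

#' Mean RT by trial type
#'
#' Arithmetic mean RT over valid (masked-in) trials, per participant and
#' trial type. Inference trials are a sub-type of switch trials and
#' contribute to both the switch and the inference mean. A type with no
#' valid trials yields `NA` (undefined, not zero).
#'
#' @param cohort A trial-log data frame.
#' @param flags Optional [trial_flags()] result.
#' @param filter A [wcst_filter()].
#' @return Data frame per participant: valid-trial counts (`n_switch`,
#'   `n_repeat`, `n_inference`) and mean RTs (`rt_switch`, `rt_repeat`,
#'   `rt_inference`).
#' @export
rt_summary <- function(cohort, flags = NULL, filter = wcst_filter()) {
  if (is.null(flags)) flags <- trial_flags(cohort, filter)
  ids <- unique(flags$participant_id)
  f <- factor(flags$participant_id, levels = ids)
  one <- function(sel) {
    n <- as.integer(rowsum(as.integer(sel), f)[, 1L])
    s <- rowsum(ifelse(sel, flags$rt_ms, 0), f)[, 1L]
    list(n = n, mean = ifelse(n > 0L, s / n, NA_real_))
  }
  sw <- one(flags$rt_valid & flags$label == "switch")
  rp <- one(flags$rt_valid & flags$label == "repeat")
  inf_ <- one(flags$rt_valid & flags$is_inference)
  data.frame(participant_id = ids,
             n_switch = sw$n, n_repeat = rp$n, n_inference = inf_$n,
             rt_switch = sw$mean, rt_repeat = rp$mean,
             rt_inference = inf_$mean, stringsAsFactors = FALSE)
}
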