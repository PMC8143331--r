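# lag helpers over a stacked per-participant vector; `first` marks the first
# experimental trial of each participant
.lag1 <- function(x, first) {
  n <- length(x)
  y <- c(x[0][NA], x)[seq_len(n)]
  y[first] <- NA
  y
}
.lag2 <- function(x, first) {
  n <- length(x)
  y <- c(x[0][NA], x[0][NA], x)[seq_len(n)]
  y[first | .shift_flag(first)] <- NA
  y
}
.shift_flag <- function(first) {
  n <- length(first)
  c(FALSE, first[-n])
}

#' Classify experimental trials as switch, repeat or inference trials
#'
#' A trial is a switch trial if the preceding trial received negative
#' feedback and a repeat trial if it received positive feedback; the first
#' experimental trial of each participant is unlabeled (no preceding
#' feedback). Inference trials are the sub-type of switch trials whose
#' preceding trial was itself a switch trial on which the applied category
#' was switched (to a different genuine category, not the no-match key) and
#' again followed by negative feedback: at that point two of the three
#' categories have been disconfirmed, so the prevailing category is
#' logically deducible.
#'
#' @param cohort A trial-log data frame; only experimental-block trials are
#'   classified.
#' @return Data frame aligned with `experimental_trials(cohort)`:
#'   `participant_id`, `label` (`"unlabeled"`, `"switch"`, `"repeat"`),
#'   `is_inference`.
#' @examples
#' log <- run_session(wcst_agent(p_persev = 0.2), seed = 1)
#' table(classify_trials(log)$label)
#' @export
classify_trials <- function(cohort) {
  ex <- experimental_trials(cohort)
  n <- nrow(ex)
  if (n == 0L)
    return(data.frame(participant_id = character(), label = character(),
                      is_inference = logical(), stringsAsFactors = FALSE))
  first <- !duplicated(ex$participant_id)
  fb1 <- .lag1(ex$feedback, first)
  fb2 <- .lag2(ex$feedback, first)
  ap1 <- .lag1(ex$applied_category, first)
  ap2 <- .lag2(ex$applied_category, first)
  label <- ifelse(is.na(fb1), "unlabeled",
                  ifelse(fb1 == "negative", "switch", "repeat"))
  is_inf <- !is.na(fb2) & fb2 == "negative" & !is.na(fb1) & fb1 == "negative" &
    ap1 != ap2 & ap1 != "other" & ap2 != "other"
  is_inf[is.na(is_inf)] <- FALSE
  data.frame(participant_id = ex$participant_id, label = label,
             is_inference = is_inf, stringsAsFactors = FALSE)
}

# per-trial error flags aligned with experimental trials
.error_flags <- function(ex, labels) {
  first <- !duplicated(ex$participant_id)
  ap1 <- .lag1(ex$applied_category, first)
  pe <- labels$label == "switch" & !is.na(ap1) &
    ex$applied_category == ap1 & ex$applied_category != "other"
  sle <- labels$label == "repeat" & !is.na(ap1) & ex$applied_category != ap1
  ie <- labels$is_inference &
    ex$applied_category != ex$prevailing_category
  data.frame(pe = pe, sle = sle, ie = ie)
}

#' Score perseveration, set-loss and inference errors
#'
#' Counts, per participant over the experimental block: perseveration
#' errors (PE; repeating the previously applied category on a switch
#' trial), set-loss errors (SLE; abandoning the previously applied category
#' on a repeat trial) and inference errors (IE; applying any category other
#' than the prevailing one on an inference trial). A perseverative response
#' on an inference trial satisfies both the PE and the IE definition and
#' increments both counters; a no-match ("other") response counts as SLE on
#' repeat trials and IE on inference trials but never as PE. The unlabeled
#' first trial contributes to `n_trials` but to no error tally.
#'
#' @param cohort A trial-log data frame.
#' @param labels Optional result of [classify_trials()] for `cohort`;
#'   recomputed when `NULL`. Must align 1:1 with the experimental trials.
#' @return A data frame of class `"wcst_scores"`, one row per participant:
#'   `participant_id`, `n_trials`, `n_switch`, `n_repeat`, `n_inference`,
#'   `pe`, `sle`, `ie`.
#' @examples
#' log <- run_session(wcst_agent(p_persev = 0.3, p_setloss = 0.05), seed = 2)
#' score_errors(log)
#' @export
score_errors <- function(cohort, labels = NULL) {
  ex <- experimental_trials(cohort)
  if (is.null(labels)) labels <- classify_trials(cohort)
  if (nrow(labels) != nrow(ex))
    stop("'labels' does not align with the experimental trials of 'cohort'")
  ids <- unique(ex$participant_id)
  f <- factor(ex$participant_id, levels = ids)
  flags <- .error_flags(ex, labels)
  agg <- function(x) as.integer(rowsum(as.integer(x), f)[, 1L])
  out <- data.frame(
    participant_id = ids,
    n_trials = as.integer(table(f)),
    n_switch = agg(labels$label == "switch"),
    n_repeat = agg(labels$label == "repeat"),
    n_inference = agg(labels$is_inference),
    pe = agg(flags$pe),
    sle = agg(flags$sle),
    ie = agg(flags$ie),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("wcst_scores", "data.frame")
  out
}

#' @export
print.wcst_scores <- function(x, ...) {
  cat(sprintf("cWCST error scores: %d participants\n", nrow(x)))
  print(as.data.frame(head(x, 10L)))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Per-participant category application counts
#'
#' Tallies how often each participant applied the color, shape and number
#' categories and the no-match key over the experimental block. These
#' counts feed the cohort-level validity screen ([screen_participants()]).
#'
#' @param cohort A trial-log data frame.
#' @return Data frame with `participant_id` and integer columns `color`,
#'   `shape`, `number`, `other`; rows sum to the participant's experimental
#'   trial count.
#' @export
category_counts <- function(cohort) {
  ex <- experimental_trials(cohort)
  ids <- unique(ex$participant_id)
  tab <- table(factor(ex$participant_id, levels = ids),
               factor(ex$applied_category, levels = .applied_levels))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (lv in .applied_levels) out[[lv]] <- as.integer(tab[, lv])
  out
}
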