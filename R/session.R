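# Assemble the integer-coded columns returned by the C++ simulator into a
# trial-log data frame with the external column vocabulary.
.assemble_log <- function(raw, participant_ids) {
  log <- data.frame(
    participant_id = participant_ids[raw$agent],
    block = c("practice", "experimental")[raw$block + 1L],
    trial_index = raw$trial_index,
    stim_number = raw$stim_number,
    stim_color = .colors[raw$stim_color_pos],
    stim_shape = .shapes[raw$stim_shape_pos],
    prevailing_category = .categories[raw$prevailing],
    response = raw$response,
    applied_category = .applied_levels[raw$applied],
    feedback = c("negative", "positive")[raw$feedback + 1L],
    rt_ms = raw$rt_ms,
    stringsAsFactors = FALSE
  )
  class(log) <- c("wcst_cohort", "data.frame")
  log
}

#' Simulate one cWCST session
#'
#' Runs a generative agent through a full session: a practice block ending
#' after the configured number of category switches, then an experimental
#' block ending after its switch target or once the combined trial count
#' reaches the session cap, whichever comes first. Stimulus cards, the
#' category-switch schedule and the agent's behavior are all drawn from R's
#' random number stream, so the resulting log is a pure function of
#' (agent, task, seed).
#'
#' @param agent A [wcst_agent()].
#' @param task A [wcst_task()].
#' @param seed Optional integer; if supplied, `set.seed(seed)` is applied
#'   first (the previous RNG state is restored on exit).
#' @param participant_id Identifier written to the log.
#' @return A trial-log data frame of class `"wcst_cohort"` with one row per
#'   trial and columns `participant_id`, `block`, `trial_index`,
#'   `stim_number`, `stim_color`, `stim_shape`, `prevailing_category`,
#'   `response`, `applied_category`, `feedback`, `rt_ms`.
#' @examples
#' log <- run_session(wcst_agent(p_persev = 0.2), wcst_task(), seed = 1)
#' head(log)
#' @export
run_session <- function(agent, task = wcst_task(), seed = NULL,
                        participant_id = "P1") {
  stopifnot(inherits(agent, "wcst_agent"), inherits(task, "wcst_task"))
  .with_seed(seed, {
    raw <- cpp_simulate_cohort(.agent_param_matrix(agent),
                               task$n_practice_switches,
                               task$n_experimental_switches,
                               task$max_total_trials,
                               task$run_length_support)
    log <- .assemble_log(raw, participant_id)
    attr(log, "task") <- task
    log
  })
}

# evaluate `expr` under set.seed(seed), restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Experimental-block trials of a cohort
#'
#' Downstream scoring, filtering and reliability analysis operate on
#' experimental trials only; practice trials are retained in logs but
#' flagged by `block`.
#'
#' @param cohort A trial-log data frame (`"wcst_cohort"`).
#' @return The experimental-block rows.
#' @export
experimental_trials <- function(cohort) {
  out <- cohort[cohort$block == "experimental", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a cohort into per-participant logs
#'
#' @param cohort A trial-log data frame.
#' @return Named list of per-participant data frames, in order of first
#'   appearance.
#' @export
participant_logs <- function(cohort) {
  ids <- unique(cohort$participant_id)
  out <- split(as.data.frame(cohort), factor(cohort$participant_id, levels = ids))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Validate a trial-log data frame
#'
#' Checks the structural invariants of a trial log: required columns, legal
#' attribute values, stimulus-card validity, consecutive 1-based trial
#' indices within each participant-block, and the consistency of
#' `applied_category` and `feedback` with the stimulus, the response and the
#' prevailing category (both are recomputed from first principles).
#'
#' @param cohort A trial-log data frame.
#' @return Invisibly, the validated cohort (classed `"wcst_cohort"`).
#' @export
validate_cohort <- function(cohort) {
  req <- c("participant_id", "block", "trial_index", "stim_number",
           "stim_color", "stim_shape", "prevailing_category", "response",
           "applied_category", "feedback", "rt_ms")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("invalid trial log: %s (first offending row %d)", what, i[1]))
  }
  bad(!cohort$block %in% c("practice", "experimental"), "unknown block")
  bad(!cohort$stim_number %in% 1:4, "stim_number outside 1..4")
  bad(!cohort$stim_color %in% .colors, "unknown stim_color")
  bad(!cohort$stim_shape %in% .shapes, "unknown stim_shape")
  bad(!cohort$prevailing_category %in% .categories, "unknown prevailing_category")
  bad(!cohort$response %in% 1:4, "response outside 1..4")
  bad(!is.finite(cohort$rt_ms) | cohort$rt_ms <= 0, "non-positive rt_ms")

  # stimulus validity: the three matched key positions must be distinct
  cpos <- match(cohort$stim_color, .colors)
  spos <- match(cohort$stim_shape, .shapes)
  npos <- as.integer(cohort$stim_number)
  bad(cpos == spos | cpos == npos | spos == npos, "ambiguous stimulus card")

  # recompute applied category and feedback
  applied <- rep("other", nrow(cohort))
  applied[cohort$response == cpos] <- "color"
  applied[cohort$response == spos] <- "shape"
  applied[cohort$response == npos] <- "number"
  bad(applied != cohort$applied_category,
      "applied_category inconsistent with stimulus and response")
  fb <- ifelse(applied == cohort$prevailing_category, "positive", "negative")
  bad(fb != cohort$feedback, "feedback inconsistent with applied category")

  # consecutive trial indices within participant x block
  grp <- interaction(cohort$participant_id, cohort$block, drop = TRUE)
  ok <- unlist(lapply(split(cohort$trial_index, grp), function(ti)
    identical(as.integer(ti), seq_along(ti))), use.names = FALSE)
  if (!all(ok))
    stop("invalid trial log: trial_index not consecutive from 1 within a block")
  if (!inherits(cohort, "wcst_cohort"))
    class(cohort) <- c("wcst_cohort", "data.frame")
  invisible(cohort)
}

#' @export
print.wcst_cohort <- function(x, ...) {
  ids <- unique(x$participant_id)
  cat(sprintf("cWCST trial log: %d participants, %d trials (%d experimental)\n",
              length(ids), nrow(x), sum(x$block == "experimental")))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
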