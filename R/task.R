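#' cWCST task configuration
#'
#' Describes the structure of a computerized Wisconsin Card Sorting Test
#' session: a practice block ending after `n_practice_switches` switches of
#' the prevailing category, followed by an experimental block ending after
#' `n_experimental_switches` switches or once the combined practice plus
#' experimental trial count reaches `max_total_trials`, whichever comes
#' first. The prevailing category switches unpredictably after a run of
#' correct sorts whose required length is drawn uniformly from
#' `run_length_support`; the successor category is drawn uniformly from the
#' two alternatives.
#'
#' The timing fields are presentation metadata carried into logs for
#' completeness; no computation uses them.
#'
#' @param n_practice_switches Category switches ending the practice block.
#' @param n_experimental_switches Category switches ending the experimental
#'   block.
#' @param max_total_trials Cap on practice + experimental trials.
#' @param run_length_support Integer set of admissible run lengths (number
#'   of correct sorts required before a switch); all values must be at least
#'   `min_run_length`.
#' @param min_run_length Minimum admissible run length (at least 2).
#' @param feedback_delay_ms,feedback_duration_ms,stimulus_delay_ms Display
#'   timing metadata, milliseconds.
#' @return A list of class `"wcst_task"`.
#' @examples
#' wcst_task()
#' @export
wcst_task <- function(n_practice_switches = 6L,
                      n_experimental_switches = 40L,
                      max_total_trials = 250L,
                      run_length_support = 2:6,
                      min_run_length = 2L,
                      feedback_delay_ms = 500,
                      feedback_duration_ms = 300,
                      stimulus_delay_ms = 500) {
  task <- list(
    n_practice_switches = as.integer(n_practice_switches),
    n_experimental_switches = as.integer(n_experimental_switches),
    max_total_trials = as.integer(max_total_trials),
    run_length_support = as.integer(sort(unique(run_length_support))),
    min_run_length = as.integer(min_run_length),
    categories = .categories,
    feedback_delay_ms = feedback_delay_ms,
    feedback_duration_ms = feedback_duration_ms,
    stimulus_delay_ms = stimulus_delay_ms
  )
  if (task$min_run_length < 2L)
    stop("'min_run_length' must be at least 2")
  if (any(task$run_length_support < task$min_run_length))
    stop("all values in 'run_length_support' must be >= min_run_length")
  if (task$n_practice_switches < 0L || task$n_experimental_switches < 1L ||
      task$max_total_trials < 1L)
    stop("switch targets and trial cap must be positive")
  class(task) <- "wcst_task"
  task
}

#' @export
print.wcst_task <- function(x, ...) {
  cat("cWCST task configuration\n")
  cat(sprintf("  practice: %d switches; experimental: %d switches\n",
              x$n_practice_switches, x$n_experimental_switches))
  cat(sprintf("  trial cap (practice + experimental): %d\n", x$max_total_trials))
  cat(sprintf("  run lengths: uniform on {%s} correct sorts\n",
              paste(x$run_length_support, collapse = ", ")))
  invisible(x)
}

#' Draw a category-switch schedule
#'
#' Samples the sequence of prevailing categories and the required run
#' lengths (correct sorts before each switch) for a block with `n_switches`
#' category switches. Each run length is drawn uniformly from the task's
#' `run_length_support`; each successor category is drawn uniformly from the
#' two alternatives, so the category never repeats across a switch. Uses the
#' current R random number stream.
#'
#' A switch is triggered only once the run's required count of correct sorts
#' has been reached; errors neither advance nor reset the count.
#'
#' @param n_switches Number of switches to schedule.
#' @param task A [wcst_task()].
#' @return Data frame with one row per run: `run`, `category`,
#'   `run_length` (required correct sorts). Contains `n_switches + 1` runs;
#'   the final run is the one left incomplete when the block ends.
#' @export
category_schedule <- function(n_switches, task = wcst_task()) {
  stopifnot(inherits(task, "wcst_task"), n_switches >= 1)
  n_runs <- n_switches + 1L
  cats <- character(n_runs)
  cats[1L] <- sample(.categories, 1L)
  for (i in seq_len(n_runs - 1L)) {
    cats[i + 1L] <- sample(setdiff(.categories, cats[i]), 1L)
  }
  sup <- task$run_length_support
  lens <- sup[sample.int(length(sup), n_runs, replace = TRUE)]
  data.frame(run = seq_len(n_runs), category = cats, run_length = lens,
             stringsAsFactors = FALSE)
}
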