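#' Read trial logs from CSV
#'
#' Reads a trial-log CSV (one row per trial, columns `participant_id`,
#' `block`, `trial_index`, `stim_number`, `stim_color`, `stim_shape`,
#' `prevailing_category`, `response`, `applied_category`, `feedback`,
#' `rt_ms`) and validates it with [validate_cohort()]: attribute values and
#' stimulus cards are checked, and `applied_category` and `feedback` are
#' recomputed from the stimulus, response and prevailing category;
#' inconsistent files are rejected with the offending row.
#'
#' @param path CSV file path.
#' @return A `"wcst_cohort"` trial-log data frame.
#' @export
read_trial_logs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$participant_id <- as.character(df$participant_id)
  validate_cohort(df)
  class(df) <- c("wcst_cohort", "data.frame")
  df
}

#' Write trial logs to CSV
#'
#' @param cohort A trial-log data frame.
#' @param path Output CSV file path.
#' @return Invisibly, `path`.
#' @export
write_trial_logs <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration mirroring the arguments of
#' [wcst_pipeline_config()]; nested blocks `task`, `population`, `filter`
#' and `reliability` map onto [wcst_task()], [wcst_population()],
#' [wcst_filter()] and the reliability settings. Exactly one input source
#' must be given: `input_csv` (trial logs to analyse) or a `population`
#' block (cohort simulation).
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A `"wcst_pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_named <- function(x) if (is.list(x)) unlist(x) else x
  pop <- if (!is.null(raw$population)) {
    args <- raw$population
    for (nm in c("persev", "setloss", "inferr", "rt_mean_ms", "rt_sd_ms",
                 "rt_sdlog"))
      if (!is.null(args[[nm]])) args[[nm]] <- as_named(args[[nm]])
    do.call(wcst_population, args)
  }
  task <- if (is.null(raw$task)) wcst_task() else do.call(wcst_task, raw$task)
  filter <- if (is.null(raw$filter)) wcst_filter()
            else do.call(wcst_filter, raw$filter)
  rel <- raw$reliability
  wcst_pipeline_config(
    input_csv = raw$input_csv,
    population = pop,
    task = task,
    filter = filter,
    measures = if (is.null(rel$measures)) wcst_measures() else
      unlist(rel$measures),
    n_samples = if (is.null(rel$n_samples)) 1000L else rel$n_samples,
    hdi_mass = if (is.null(rel$hdi_mass)) 0.95 else rel$hdi_mass,
    seed = raw$seed
  )
}
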