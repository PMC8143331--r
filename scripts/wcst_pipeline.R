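#!/usr/bin/env Rscript

# Thin command-line wrapper over the wcstsplit package.
#
# Usage:
#   Rscript scripts/wcst_pipeline.R all        --config cfg.yaml --out DIR
#   Rscript scripts/wcst_pipeline.R simulate   --config cfg.yaml --out DIR
#   Rscript scripts/wcst_pipeline.R score      --logs logs.csv   --out DIR
#   Rscript scripts/wcst_pipeline.R filter     --logs logs.csv   --out DIR
#   Rscript scripts/wcst_pipeline.R reliability --logs logs.csv  --out DIR
#                                              [--seed N] [--n-samples N]
#                                              [--hdi-mass M]
#
# The config file (YAML or JSON) mirrors wcst_pipeline_config(); see
# ?read_pipeline_config.

suppressPackageStartupMessages(library(wcstsplit))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("missing subcommand; see the header of this script")
cmd <- args[1L]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
out_dir <- get_arg("--out", "wcst_output")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
msg <- function(...) cat(sprintf(...), "\n", file = stderr())

load_config <- function() {
  path <- get_arg("--config")
  cfg <- if (is.null(path))
    wcst_pipeline_config(population = wcst_population(), seed = 1L)
  else read_pipeline_config(path)
  seed <- get_arg("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ns <- get_arg("--n-samples")
  if (!is.null(ns)) cfg$n_samples <- as.integer(ns)
  hm <- get_arg("--hdi-mass")
  if (!is.null(hm)) cfg$hdi_mass <- as.numeric(hm)
  cfg
}

load_logs <- function() {
  path <- get_arg("--logs")
  if (is.null(path)) stop("this subcommand needs --logs <trial log CSV>")
  logs <- read_trial_logs(path)
  msg("read %d trials from %d participants", nrow(logs),
      length(unique(logs$participant_id)))
  logs
}

if (cmd == "simulate") {
  cfg <- load_config()
  if (is.null(cfg$population)) stop("simulate needs a population block")
  cohort <- generate_cohort(cfg$population, cfg$task, seed = cfg$seed)
  write_trial_logs(cohort, file.path(out_dir, "trial_logs.csv"))
  jsonlite::write_json(as.data.frame(attr(cohort, "agents")),
                       file.path(out_dir, "agents.json"), digits = NA)
  msg("simulated %d participants (%d trials) -> %s",
      length(unique(cohort$participant_id)), nrow(cohort), out_dir)
} else if (cmd == "score") {
  logs <- load_logs()
  write.csv(as.data.frame(score_errors(logs)),
            file.path(out_dir, "participant_scores.csv"), row.names = FALSE)
  msg("scores -> %s", file.path(out_dir, "participant_scores.csv"))
} else if (cmd == "filter") {
  logs <- load_logs()
  scr <- screen_participants(logs)
  write.csv(as.data.frame(scr), file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)
  keep <- scr$participant_id[!scr$excluded]
  write.csv(rt_summary(logs[logs$participant_id %in% keep, ]),
            file.path(out_dir, "rt_summary.csv"), row.names = FALSE)
  msg("%d of %d participants retained", length(keep), nrow(scr))
} else if (cmd == "reliability" || cmd == "all") {
  cfg <- load_config()
  if (cmd == "reliability") {
    cfg$input_csv <- get_arg("--logs", cfg$input_csv)
    cfg$population <- NULL
    if (is.null(cfg$input_csv)) stop("reliability needs --logs or input_csv")
  }
  res <- run_pipeline(cfg, out_dir = out_dir)
  msg("analysed %d participants (%d excluded); outputs in %s",
      res$manifest$n_included, res$manifest$n_excluded, out_dir)
} else {
  stop("unknown subcommand: ", cmd)
}
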