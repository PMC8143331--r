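#' Cohort-level generative model of cWCST performance
#'
#' Describes between-participant heterogeneity for simulated cohorts: error
#' probabilities are drawn from beta distributions (parameterized by mean
#' and concentration = shape1 + shape2; an infinite concentration yields
#' identical agents), individual lognormal RT locations are normal on the
#' log scale, and optional per-trial linear drift in RT location and error
#' log-odds is normal with mean zero across participants (heterogeneous
#' long-term trends: some participants speed up or improve, others slow
#' down or deteriorate).
#'
#' RT heterogeneity is specified on the natural scale as the
#' between-participant mean and SD of the individual mean RT per trial
#' type; these moments are converted internally to the location
#' hyperparameters of the lognormal model. The defaults target the
#' descriptive moments typical of young self-administered cohorts:
#' mean RT near 1835/1241/1700 ms (SD 694/441/636 ms) on switch, repeat and
#' inference trials, and error rates that put the average participant near
#' 12 perseveration errors, 5 set-loss errors and 8.5 inference errors per
#' session.
#'
#' @param n_participants Cohort size (at least 2).
#' @param persev,setloss,inferr Named vectors `c(mean, concentration)` of
#'   the beta distributions of `p_persev`, `p_setloss`, `p_inferr`.
#' @param p_other Probability of pressing the no-match key when committing
#'   an erroneous switch (shared by all agents).
#' @param rt_mean_ms,rt_sd_ms Named vectors (`switch`, `repeat`,
#'   `inference`): between-participant mean and SD of individual mean RT.
#' @param rt_sdlog `c(mean, sd)` of the within-participant lognormal scale
#'   (truncated below at 0.05).
#' @param rt_cor Between-participant correlation of the per-type RT
#'   locations, induced by a shared general-speed factor (default 0.8; slow
#'   participants tend to be slow on all trial types).
#' @param drift_rt_sd Between-participant SD of the per-trial RT drift
#'   (log-ms per trial).
#' @param drift_logodds_sd Between-participant SD of the per-trial error
#'   log-odds drift.
#' @return A list of class `"wcst_population"`.
#' @examples
#' pop <- wcst_population(n_participants = 20)
#' cohort <- simulate(pop, seed = 1)
#' @export
wcst_population <- function(n_participants = 375L,
                            persev = c(mean = 0.165, concentration = 2.2),
                            setloss = c(mean = 0.045, concentration = 8),
                            inferr = c(mean = 0.22, concentration = 4),
                            p_other = 0.05,
                            rt_mean_ms = c(switch = 1835, `repeat` = 1241,
                                           inference = 1700),
                            rt_sd_ms = c(switch = 694, `repeat` = 441,
                                         inference = 636),
                            rt_sdlog = c(mean = 0.4, sd = 0.05),
                            rt_cor = 0.8,
                            drift_rt_sd = 0,
                            drift_logodds_sd = 0) {
  chk_beta <- function(x, nm) {
    if (!all(c("mean", "concentration") %in% names(x)) ||
        x[["mean"]] < 0 || x[["mean"]] > 1 || x[["concentration"]] <= 0)
      stop("'", nm, "' needs mean in [0,1] and a positive concentration")
    x
  }
  pop <- list(
    n_participants = as.integer(n_participants),
    persev = chk_beta(persev, "persev"),
    setloss = chk_beta(setloss, "setloss"),
    inferr = chk_beta(inferr, "inferr"),
    p_other = p_other,
    rt_mean_ms = rt_mean_ms[c("switch", "repeat", "inference")],
    rt_sd_ms = rt_sd_ms[c("switch", "repeat", "inference")],
    rt_sdlog = rt_sdlog,
    rt_cor = rt_cor,
    drift_rt_sd = drift_rt_sd,
    drift_logodds_sd = drift_logodds_sd
  )
  if (pop$n_participants < 2L) stop("'n_participants' must be at least 2")
  if (p_other < 0 || p_other > 1) stop("'p_other' must be in [0, 1]")
  if (anyNA(pop$rt_mean_ms) || anyNA(pop$rt_sd_ms) ||
      any(pop$rt_mean_ms <= 0) || any(pop$rt_sd_ms < 0))
    stop("RT moments need positive means and non-negative SDs for switch, repeat, inference")
  if (drift_rt_sd < 0 || drift_logodds_sd < 0)
    stop("drift SDs must be non-negative")
  if (rt_cor < 0 || rt_cor > 1) stop("'rt_cor' must be in [0, 1]")
  class(pop) <- "wcst_population"
  pop
}

#' @export
print.wcst_population <- function(x, ...) {
  cat(sprintf("cWCST population model: %d participants\n", x$n_participants))
  cat(sprintf("  p_persev ~ Beta(mean %.3f, conc %.2f); p_setloss ~ Beta(%.3f, %.2f); p_inferr ~ Beta(%.3f, %.2f)\n",
              x$persev[["mean"]], x$persev[["concentration"]],
              x$setloss[["mean"]], x$setloss[["concentration"]],
              x$inferr[["mean"]], x$inferr[["concentration"]]))
  cat(sprintf("  individual mean RT (ms): switch %0.f (SD %0.f), repeat %0.f (SD %0.f), inference %0.f (SD %0.f)\n",
              x$rt_mean_ms[[1]], x$rt_sd_ms[[1]], x$rt_mean_ms[[2]],
              x$rt_sd_ms[[2]], x$rt_mean_ms[[3]], x$rt_sd_ms[[3]]))
  if (x$drift_rt_sd > 0 || x$drift_logodds_sd > 0)
    cat(sprintf("  drift SDs: RT %.4g, error log-odds %.4g\n",
                x$drift_rt_sd, x$drift_logodds_sd))
  invisible(x)
}

.rbeta_mc <- function(n, mc) {
  m <- mc[["mean"]]; k <- mc[["concentration"]]
  if (m <= 0) return(rep(0, n))
  if (m >= 1) return(rep(1, n))
  if (!is.finite(k)) return(rep(m, n))
  rbeta(n, m * k, (1 - m) * k)
}

# convert target between-person moments of the individual mean RT to the
# normal hyperparameters of the lognormal location
.rt_location_hyper <- function(mean_ms, sd_ms, sdlog_mean) {
  tau2 <- log(1 + (sd_ms / mean_ms)^2)
  mu <- log(mean_ms) - tau2 / 2 - sdlog_mean^2 / 2
  list(mu = mu, tau = sqrt(tau2))
}

#' Draw a cohort of agents from a population model
#'
#' @param population A [wcst_population()].
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return Data frame of class `"wcst_agents"`, one row per participant,
#'   with `participant_id` and the [wcst_agent()] parameters.
#' @export
sample_population <- function(population, seed = NULL) {
  stopifnot(inherits(population, "wcst_population"))
  n <- population$n_participants
  .with_seed(seed, {
    rho <- population$rt_cor
    u <- rnorm(n) # shared general-speed factor
    loc <- lapply(c(switch = "switch", `repeat` = "repeat",
                    inference = "inference"), function(ty) {
      h <- .rt_location_hyper(population$rt_mean_ms[[ty]],
                              population$rt_sd_ms[[ty]],
                              population$rt_sdlog[["mean"]])
      z <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
      h$mu + h$tau * z
    })
    out <- data.frame(
      participant_id = sprintf("S%03d", seq_len(n)),
      p_persev = .rbeta_mc(n, population$persev),
      p_setloss = .rbeta_mc(n, population$setloss),
      p_inferr = .rbeta_mc(n, population$inferr),
      p_other = rep(population$p_other, n),
      loc_switch = loc$switch,
      loc_repeat = loc$`repeat`,
      loc_inference = loc$inference,
      scale_switch = pmax(0.05, rnorm(n, population$rt_sdlog[["mean"]],
                                      population$rt_sdlog[["sd"]])),
      stringsAsFactors = FALSE
    )
    out$scale_repeat <- out$scale_switch
    out$scale_inference <- out$scale_switch
    out$drift_rt <- if (population$drift_rt_sd > 0)
      rnorm(n, 0, population$drift_rt_sd) else rep(0, n)
    out$drift_logodds <- if (population$drift_logodds_sd > 0)
      rnorm(n, 0, population$drift_logodds_sd) else rep(0, n)
    class(out) <- c("wcst_agents", "data.frame")
    out
  })
}

#' Simulate cWCST sessions for a whole cohort
#'
#' Draws agents from the population model and runs each through a full
#' session. The true agent parameters are attached to the returned log as
#' attribute `"agents"` (the provenance sidecar used by parameter-recovery
#' studies; [run_pipeline()] writes it to disk as JSON).
#'
#' @param population A [wcst_population()] or a `"wcst_agents"` data frame.
#' @param task A [wcst_task()].
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return A `"wcst_cohort"` trial-log data frame.
#' @export
generate_cohort <- function(population, task = wcst_task(), seed = NULL) {
  stopifnot(inherits(task, "wcst_task"))
  .with_seed(seed, {
    agents <- if (inherits(population, "wcst_population"))
      sample_population(population) else population
    raw <- cpp_simulate_cohort(.agent_param_matrix(agents),
                               task$n_practice_switches,
                               task$n_experimental_switches,
                               task$max_total_trials,
                               task$run_length_support)
    cohort <- .assemble_log(raw, agents$participant_id)
    attr(cohort, "agents") <- agents
    attr(cohort, "task") <- task
    cohort
  })
}

#' @rdname generate_cohort
#' @param object,nsim,... [stats::simulate()] interface: `object` is the
#'   population model, `nsim` the number of independent cohorts.
#' @return For `simulate()`: a cohort (`nsim = 1`) or a list of cohorts.
#' @export
simulate.wcst_population <- function(object, nsim = 1, seed = NULL,
                                     task = wcst_task(), ...) {
  .with_seed(seed, {
    out <- lapply(seq_len(nsim), function(i) generate_cohort(object, task))
    if (nsim == 1L) out[[1L]] else out
  })
}

#' Monte-Carlo oracle for expected split-half reliability
#'
#' Brute-force reference value for parameter-recovery tests: simulates
#' `n_mc` independent cohorts from the population model, draws one random
#' balanced split per participant in each cohort, computes the half scores
#' of `measure` directly from their definitions, correlates the halves
#' across participants and applies the Spearman-Brown formula. Each cohort
#' passes through the same single-pass validity screen as the analysis
#' pipeline. No split or correlation machinery is shared with
#' [sample_reliability()]; only the per-trial labels, error flags and RT
#' mask are reused.
#'
#' @param population A [wcst_population()].
#' @param task A [wcst_task()].
#' @param measure A single measure name ([wcst_measures()]).
#' @param n_mc Number of Monte-Carlo cohorts (at least 100).
#' @param filter A [wcst_filter()].
#' @param seed Optional integer seed.
#' @return List of class `"wcst_oracle"`: `mean`, `sd` (across-cohort SD,
#'   the Monte-Carlo predictive error of a single-cohort estimate), `se`
#'   (standard error of the mean), `values`, `n_mc`, `n_undefined`.
#' @export
oracle_reliability <- function(population, task = wcst_task(),
                               measure = "pe", n_mc = 200L,
                               filter = wcst_filter(), seed = NULL) {
  stopifnot(inherits(population, "wcst_population"))
  if (n_mc < 100L) stop("'n_mc' must be at least 100")
  measure <- match.arg(measure, wcst_measures(include_probs = TRUE))
  half_value <- function(d, sel) {
    sub <- d[sel, , drop = FALSE]
    v <- switch(measure,
      pe = sum(sub$pe), sle = sum(sub$sle), ie = sum(sub$ie),
      rt_switch = mean(sub$rt_ms[sub$rt_valid & sub$label == "switch"]),
      rt_repeat = mean(sub$rt_ms[sub$rt_valid & sub$label == "repeat"]),
      rt_inference = mean(sub$rt_ms[sub$rt_valid & sub$is_inference]),
      p_pe = sum(sub$pe) / sum(sub$label == "switch"),
      p_sle = sum(sub$sle) / sum(sub$label == "repeat"),
      p_ie = sum(sub$ie) / sum(sub$is_inference))
    if (is.nan(v)) NA_real_ else v
  }
  .with_seed(seed, {
    vals <- vapply(seq_len(n_mc), function(i) {
      cohort <- generate_cohort(population, task)
      # same single-pass validity screen the analysis pipeline applies
      cohort <- .analysable_cohort(cohort, filter, screen = TRUE)$cohort
      fl <- trial_flags(cohort, filter)
      by_p <- split(fl, factor(fl$participant_id,
                               levels = unique(fl$participant_id)))
      ab <- vapply(by_p, function(d) {
        n <- nrow(d)
        size_a <- n %/% 2L + if (n %% 2L == 1L) rbinom(1L, 1L, 0.5) else 0L
        sel <- logical(n)
        sel[sample.int(n, size_a)] <- TRUE
        c(half_value(d, sel), half_value(d, !sel))
      }, numeric(2L))
      ok <- is.finite(ab[1L, ]) & is.finite(ab[2L, ])
      if (sum(ok) < 3L) return(NA_real_)
      a <- ab[1L, ok]; b <- ab[2L, ok]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      r <- cor(a, b)
      2 * r / (1 + r)
    }, numeric(1))
    ok <- is.finite(vals)
    structure(list(mean = mean(vals[ok]), sd = sd(vals[ok]),
                   se = sd(vals[ok]) / sqrt(sum(ok)), values = vals,
                   n_mc = n_mc, n_undefined = sum(!ok), measure = measure),
              class = "wcst_oracle")
  })
}

#' @export
print.wcst_oracle <- function(x, ...) {
  cat(sprintf("Monte-Carlo oracle reliability for '%s': mean r_sb = %.4f (sd %.4f, se %.4f, %d cohorts",
              x$measure, x$mean, x$sd, x$se, x$n_mc))
  if (x$n_undefined > 0) cat(sprintf(", %d undefined", x$n_undefined))
  cat(")\n")
  invisible(x)
}
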