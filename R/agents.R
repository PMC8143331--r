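#' A generative cWCST agent
#'
#' A simple memoryless behavioral policy that reproduces the error taxonomy
#' of the cWCST. On a switch trial the agent repeats the previously applied
#' category with probability `p_persev` (a perseveration error); on a repeat
#' trial it abandons the prevailing category with probability `p_setloss` (a
#' set-loss error); on an inference trial (both alternatives to the
#' prevailing category already disconfirmed) it fails to infer the
#' prevailing category with probability `p_inferr` given that it did not
#' perseverate. When committing an erroneous switch the agent presses the
#' no-match key with probability `p_other` instead of sorting by a category.
#' On a switch trial that permits no inference the agent guesses uniformly
#' between the two categories it did not just apply.
#'
#' Response times are drawn from a lognormal distribution per trial type
#' with log-scale location `rt_location` and scale `rt_scale`; the trial
#' type of the session's first trial uses the repeat parameters. `drift_rt`
#' adds a linear per-trial change to the lognormal location (multiplicative
#' drift in RT) and `drift_logodds` a linear per-trial change to the
#' log-odds of each error probability, both indexed by the session-wide
#' trial number.
#'
#' @param p_persev,p_setloss,p_inferr,p_other Error probabilities in
#'   `[0, 1]`; see Details.
#' @param rt_location Named numeric (`switch`, `repeat`, `inference`):
#'   lognormal location, log-milliseconds.
#' @param rt_scale Named numeric, same names: lognormal scale (> 0).
#' @param drift_rt Per-trial change of the RT location (log-ms per trial).
#' @param drift_logodds Per-trial change of error log-odds.
#' @return A list of class `"wcst_agent"`.
#' @examples
#' wcst_agent(p_persev = 0.3)
#' @export
wcst_agent <- function(p_persev = 0, p_setloss = 0, p_inferr = 0,
                       p_other = 0,
                       rt_location = c(switch = log(1800), `repeat` = log(1200),
                                       inference = log(1700)),
                       rt_scale = c(switch = 0.4, `repeat` = 0.4,
                                    inference = 0.4),
                       drift_rt = 0, drift_logodds = 0) {
  probs <- c(p_persev = p_persev, p_setloss = p_setloss,
             p_inferr = p_inferr, p_other = p_other)
  if (any(probs < 0 | probs > 1)) stop("error probabilities must be in [0, 1]")
  rt_location <- rt_location[c("switch", "repeat", "inference")]
  rt_scale <- rt_scale[c("switch", "repeat", "inference")]
  if (anyNA(rt_location) || anyNA(rt_scale))
    stop("'rt_location' and 'rt_scale' need entries switch, repeat, inference")
  if (any(rt_scale <= 0)) stop("'rt_scale' must be positive")
  structure(list(p_persev = p_persev, p_setloss = p_setloss,
                 p_inferr = p_inferr, p_other = p_other,
                 rt_location = rt_location, rt_scale = rt_scale,
                 drift_rt = drift_rt, drift_logodds = drift_logodds),
            class = "wcst_agent")
}

#' @export
print.wcst_agent <- function(x, ...) {
  cat("cWCST agent\n")
  cat(sprintf("  p_persev = %.3f, p_setloss = %.3f, p_inferr = %.3f, p_other = %.3f\n",
              x$p_persev, x$p_setloss, x$p_inferr, x$p_other))
  cat(sprintf("  RT location (log-ms): switch %.2f, repeat %.2f, inference %.2f\n",
              x$rt_location[["switch"]], x$rt_location[["repeat"]],
              x$rt_location[["inference"]]))
  if (x$drift_rt != 0 || x$drift_logodds != 0)
    cat(sprintf("  drift: RT %.4g log-ms/trial, error log-odds %.4g /trial\n",
                x$drift_rt, x$drift_logodds))
  invisible(x)
}

.agent_param_matrix <- function(agents) {
  cols <- c("p_persev", "p_setloss", "p_inferr", "p_other",
            "loc_switch", "loc_repeat", "loc_inference",
            "scale_switch", "scale_repeat", "scale_inference",
            "drift_rt", "drift_logodds")
  if (inherits(agents, "wcst_agent")) agents <- list(agents)
  if (is.data.frame(agents)) {
    m <- as.matrix(agents[, cols])
  } else {
    m <- t(vapply(agents, function(a) {
      c(a$p_persev, a$p_setloss, a$p_inferr, a$p_other,
        a$rt_location, a$rt_scale, a$drift_rt, a$drift_logodds)
    }, numeric(12L)))
    colnames(m) <- cols
  }
  storage.mode(m) <- "double"
  m
}

#' Single behavioral step of the agent policy
#'
#' Draws one card sort and response time for a given trial context. This is
#' the per-trial policy realized by [run_session()]; it is exposed for
#' inspection and property testing at the level of a single decision. Uses
#' the current R random number stream.
#'
#' @param agent A [wcst_agent()].
#' @param state List describing the trial context: `context` (one of
#'   `"start"`, `"repeat"`, `"switch"`, `"inference"`), `prevailing`
#'   category, `previous_applied` and `prev2_applied` categories (or `NA`),
#'   `stimulus` (a `"wcst_stimulus"`), and `trial_number` (session-wide,
#'   1-based; drives drift).
#' @return List with `category` applied (`"color"`, `"shape"`, `"number"`,
#'   `"other"`), the pressed `response` key, and `rt_ms`.
#' @export
agent_response <- function(agent, state) {
  stopifnot(inherits(agent, "wcst_agent"))
  ctx <- match.arg(state$context, c("start", "repeat", "switch", "inference"))
  t <- if (is.null(state$trial_number)) 1L else state$trial_number
  shift <- function(p) {
    if (agent$drift_logodds == 0 || p <= 0 || p >= 1) p
    else plogis(qlogis(p) + agent$drift_logodds * (t - 1))
  }
  prev <- state$previous_applied
  guess2 <- function(excl) {
    pool <- setdiff(.categories, excl)
    pool[sample.int(length(pool), 1L)]
  }
  category <- switch(ctx,
    start = .categories[sample.int(3L, 1L)],
    `repeat` = {
      if (runif(1) < shift(agent$p_setloss)) {
        if (runif(1) < agent$p_other) "other" else guess2(prev)
      } else prev
    },
    switch = {
      if (!is.na(prev) && prev != "other" && runif(1) < shift(agent$p_persev)) {
        prev
      } else if (runif(1) < agent$p_other) {
        "other"
      } else if (!is.na(prev) && prev != "other") {
        guess2(prev)
      } else .categories[sample.int(3L, 1L)]
    },
    inference = {
      if (runif(1) < shift(agent$p_persev)) prev
      else if (runif(1) < shift(agent$p_inferr)) {
        if (runif(1) < agent$p_other) "other" else state$prev2_applied
      } else state$prevailing
    })
  rt_type <- switch(ctx, start = "repeat", `repeat` = "repeat",
                    switch = "switch", inference = "inference")
  rt <- exp(rnorm(1, agent$rt_location[[rt_type]] + agent$drift_rt * (t - 1),
                  agent$rt_scale[[rt_type]]))
  response <- if (category == "other") {
    setdiff(1:4, match_positions(state$stimulus))
  } else {
    match_positions(state$stimulus)[[category]]
  }
  list(category = category, response = as.integer(response), rt_ms = rt)
}
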