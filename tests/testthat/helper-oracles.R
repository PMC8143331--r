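# Shared fixtures and independent brute-force oracles. Everything here is
# written directly from the trial-type and error definitions, with explicit
# loops, and deliberately shares no code with the package internals it checks.

# Build a trial log from an explicit sequence of applied categories and
# prevailing categories. Stimuli are chosen from the valid deck so that the
# requested category maps to a concrete key press; feedback follows from
# applied vs prevailing.
make_log <- function(applied, prevailing, rt_ms = NULL, id = "T1",
                     block = "experimental") {
  n <- length(applied)
  stopifnot(length(prevailing) == n)
  if (is.null(rt_ms)) rt_ms <- rep(1000, n)
  deck <- stimulus_deck()
  rows <- vector("list", n)
  prev_idx <- 0L
  for (t in seq_len(n)) {
    idx <- if (prev_idx == nrow(deck)) 1L else prev_idx + 1L
    st <- stimulus_card(deck$number[idx], deck$color[idx], deck$shape[idx])
    pos <- match_positions(st)
    response <- if (applied[t] == "other") setdiff(1:4, pos) else pos[[applied[t]]]
    ev <- evaluate_response(st, response, prevailing[t])
    stopifnot(ev$applied_category == applied[t])
    rows[[t]] <- data.frame(
      participant_id = id, block = block, trial_index = t,
      stim_number = st$number, stim_color = st$color, stim_shape = st$shape,
      prevailing_category = prevailing[t], response = as.integer(response),
      applied_category = ev$applied_category, feedback = ev$feedback,
      rt_ms = rt_ms[t], stringsAsFactors = FALSE
    )
    prev_idx <- idx
  }
  out <- do.call(rbind, rows)
  class(out) <- c("wcst_cohort", "data.frame")
  out
}

rbind_cohort <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("wcst_cohort", "data.frame")
  out
}

# Brute-force trial-type labels: loops, straight from the definitions.
oracle_labels <- function(ap, fb) {
  n <- length(ap)
  label <- character(n)
  is_inf <- logical(n)
  for (t in seq_len(n)) {
    if (t == 1L) {
      label[t] <- "unlabeled"
    } else if (fb[t - 1L] == "negative") {
      label[t] <- "switch"
    } else {
      label[t] <- "repeat"
    }
    if (t >= 3L &&
        fb[t - 2L] == "negative" && fb[t - 1L] == "negative" &&
        ap[t - 1L] != ap[t - 2L] &&
        ap[t - 1L] != "other" && ap[t - 2L] != "other") {
      is_inf[t] <- TRUE
    }
  }
  list(label = label, is_inference = is_inf)
}

# Brute-force error scores for one participant's experimental trials.
oracle_scores <- function(log1) {
  ex <- log1[log1$block == "experimental", , drop = FALSE]
  ap <- ex$applied_category
  fb <- ex$feedback
  pv <- ex$prevailing_category
  lb <- oracle_labels(ap, fb)
  pe <- sle <- ie <- 0L
  for (t in seq_along(ap)) {
    if (lb$label[t] == "switch" && ap[t] == ap[t - 1L] && ap[t] != "other")
      pe <- pe + 1L
    if (lb$label[t] == "repeat" && ap[t] != ap[t - 1L])
      sle <- sle + 1L
    if (lb$is_inference[t] && ap[t] != pv[t])
      ie <- ie + 1L
  }
  list(n_trials = length(ap),
       n_switch = sum(lb$label == "switch"),
       n_repeat = sum(lb$label == "repeat"),
       n_inference = sum(lb$is_inference),
       pe = pe, sle = sle, ie = ie)
}

# Brute-force per-type RT means under the exclusion rules, for one
# participant: floor, individual ceiling from all experimental trials, and
# no error trials.
oracle_rt_means <- function(log1, floor_ms = 100, k = 3) {
  ex <- log1[log1$block == "experimental", , drop = FALSE]
  lb <- oracle_labels(ex$applied_category, ex$feedback)
  cutoff <- mean(ex$rt_ms) + k * sd(ex$rt_ms)
  valid <- logical(nrow(ex))
  for (t in seq_len(nrow(ex))) {
    err <- (lb$label[t] == "switch" && ex$applied_category[t] != "other" &&
              ex$applied_category[t] == ex$applied_category[t - 1L]) ||
      (lb$label[t] == "repeat" &&
         ex$applied_category[t] != ex$applied_category[t - 1L]) ||
      (lb$is_inference[t] &&
         ex$applied_category[t] != ex$prevailing_category[t])
    valid[t] <- ex$rt_ms[t] >= floor_ms && ex$rt_ms[t] <= cutoff && !err
  }
  mean_of <- function(sel) {
    v <- ex$rt_ms[sel & valid]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  c(switch = mean_of(lb$label == "switch"),
    `repeat` = mean_of(lb$label == "repeat"),
    inference = mean_of(lb$is_inference))
}

# A random hand-rolled trial log (not produced by the session simulator):
# applied categories drawn with participant-specific biases, prevailing
# category following an arbitrary switch process, RTs with occasional
# extreme values.
random_log <- function(n = 120, id = "R1") {
  ap <- sample(c("color", "shape", "number", "other"), n, replace = TRUE,
               prob = c(0.35, 0.3, 0.25, 0.1))
  pv <- character(n)
  pv[1] <- sample(c("color", "shape", "number"), 1)
  for (t in 2:n) {
    pv[t] <- if (runif(1) < 0.15)
      sample(setdiff(c("color", "shape", "number"), pv[t - 1]), 1)
    else pv[t - 1]
  }
  rt <- exp(rnorm(n, log(1200), 0.5))
  fast <- runif(n) < 0.02
  rt[fast] <- runif(sum(fast), 10, 99)
  make_log(ap, pv, rt_ms = rt, id = id)
}

# Fig-style mini-sequences used by scoring tests: a trial applying `shape`
# under a given prevailing category, plus continuations.
fig_switch_pe <- function() {
  # shape applied, negative feedback -> next trial is a switch trial;
  # repeating shape there is a perseveration error
  make_log(applied = c("shape", "shape"), prevailing = c("color", "color"))
}
fig_repeat_sle <- function() {
  # shape applied, positive feedback -> next trial is a repeat trial;
  # switching to color there is a set-loss error
  make_log(applied = c("shape", "color"), prevailing = c("shape", "shape"))
}
fig_inference <- function(third = "shape") {
  # shape then number applied, both negative -> the third trial is an
  # inference trial with color prevailing
  make_log(applied = c("shape", "number", third),
           prevailing = c("color", "color", "color"))
}
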