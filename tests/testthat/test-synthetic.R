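test_that("zero-variance hyperparameters produce identical agents", {
  pop <- wcst_population(
    n_participants = 8,
    persev = c(mean = 0.3, concentration = Inf),
    setloss = c(mean = 0.1, concentration = Inf),
    inferr = c(mean = 0.2, concentration = Inf),
    rt_sd_ms = c(switch = 1e-9, `repeat` = 1e-9, inference = 1e-9),
    rt_sdlog = c(mean = 0.4, sd = 0))
  ag <- sample_population(pop, seed = 1)
  for (v in c("p_persev", "p_setloss", "p_inferr", "loc_switch",
              "scale_switch"))
    expect_equal(length(unique(round(ag[[v]], 9))), 1L, info = v)
})

test_that("population sampling and cohort generation are seed-reproducible", {
  pop <- wcst_population(n_participants = 6)
  expect_identical(sample_population(pop, seed = 3),
                   sample_population(pop, seed = 3))
  expect_identical(generate_cohort(pop, seed = 4), generate_cohort(pop, seed = 4))
  expect_false(identical(generate_cohort(pop, seed = 4),
                         generate_cohort(pop, seed = 5)))
})

test_that("the single-step policy commits perseveration errors at the configured rate", {
  set.seed(50)
  ag <- wcst_agent(p_persev = 0.3)
  st <- stimulus_card(1, "green", "cross")
  state <- list(context = "switch", prevailing = "color",
                previous_applied = "shape", prev2_applied = NA,
                stimulus = st, trial_number = 10)
  draws <- replicate(4000, agent_response(ag, state)$category)
  frac <- mean(draws == "shape")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("simulated sessions commit PE on switch trials at the configured rate", {
  pop <- wcst_population(n_participants = 60,
                         persev = c(mean = 0.3, concentration = Inf),
                         setloss = c(mean = 0.05, concentration = Inf),
                         inferr = c(mean = 0.2, concentration = Inf))
  co <- simulate(pop, seed = 51)
  sc <- score_errors(co)
  # PE happen with probability 0.3 on every switch trial (inference included)
  frac <- sum(sc$pe) / sum(sc$n_switch)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / sum(sc$n_switch)))
})

test_that("agents with zero error probabilities never commit scored errors", {
  pop <- wcst_population(n_participants = 10,
                         persev = c(mean = 0, concentration = Inf),
                         setloss = c(mean = 0, concentration = Inf),
                         inferr = c(mean = 0, concentration = Inf),
                         p_other = 0)
  co <- simulate(pop, seed = 52)
  sc <- score_errors(co)
  expect_true(all(sc$pe == 0) && all(sc$sle == 0) && all(sc$ie == 0))
})

test_that("default cohorts reproduce the configured error rates and RT moments", {
  pop <- wcst_population() # 375 participants
  co <- simulate(pop, seed = 53)
  sc <- score_errors(co)
  n <- nrow(sc)

  # per-participant conditional error rates are unbiased for the beta means
  p_pe <- sc$pe / sc$n_switch
  expect_lt(abs(mean(p_pe) - 0.165), 3 * sd(p_pe) / sqrt(n))
  p_sle <- sc$sle / sc$n_repeat
  expect_lt(abs(mean(p_sle) - 0.045), 3 * sd(p_sle) / sqrt(n))

  # cohort error-count means approach the configured descriptive targets
  # (bands are target +/- ~4 standard errors of these heavy-tailed counts)
  expect_gt(mean(sc$pe), 8)
  expect_lt(mean(sc$pe), 17)
  expect_gt(mean(sc$sle), 3.5)
  expect_lt(mean(sc$sle), 7)
  expect_gt(mean(sc$ie), 6)
  expect_lt(mean(sc$ie), 11.5)

  # session length: 40 switches with runs of 2-6 correct sorts plus search
  expect_gt(mean(sc$n_trials), 185)
  expect_lte(mean(sc$n_trials), 244)

  # raw per-type mean RTs against configured targets; the switch measure
  # mixes in inference trials (a sub-type) whose target mean is lower, so a
  # 60 ms systematic allowance accompanies the 3-SE sampling band
  ex <- experimental_trials(co)
  lab <- classify_trials(co)
  f <- factor(ex$participant_id, levels = unique(ex$participant_id))
  for (chk in list(list(sel = lab$label == "switch", target = 1835, sd = 694),
                   list(sel = lab$label == "repeat", target = 1241, sd = 441),
                   list(sel = lab$is_inference, target = 1700, sd = 636))) {
    mrt <- tapply(ifelse(chk$sel, ex$rt_ms, NA), f, mean, na.rm = TRUE)
    mrt <- mrt[is.finite(mrt)]
    expect_lt(abs(mean(mrt) - chk$target), 3 * chk$sd / sqrt(length(mrt)) + 60)
  }
})

test_that("heterogeneous RT drift shows up as variance in fitted per-participant slopes", {
  slopes <- function(drift_sd, seed) {
    pop <- wcst_population(n_participants = 25, drift_rt_sd = drift_sd)
    co <- simulate(pop, seed = seed)
    ex <- experimental_trials(co)
    vapply(split(ex, ex$participant_id), function(d)
      unname(coef(lm(log(d$rt_ms) ~ d$trial_index))[2]), numeric(1))
  }
  s0 <- slopes(0, 60)
  s1 <- slopes(0.002, 61)
  expect_gt(sd(s1), 2 * sd(s0))
})

test_that("the Monte-Carlo oracle returns a coherent summary", {
  pop <- wcst_population(n_participants = 40)
  or <- oracle_reliability(pop, measure = "pe", n_mc = 100, seed = 70)
  expect_s3_class(or, "wcst_oracle")
  expect_length(or$values, 100L)
  ok <- is.finite(or$values)
  expect_equal(or$mean, mean(or$values[ok]))
  expect_equal(or$se, or$sd / sqrt(sum(ok)))
  expect_true(or$mean > 0 && or$mean <= 1)
  expect_error(oracle_reliability(pop, n_mc = 50), "at least 100")
})
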