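test_that("a trial after negative feedback is a switch trial; repeating the set there is a PE", {
  log <- fig_switch_pe()
  lab <- classify_trials(log)
  expect_equal(lab$label, c("unlabeled", "switch"))
  expect_false(any(lab$is_inference))
  sc <- score_errors(log)
  expect_equal(sc$pe, 1L)
  expect_equal(sc$sle, 0L)
  expect_equal(sc$ie, 0L)
})

test_that("a trial after positive feedback is a repeat trial; switching there is an SLE", {
  log <- fig_repeat_sle()
  lab <- classify_trials(log)
  expect_equal(lab$label, c("unlabeled", "repeat"))
  sc <- score_errors(log)
  expect_equal(sc$sle, 1L)
  expect_equal(sc$pe, 0L)
})

test_that("two disconfirmed categories make the next trial an inference trial", {
  # applying the remaining (prevailing) category: no error
  ok <- fig_inference(third = "color")
  lab <- classify_trials(ok)
  expect_equal(lab$label, c("unlabeled", "switch", "switch"))
  expect_equal(lab$is_inference, c(FALSE, FALSE, TRUE))
  expect_equal(score_errors(ok)$ie, 0L)
  # applying any other category is an inference error
  bad <- fig_inference(third = "shape")
  expect_equal(score_errors(bad)$ie, 1L)
  # a perseverative response on an inference trial is both PE and IE
  pers <- fig_inference(third = "number")
  sc <- score_errors(pers)
  expect_equal(sc$pe, 1L)
  expect_equal(sc$ie, 1L)
  # the no-match key on an inference trial is an IE but never a PE
  oth <- fig_inference(third = "other")
  sc2 <- score_errors(oth)
  expect_equal(sc2$ie, 1L)
  expect_equal(sc2$pe, 0L)
})

test_that("a single-trial log is unlabeled and error-free", {
  log <- make_log("color", "color")
  lab <- classify_trials(log)
  expect_equal(lab$label, "unlabeled")
  sc <- score_errors(log)
  expect_equal(sc$n_trials, 1L)
  expect_equal(sc$n_switch + sc$n_repeat, 0L)
  expect_equal(sc$pe + sc$sle + sc$ie, 0L)
})

test_that("scores equal an independent brute-force re-scorer on random logs", {
  set.seed(99)
  for (i in 1:40) {
    log <- random_log(n = sample(30:150, 1), id = sprintf("R%02d", i))
    sc <- score_errors(log)
    or <- oracle_scores(log)
    for (f in names(or)) expect_equal(sc[[f]], or[[f]], info = f)
    # structural invariants
    expect_equal(sc$n_switch + sc$n_repeat, sc$n_trials - 1L)
    expect_lte(sc$n_inference, sc$n_switch)
    expect_lte(sc$pe, sc$n_switch)
    expect_lte(sc$sle, sc$n_repeat)
    expect_lte(sc$ie, sc$n_inference)
  }
})

test_that("scoring ignores response times and practice trials", {
  set.seed(5)
  log <- random_log(80)
  log2 <- log
  log2$rt_ms <- log$rt_ms * 10 + 3
  expect_equal(score_errors(log), score_errors(log2))
  # prepend practice trials: scores unchanged
  pr <- make_log(c("color", "color"), c("color", "color"), block = "practice",
                 id = "R1")
  expect_equal(score_errors(rbind_cohort(pr, log))[-1],
               score_errors(log)[-1])
})

test_that("category application counts partition the experimental trials", {
  log <- fig_inference("color")
  cc <- category_counts(log)
  expect_equal(cc$shape, 1L)
  expect_equal(cc$number, 1L)
  expect_equal(cc$color, 1L)
  expect_equal(cc$other, 0L)
  set.seed(17)
  for (i in 1:20) {
    log <- random_log(60, id = "P")
    cc <- category_counts(log)
    expect_equal(cc$color + cc$shape + cc$number + cc$other, 60L)
  }
})

test_that("no trial is scored as both PE and SLE", {
  set.seed(23)
  co <- simulate(wcst_population(n_participants = 10), seed = 23)
  fl <- trial_flags(co)
  expect_false(any(fl$pe & fl$sle))
})

test_that("every scored inference trial has the required two-trial history", {
  co <- simulate(wcst_population(n_participants = 15), seed = 31)
  ex <- experimental_trials(co)
  lab <- classify_trials(co)
  idx <- which(lab$is_inference)
  for (t in idx) {
    expect_gte(ex$trial_index[t], 3L)
    expect_equal(ex$participant_id[t], ex$participant_id[t - 2L])
    expect_equal(ex$feedback[t - 1L], "negative")
    expect_equal(ex$feedback[t - 2L], "negative")
    expect_false(ex$applied_category[t - 1L] == ex$applied_category[t - 2L])
  }
})
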