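test_that("the 100 ms RT floor is strict: 99 ms out, 100 ms in", {
  n <- 20
  rt <- rep(1000, n)
  rt[5] <- 99
  rt[6] <- 100
  log <- make_log(rep("color", n), rep("color", n), rt_ms = rt)
  mask <- valid_rt_mask(log)
  expect_false(mask[5])
  expect_true(mask[6])
})

test_that("the individual ceiling is mean + 3 SD over all experimental trials", {
  rt <- c(rep(1000, 19), 5000)
  log <- make_log(rep("color", 20), rep("color", 20), rt_ms = rt)
  cut <- rt_cutoffs(log)
  expect_equal(cut$cutoff_ms, mean(rt) + 3 * sd(rt))
  mask <- valid_rt_mask(log)
  expect_false(mask[20]) # 5000 > 1200 + 3*894
  expect_true(all(mask[1:19]))
})

test_that("identical RTs give a zero-width ceiling that excludes nothing", {
  log <- make_log(rep("color", 10), rep("color", 10), rt_ms = rep(800, 10))
  expect_true(all(valid_rt_mask(log)))
})

test_that("error trials are excluded from RT analysis", {
  log <- fig_switch_pe() # second trial is a PE
  log$rt_ms <- c(1000, 1000)
  mask <- valid_rt_mask(log)
  expect_true(mask[1])
  expect_false(mask[2])
})

test_that("RT means per type use valid trials only, inference feeding both switch and inference", {
  # 5 trials: unlabeled, switch, switch(inference), repeat, repeat
  log <- make_log(applied = c("shape", "number", "color", "color", "color"),
                  prevailing = rep("color", 5),
                  rt_ms = c(500, 700, 900, 1100, 1300))
  lab <- classify_trials(log)
  expect_equal(lab$label, c("unlabeled", "switch", "switch", "repeat", "repeat"))
  expect_true(lab$is_inference[3])
  rs <- rt_summary(log)
  expect_equal(rs$rt_switch, mean(c(700, 900)))
  expect_equal(rs$rt_inference, 900)
  expect_equal(rs$rt_repeat, mean(c(1100, 1300)))
  expect_equal(rs$n_switch, 2L)
  expect_equal(rs$n_inference, 1L)
})

test_that("a type with no valid trials yields an undefined (NA) mean", {
  log <- make_log(rep("color", 6), rep("color", 6)) # no inference trials
  rs <- rt_summary(log)
  expect_true(is.na(rs$rt_inference))
  expect_equal(rs$n_inference, 0L)
  expect_false(is.na(rs$rt_repeat))
})

test_that("RT means match a brute-force recomputation on random logs", {
  set.seed(77)
  for (i in 1:25) {
    log <- random_log(n = sample(40:120, 1))
    rs <- rt_summary(log)
    or <- oracle_rt_means(log)
    expect_equal(rs$rt_switch, unname(or["switch"]))
    expect_equal(rs$rt_repeat, unname(or["repeat"]))
    expect_equal(rs$rt_inference, unname(or["inference"]))
  }
})

test_that("the cohort validity screen excludes only deviant category users", {
  set.seed(8)
  co <- simulate(wcst_population(n_participants = 30), seed = 8)
  scr <- screen_participants(co)
  m <- attr(scr, "cohort_mean")
  s <- attr(scr, "cohort_sd")
  # recompute the rule by hand
  for (i in seq_len(nrow(scr))) {
    dev <- abs(c(scr$color[i], scr$shape[i], scr$number[i], scr$other[i]) - m)
    expect_equal(scr$excluded[i], any(dev > 3 * s))
  }
})

test_that("a participant 4 SD out on one category is excluded, identical cohorts keep everyone", {
  # 12 participants applying mostly balanced categories, one applying color
  # far more often than the cohort mean
  base <- rep(c("color", "shape", "number"), each = 10)
  logs <- lapply(1:11, function(i)
    make_log(sample(base), rep("color", 30), id = sprintf("P%02d", i)))
  dev <- make_log(rep("color", 30), rep("color", 30), id = "P12")
  co <- do.call(rbind_cohort, c(logs, list(dev)))
  scr <- screen_participants(co)
  m <- attr(scr, "cohort_mean")[["color"]]
  s <- attr(scr, "cohort_sd")[["color"]]
  expect_gt((30 - m) / s, 3) # the deviant really is beyond 3 SD
  expect_true(scr$excluded[scr$participant_id == "P12"])
  expect_false(any(scr$excluded[scr$participant_id != "P12"]))

  # all-identical cohort: zero SDs, zero deviations, nobody excluded
  same <- do.call(rbind_cohort, lapply(1:5, function(i)
    make_log(base, rep("color", 30), id = sprintf("S%d", i))))
  expect_false(any(screen_participants(same)$excluded))
})

test_that("screening is single-pass and idempotent under the original statistics", {
  set.seed(13)
  co <- simulate(wcst_population(n_participants = 40), seed = 13)
  scr <- screen_participants(co)
  keep <- scr$participant_id[!scr$excluded]
  sub <- co[co$participant_id %in% keep, ]
  m <- attr(scr, "cohort_mean")
  s <- attr(scr, "cohort_sd")
  cc <- category_counts(sub)
  dev <- abs(sweep(as.matrix(cc[c("color", "shape", "number", "other")]), 2, m))
  expect_false(any(sweep(dev, 2, 3 * s) > 0))
})

test_that("degenerate inputs are rejected", {
  one <- make_log(rep("color", 5), rep("color", 5))
  expect_error(screen_participants(one), "at least 2")
  tiny <- make_log("color", "color")
  expect_error(rt_cutoffs(tiny), "fewer than 2")
  expect_error(wcst_filter(rt_floor_ms = 0), "positive")
})
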