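# construct a participant whose PE count is exactly k in each half of a
# 2m-trial sequence of all-switch trials (prevailing never matches applied)
pe_participant <- function(k, m = 10, id = "P") {
  seq_half <- function(k) {
    # applied alternates color/number; a repetition of the predecessor is a PE
    ap <- character(m)
    ap[1] <- "color"
    for (t in 2:m) ap[t] <- if (t <= k + 1) ap[t - 1] else
      setdiff(c("color", "number"), ap[t - 1])
    ap
  }
  first <- seq_half(k)
  second <- seq_half(k)
  # keep the boundary from creating an extra PE
  if (second[1] == first[m]) second <- ifelse(second == "color", "number", "color")
  make_log(c(first, second), rep("shape", 2 * m), id = id)
}

test_that("constructed PE placements give identical half scores and r_sb = 1", {
  co <- do.call(rbind_cohort,
                lapply(0:5, function(k) pe_participant(k, id = paste0("P", k))))
  fl <- trial_flags(co)
  hs <- half_scores(fl, cohort_split(fl, "first_second"), "pe")
  expect_equal(hs$a[, "pe"], hs$b[, "pe"], ignore_attr = TRUE)
  est <- reliability_estimate(co, "first_second", "pe")
  expect_equal(est$r, 1)
  expect_equal(est$r_sb, 1)
  expect_equal(est$n_pairs, 6L)
})

test_that("half scores match a brute-force evaluator on random cohorts and splits", {
  set.seed(41)
  for (rep in 1:15) {
    co <- do.call(rbind_cohort, lapply(1:4, function(i)
      random_log(sample(40:90, 1), id = sprintf("Q%d", i))))
    fl <- trial_flags(co)
    assign <- as.logical(unlist(lapply(
      split(seq_len(nrow(fl)), factor(fl$participant_id,
                                      levels = unique(fl$participant_id))),
      function(i) split_half(length(i), "random"))))
    hs <- half_scores(fl, assign, wcst_measures())
    # oracle: per participant, filter rows and recompute from raw flags
    for (id in unique(fl$participant_id)) {
      sel <- fl$participant_id == id
      for (half in c(TRUE, FALSE)) {
        d <- fl[sel & (assign == half), ]
        got <- if (half) hs$a[id, ] else hs$b[id, ]
        expect_equal(unname(got["pe"]), sum(d$pe))
        expect_equal(unname(got["sle"]), sum(d$sle))
        expect_equal(unname(got["ie"]), sum(d$ie))
        rts <- d$rt_ms[d$rt_valid & d$label == "switch"]
        expect_equal(unname(got["rt_switch"]),
                     if (length(rts)) mean(rts) else NA_real_)
        rti <- d$rt_ms[d$rt_valid & d$is_inference]
        expect_equal(unname(got["rt_inference"]),
                     if (length(rti)) mean(rti) else NA_real_)
      }
    }
  }
})

test_that("a zero-error cohort leaves count reliabilities undefined, not zero", {
  co <- simulate(wcst_population(
    n_participants = 12,
    persev = c(mean = 0, concentration = Inf),
    setloss = c(mean = 0, concentration = Inf),
    inferr = c(mean = 0, concentration = Inf), p_other = 0), seed = 2)
  fl <- trial_flags(co)
  hs <- half_scores(fl, cohort_split(fl, "first_second"), "pe")
  expect_true(all(hs$a == 0) && all(hs$b == 0))
  est <- reliability_estimate(co, "first_second", "pe")
  expect_true(is.na(est$r))
  expect_true(is.na(est$r_sb))
  expect_equal(est$n_pairs, 12L)
})

test_that("identical agents carry no true signal: sampled median r_sb near zero", {
  pop <- wcst_population(
    n_participants = 250,
    persev = c(mean = 0.2, concentration = Inf),
    setloss = c(mean = 0.05, concentration = Inf),
    inferr = c(mean = 0.2, concentration = Inf),
    rt_sd_ms = c(switch = 1e-6, `repeat` = 1e-6, inference = 1e-6),
    rt_sdlog = c(mean = 0.4, sd = 0))
  co <- simulate(pop, seed = 4)
  sr <- sample_reliability(co, measures = c("pe", "rt_repeat"),
                           n_samples = 300, seed = 5)
  expect_lt(abs(sr$summary$median[1]), 0.25)
  expect_lt(abs(sr$summary$median[2]), 0.25)
})

test_that("sampled reliability is reproducible and summarized consistently", {
  co <- simulate(wcst_population(n_participants = 30), seed = 6)
  s1 <- sample_reliability(co, n_samples = 120, seed = 7)
  s2 <- sample_reliability(co, n_samples = 120, seed = 7)
  expect_identical(s1$samples, s2$samples)
  ok <- is.finite(s1$samples[, "pe"])
  expect_equal(s1$summary$median[1], median(s1$samples[ok, "pe"]))
  expect_true(all(s1$summary$hdi_lower <= s1$summary$median, na.rm = TRUE))
  expect_true(all(s1$summary$median <= s1$summary$hdi_upper, na.rm = TRUE))
})

test_that("systematic split estimates lie inside the sampled min-max range", {
  co <- simulate(wcst_population(n_participants = 60), seed = 14)
  fl <- trial_flags(co)
  sr <- sample_reliability(co, measures = "pe", n_samples = 800, flags = fl,
                           seed = 15)
  fs <- reliability_estimate(co, "first_second", "pe", flags = fl)$r_sb
  oe <- reliability_estimate(co, "odd_even", "pe", flags = fl)$r_sb
  rng <- range(sr$samples[is.finite(sr$samples[, "pe"]), "pe"])
  expect_gte(fs, rng[1] - 0.05)
  expect_lte(fs, rng[2] + 0.05)
  expect_gte(oe, rng[1] - 0.05)
  expect_lte(oe, rng[2] + 0.05)
})

test_that("the full fit returns a complete reliability table and methods work", {
  co <- simulate(wcst_population(n_participants = 40), seed = 20)
  fit <- wcst_reliability(co, n_samples = 150, seed = 21)
  expect_s3_class(fit, "wcst_reliability")
  expect_equal(nrow(fit$table), 6L)
  expect_false(any(is.na(fit$table$r_sb_random_median)))
  cf <- coef(fit)
  expect_equal(dim(cf), c(6L, 3L))
  expect_output(print(fit), "random splits")
  expect_output(print(summary(fit)), "Error scores")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("conditional error probabilities are available as extra measures", {
  co <- simulate(wcst_population(n_participants = 40), seed = 25)
  fl <- trial_flags(co)
  ms <- measure_scores(fl, wcst_measures(include_probs = TRUE))
  sc <- score_errors(co)
  expect_equal(unname(ms[, "p_pe"]), sc$pe / sc$n_switch)
  expect_equal(unname(ms[, "p_sle"]), sc$sle / sc$n_repeat)
})

test_that("fewer than three participants is an error", {
  co <- rbind_cohort(random_log(40, "A"), random_log(40, "B"))
  expect_error(reliability_estimate(co, "first_second", "pe"), "3 participants")
  expect_error(sample_reliability(co, "pe", 50), "3 participants")
})
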