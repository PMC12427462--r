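# The printed two-bowl worked examples: totals, percents, ratios and
# first-choice counts for the three diet pairings.
pair_record <- function(diet_a, grams_a, diet_b, grams_b) {
  data.frame(cat_id = "agg", day = 1, diet_a = diet_a, diet_b = diet_b,
             grams_a = grams_a, grams_b = grams_b, first_choice = "none",
             stringsAsFactors = FALSE)
}

test_that("consumption summaries reproduce the trial's printed ratios", {
  s1 <- consumption_summary(pair_record("CD", 988, "T150", 1699))
  expect_equal(s1$diets, c("T150", "CD"))
  expect_equal(unname(s1$percents), c(63.2, 36.8), tolerance = 1e-3)
  expect_equal(s1$ratio, 1.72, tolerance = 5e-3)
  expect_false(s1$clear_preference)

  s2 <- consumption_summary(pair_record("CD", 759, "T300", 1783))
  expect_equal(unname(s2$percents["T300"]), 70.1, tolerance = 1e-3)
  expect_equal(s2$ratio, 2.35, tolerance = 5e-3)
  expect_true(s2$clear_preference)

  s3 <- consumption_summary(pair_record("T150", 1484, "T300", 1047))
  expect_equal(s3$ratio, 1.42, tolerance = 5e-3)

  seq_ <- consumption_summary(pair_record("A", 50, "B", 50))
  expect_equal(seq_$ratio, 1)
  expect_error(consumption_summary(pair_record("A", 0, "B", 0)),
               "no consumption")
})

test_that("consumption summary is scale invariant and percents close", {
  set.seed(71)
  rec <- data.frame(cat_id = rep(sprintf("c%d", 1:5), 2),
                    day = rep(1:2, each = 5), diet_a = "CD", diet_b = "T150",
                    grams_a = runif(10, 0, 90), grams_b = runif(10, 0, 90),
                    first_choice = "none", stringsAsFactors = FALSE)
  s <- consumption_summary(rec)
  expect_equal(sum(s$percents), 100, tolerance = 0.1)
  rec2 <- rec
  rec2$grams_a <- 3 * rec$grams_a
  rec2$grams_b <- 3 * rec$grams_b
  s2 <- consumption_summary(rec2)
  expect_equal(s2$ratio, s$ratio)
  expect_equal(s2$percents, s$percents)
  expect_equal(intake_ratio_per_cat(rec2)$mean_ir,
               intake_ratio_per_cat(rec)$mean_ir)
})

test_that("per-cat intake ratios close to 1 and average correctly", {
  rec <- data.frame(cat_id = c("c1", "c2", "c3"), day = 1,
                    diet_a = "A", diet_b = "B",
                    grams_a = c(30, 10, 25), grams_b = c(10, 30, 75),
                    first_choice = "none", stringsAsFactors = FALSE)
  ir <- intake_ratio_per_cat(rec)
  expect_equal(ir$per_cat$ir_a, c(0.75, 0.25, 0.25))
  expect_equal(ir$per_cat$ir_a + ir$per_cat$ir_b, rep(1, 3))
  expect_equal(unname(ir$mean_ir), c(mean(c(0.75, 0.25, 0.25)),
                                     mean(c(0.25, 0.75, 0.75))))
  rec0 <- rbind(rec, data.frame(cat_id = "c4", day = 1, diet_a = "A",
                                diet_b = "B", grams_a = 0, grams_b = 0,
                                first_choice = "none"))
  expect_message(ir0 <- intake_ratio_per_cat(rec0), "zero total")
  expect_equal(nrow(ir0$per_cat), 3)
})

test_that("first-choice chi-square uses the half-of-cat-days expectation", {
  # printed daily counts: (14, 5) of 20 cats -> X2 = 4.1, p ~ 0.043
  fc <- first_choice_test(c(14, 5), n_cats = 20, n_days = 1)
  expect_equal(fc$statistic, 4.1, tolerance = 1e-9)
  expect_equal(fc$p_value, 0.043, tolerance = 5e-3)
  # abstentions do not shrink the expectation
  expect_equal(fc$expected, 10)
  # overall counts (21, 19) over 2 days -> X2 = 0.1, p ~ 0.752
  fc2 <- first_choice_test(c(21, 19), n_cats = 20, n_days = 2)
  expect_equal(fc2$statistic, 0.1, tolerance = 1e-9)
  expect_equal(fc2$p_value, 0.752, tolerance = 5e-3)
  expect_equal(first_choice_test(c(10, 10), 20, 1)$p_value, 1)
  # symmetric in the two diets
  expect_equal(first_choice_test(c(5, 14), 20, 1)$statistic, fc$statistic)
  expect_error(first_choice_test(c(15, 8), 20, 1), "exceed")
})

test_that("clear preference is the inclusive 2:1 criterion", {
  expect_true(clear_preference(2.35))
  expect_false(clear_preference(1.72))
  expect_true(clear_preference(2.0))
  expect_error(clear_preference(0.9), ">= 1")
})

test_that("daily paired t-test handles standard and degenerate input", {
  rec <- data.frame(cat_id = sprintf("c%d", 1:3), day = 1,
                    diet_a = "A", diet_b = "B",
                    grams_a = c(3, 4, 5), grams_b = c(1, 2, 3),
                    first_choice = "none", stringsAsFactors = FALSE)
  deg <- daily_consumption_test(rec, day = 1)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)  # constant nonzero difference

  rec$grams_b <- rec$grams_a
  same <- daily_consumption_test(rec, day = 1)
  expect_equal(same$p_value, 1)

  set.seed(73)
  rej <- replicate(400, {
    r <- data.frame(cat_id = sprintf("c%d", 1:20), day = 1,
                    diet_a = "A", diet_b = "B",
                    grams_a = rnorm(20, 40, 10), grams_b = rnorm(20, 40, 10),
                    first_choice = "none")
    daily_consumption_test(r, 1)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("acceptance model recovers a planted logit shift and is null
           under no effect", {
  set.seed(79)
  make_data <- function(shift) {
    n <- 40
    cats <- sprintf("c%02d", 1:n)
    trt <- rep(c("CD", "SCFP"), each = n / 2)
    cat_eff <- rnorm(n, 0, 0.3)
    do.call(rbind, lapply(1:2, function(period) {
      eta <- 0.5 + cat_eff + ifelse(trt == "SCFP", shift, 0) +
        rnorm(n, 0, 0.2)
      data.frame(cat_id = cats, treatment = trt, period = period,
                 intake_g = 100 * plogis(eta), offered_g = 100)
    }))
  }
  or_null <- replicate(20, {
    f <- acceptance_model(make_data(0))
    f$lower <= 1 & f$upper >= 1
  })
  expect_gte(mean(or_null), 0.9)
  or_eff <- replicate(20, acceptance_model(make_data(0.5))$odds_ratio)
  expect_equal(mean(or_eff), exp(0.5), tolerance = 0.2 * exp(0.5))
  bad <- make_data(0)
  bad$intake_g[1] <- 200
  expect_error(acceptance_model(bad), "exceeds offered")
})

test_that("ATTD follows the intake/output formula and flags negatives", {
  expect_equal(attd(intake = 10, output = 2)$digestibility_pct, 80)
  expect_equal(attd(intake = 10, output = 0)$digestibility_pct, 100)
  expect_equal(attd(intake = 16.55, output = 3.044)$digestibility_pct,
               81.61, tolerance = 0.01)
  expect_error(attd(intake = 0, output = 1), "positive")
  neg <- attd(intake = 5, output = 6)
  expect_true(neg$flagged)
  # monotone decreasing in output at fixed intake
  outs <- seq(0, 9, by = 1.5)
  vals <- attd(data.frame(cat_id = "c", nutrient = "dm",
                          intake_g_per_day = 10,
                          fecal_output_g_per_day = outs))$digestibility_pct
  expect_true(all(diff(vals) < 0))
})

test_that("the full palatability report hangs together on synthetic records", {
  b <- generate_trial(reduced_cohort_config(), seed = 5)
  rec <- b$palatability
  pair <- rec[rec$diet_a == "CD" & rec$diet_b == "T300", ]
  rep_ <- palatability_report(pair)
  expect_equal(sum(rep_$consumption$percents), 100)
  expect_gte(rep_$consumption$ratio, 1)
  counts <- rep_$first_choice$overall$counts
  expect_lte(sum(counts), 20 * 2)
  expect_length(rep_$daily_t, 2)
  expect_true(rep_$first_choice$overall$p_value >= 0 &&
                rep_$first_choice$overall$p_value <= 1)
})
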