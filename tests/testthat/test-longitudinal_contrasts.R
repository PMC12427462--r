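test_that("polynomial contrasts reproduce the classical 3-level coding and
           are affine invariant", {
  pc <- polynomial_contrasts(c(0, 150, 300))
  expect_equal(unname(pc[, "linear"]), c(-1, 0, 1) / sqrt(2))
  expect_equal(unname(pc[, "quadratic"]), c(1, -2, 1) / sqrt(6))
  expect_equal(sum(pc[, "linear"] * pc[, "quadratic"]), 0, tolerance = 1e-12)
  expect_equal(colSums(pc), c(linear = 0, quadratic = 0), tolerance = 1e-12)
  expect_equal(unname(colSums(pc^2)), c(1, 1))
  # days code identically to doses (affine invariance)
  expect_equal(unname(polynomial_contrasts(c(0, 21, 42))), unname(pc))
  # unequally spaced levels stay orthonormal
  pu <- polynomial_contrasts(c(0, 10, 40))
  expect_equal(unname(crossprod(cbind(1, pu))[2:3, 2:3]), diag(2),
               tolerance = 1e-12)
  expect_equal(ncol(polynomial_contrasts(c(0, 1))), 1L)
})

test_that("BH adjustment matches the hand example and the brute-force
           step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:20) {
    p <- round(runif(sample(1:10, 1)), 3)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # monotone: q ordering preserves p ordering
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("bias correction removes a planted compositional shift", {
  bc <- bias_correct(c(1, 1, 1, 1, 5))
  expect_equal(bc$offset, 1)
  expect_equal(bc$corrected, c(0, 0, 0, 0, 4))
  expect_equal(bias_correct(rep(2.5, 6))$corrected, rep(0, 6))
  expect_warning(out <- bias_correct(c(1, 2)), "fewer than 5")
  expect_equal(out$offset, 0)
  # 90% nulls contaminated by a constant +0.4 shift
  set.seed(47)
  reps <- replicate(50, {
    beta <- c(rnorm(90, 0, 0.05), rnorm(10, 1, 0.1)) + 0.4
    mean(bias_correct(beta)$corrected[1:90])
  })
  expect_lt(max(abs(reps)), 0.05)
  # mode-based correction agrees for a unimodal null
  set.seed(48)
  beta <- rnorm(200, 0.4, 0.05)
  expect_equal(bias_correct(beta, mode = "mode")$offset, 0.4,
               tolerance = 0.05)
})

test_that("per-feature mixed models recover planted time trends", {
  set.seed(53)
  design <- tiny_design(n_cats_per_arm = 7)
  n <- nrow(design)
  step <- design$timepoint_day / 21
  in_t300 <- design$diet == "T300"
  n_feat <- 12
  values <- sapply(seq_len(n_feat), function(j) {
    cat_eff <- rnorm(length(unique(design$cat_id)), 0, 0.4)
    y <- cat_eff[match(design$cat_id, unique(design$cat_id))] +
      rnorm(n, 0, 0.3)
    if (j <= 10) y <- y + 0.3 * step * in_t300
    y
  })
  dimnames(values) <- list(design$sample_id, sprintf("f%02d", 1:n_feat))
  fits <- fit_feature_models(values, design, df_method = "satterthwaite")
  tr <- fits[fits$term == "time_linear@T300" &
               fits$feature_id %in% sprintf("f%02d", 1:10), ]
  expect_gte(sum(tr$estimate > 0), 9)
  expect_equal(mean(tr$estimate), 0.3, tolerance = 0.1)
  # satterthwaite df are finite and positive
  expect_true(all(is.finite(tr$df) & tr$df > 0))
  # null features are not systematically trending
  null_tr <- fits[fits$term == "time_linear@T300" &
                    !fits$feature_id %in% sprintf("f%02d", 1:10), ]
  expect_lt(max(abs(null_tr$estimate)), 0.5)
})

test_that("constant features are skipped, not fatal, and rank deficiency
           is reported", {
  design <- tiny_design(3)
  values <- matrix(rnorm(nrow(design) * 2), nrow(design), 2,
                   dimnames = list(design$sample_id, c("ok", "flat")))
  values[, "flat"] <- 7
  fits <- fit_feature_models(values, design, df_method = "residual")
  expect_false("flat" %in% fits$feature_id)
  expect_equal(attr(fits, "skipped")$feature_id, "flat")

  bad <- design
  bad$dose_mg_per_kg <- 0  # single dose level
  expect_error(fit_feature_models(values, bad), "dose level")
})

test_that("raw p-values of the null mixed model are calibrated", {
  r <- simulate_lmm_type1(n_features = 1000, seed = 4)
  expect_gt(r$fraction_below_alpha, 0.03)
  expect_lt(r$fraction_below_alpha, 0.07)
})

test_that("differential abundance corrects a shared shift and controls
           q ordering", {
  set.seed(59)
  design <- tiny_design(5)
  n <- nrow(design)
  step <- design$timepoint_day / 21
  n_feat <- 30
  values <- sapply(seq_len(n_feat), function(j) {
    rnorm(n, 0, 0.3) + 0.25 * step  # shared time shift = compositional bias
  })
  dimnames(values) <- list(design$sample_id, sprintf("f%02d", 1:n_feat))
  da <- differential_abundance(values, design, df_method = "residual")
  tl <- da[da$term == "time_linear@CD", ]
  # the shared trend is absorbed into the bias offset, not the estimates
  expect_equal(tl$bias_offset[1], 0.25, tolerance = 0.1)
  expect_lt(mean(abs(tl$estimate)), 0.15)
  expect_true(all(tl$q_value >= tl$p_value - 1e-12))
  expect_equal(tl$q_value, bh_adjust(tl$p_value))
})

test_that("timepoint ratio contrasts recover planted declines", {
  # identical counts at both days -> ratio exactly 1
  d <- expand.grid(cat_id = sprintf("c%02d", 1:12),
                   timepoint_day = c(0, 42), stringsAsFactors = FALSE)
  d$group <- rep(rep(c("CD", "T150", "T300"), each = 4), 2)
  d$value <- rep(21:32, 2)
  rc <- suppressMessages(timepoint_ratio_contrast(d, family = "poisson"))
  expect_equal(rc$ratios$ratio, rep(1, 3), tolerance = 1e-6)

  # multiplicative 20% decline, recovered within a few percent
  set.seed(61)
  reps <- replicate(30, {
    d2 <- expand.grid(cat_id = sprintf("c%02d", 1:21),
                      timepoint_day = c(0, 42), stringsAsFactors = FALSE)
    d2$group <- "CD"
    base <- rlnorm(21, 3, 0.3)
    d2$value <- ifelse(d2$timepoint_day == 0, base,
                       base * 0.8 * rlnorm(21, 0, 0.1))
    timepoint_ratio_contrast(d2, family = "gaussian_log")$ratios$ratio
  })
  expect_equal(mean(reps), 0.8, tolerance = 0.05)

  # planted group difference in ratios is detected most of the time
  set.seed(67)
  hits <- replicate(25, {
    d3 <- expand.grid(cat_id = sprintf("c%02d", 1:42),
                      timepoint_day = c(0, 42), stringsAsFactors = FALSE)
    d3$group <- rep(rep(c("CD", "T300"), each = 21), 2)
    base <- rlnorm(42, 3, 0.3)
    ratio_true <- ifelse(d3$group == "CD", 1, 0.8)
    d3$value <- ifelse(d3$timepoint_day == 0, base,
                       base * ratio_true * rlnorm(84, 0, 0.1)[1:84])
    rr <- timepoint_ratio_contrast(d3, family = "gaussian_log")
    rr$pairwise$p_value[1] < 0.05
  })
  expect_gte(mean(hits), 0.8)

  # zero cell under poisson is refused
  dz <- d
  dz$value[dz$group == "CD" & dz$timepoint_day == 42] <- 0
  expect_error(timepoint_ratio_contrast(dz, family = "poisson"),
               "zero counts")
})
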