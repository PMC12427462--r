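# Calibration / validation studies for the pipeline: Monte-Carlo recovery of
# the planted Shannon trend, PERMANOVA type-I error under the null, and
# end-to-end differential-abundance recovery of the planted trending
# butyrate producers. These are the package's own evidence that the chain
# measures what it claims; the test suite and the reproduction script both
# run them.

#' Reduced-size cohort configuration for simulation studies
#'
#' The default study sizes (10 cats/arm, 200 species, 20 producers) keep
#' replicated cohort generation affordable while preserving the design
#' structure; all other parameters are the full-cohort defaults.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
reduced_cohort_config <- function(...) {
  args <- list(n_cats_per_arm = 10, n_species = 200, n_genera = 80,
               n_butyrate_producers = 20)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

#' Fitted per-arm Shannon time trends of one cohort
#'
#' Shannon diversity per sample (computed on raw counts: depth is drawn
#' independently of timepoint, so finite-depth bias cancels in the slope),
#' then an ordinary-least-squares slope of H against timepoint step within
#' each arm.
#'
#' @param bundle A `trial_bundle`.
#' @return Named numeric vector of per-arm OLS slopes (H per timepoint
#'   step).
#' @export
shannon_arm_slopes <- function(bundle) {
  h <- apply(bundle$abundance$counts, 1, shannon)
  des <- bundle$design[match(names(h), bundle$design$sample_id), ]
  step <- (des$timepoint_day - min(des$timepoint_day)) /
    diff(sort(unique(des$timepoint_day))[1:2])
  vapply(sort(unique(des$diet)), function(arm) {
    i <- des$diet == arm
    unname(stats::coef(stats::lm(h[i] ~ step[i]))[2])
  }, numeric(1))
}

#' Monte-Carlo recovery of the planted Shannon decline
#'
#' Generates replicate cohorts and fits the per-arm linear Shannon trend;
#' with the planted control-arm decline the mean fitted CD slope should
#' match the planted value while the supplemented arms' slopes straddle
#' zero.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param config Cohort configuration (default [reduced_cohort_config()]).
#' @param seed Base seed; cohort r uses `seed * 10000 + r`.
#' @return List: `slopes` (n_cohorts x arms matrix), `mean_slopes`,
#'   `planted` (the configured CD slope).
#' @export
simulate_shannon_trend_recovery <- function(n_cohorts = 200,
                                            config = reduced_cohort_config(),
                                            seed = 1L) {
  slopes <- t(vapply(seq_len(n_cohorts), function(r) {
    shannon_arm_slopes(generate_trial(config, seed = derive_seed(seed, 1, r)))
  }, numeric(length(config$arms))))
  list(slopes = slopes,
       mean_slopes = colMeans(slopes),
       planted = config$shannon_decline_slope)
}

#' PERMANOVA type-I error under the null
#'
#' Replicates a null experiment: log-normal multinomial counts with no
#' group structure, random group labels, CLR, Aitchison distance,
#' one-factor PERMANOVA. Returns the empirical rejection rate at
#' `alpha` — for a calibrated test it matches `alpha`.
#'
#' @param n_rep Number of null replicates.
#' @param n_samples Samples per replicate.
#' @param n_taxa Taxa per replicate.
#' @param n_groups Number of (structureless) groups.
#' @param n_perm Permutations per test.
#' @param alpha Nominal level.
#' @param depth Reads per sample.
#' @param seed Base seed.
#' @return List: `p_values`, `rejection_rate`.
#' @export
simulate_permanova_type1 <- function(n_rep = 500, n_samples = 30,
                                     n_taxa = 50, n_groups = 3,
                                     n_perm = 199, alpha = 0.05,
                                     depth = 20000, seed = 1L) {
  p_values <- vapply(seq_len(n_rep), function(r) {
    with_preserved_rng(derive_seed(seed, 2, r), {
      base <- stats::rnorm(n_taxa, 0, 1.5)
      counts <- t(vapply(seq_len(n_samples), function(i) {
        p <- exp(base + stats::rnorm(n_taxa, 0, 0.5))
        stats::rmultinom(1, depth, p / sum(p))[, 1]
      }, numeric(n_taxa)))
      dimnames(counts) <- list(sprintf("s%03d", seq_len(n_samples)),
                               sprintf("t%03d", seq_len(n_taxa)))
      design <- data.frame(
        sample_id = rownames(counts),
        group = sample(rep(LETTERS[seq_len(n_groups)],
                           length.out = n_samples)))
      d <- aitchison_distance(clr_transform(counts))
      res <- permanova(d, design, terms = "group", n_perm = n_perm,
                       seed = r)
      res$p_value[res$term == "group"]
    })
  }, numeric(1))
  list(p_values = p_values,
       rejection_rate = mean(p_values <= alpha))
}

#' End-to-end differential-abundance recovery
#'
#' For each seed: generate a cohort, identify butyrate producers from the
#' bundle's genome annotations, restrict the abundance table to them, run
#' the LinDA-style differential abundance, and score the planted trending
#' taxa against the arm-stratified linear time trend at `q_threshold`.
#' Sensitivity is the fraction of planted taxa detected; the false-positive
#' rate is the fraction of non-planted producers flagged.
#'
#' @param n_seeds Number of replicate cohorts.
#' @param config Cohort configuration (default [reduced_cohort_config()]).
#' @param q_threshold BH q-value threshold.
#' @param seed Base seed.
#' @return List: `sensitivity`, `fp_rate` (means across seeds),
#'   `per_seed` (data frame).
#' @export
simulate_da_recovery <- function(n_seeds = 50,
                                 config = reduced_cohort_config(),
                                 q_threshold = 0.05, seed = 1L) {
  per_seed <- do.call(rbind, lapply(seq_len(n_seeds), function(r) {
    bundle <- generate_trial(config, seed = derive_seed(seed, 3, r))
    calls <- classify_species(bundle$annotations)
    producers <- producer_subset(bundle$abundance, calls)
    da <- differential_abundance(producers, bundle$design,
                                 df_method = "residual")
    term <- paste0("time_linear@", config$trend_arm)
    hits <- da$feature_id[da$term == term & da$q_value < q_threshold]
    planted <- bundle$truth$planted_trend$taxon_id
    nulls <- setdiff(taxon_ids(producers), planted)
    data.frame(seed = r,
               sensitivity = mean(planted %in% hits),
               fp_rate = if (length(nulls)) mean(nulls %in% hits) else 0)
  }))
  list(sensitivity = mean(per_seed$sensitivity),
       fp_rate = mean(per_seed$fp_rate),
       per_seed = per_seed)
}

#' Null calibration of the per-feature mixed model
#'
#' Pure-noise responses (random intercept per cat plus white noise) run
#' through [fit_feature_models()]; returns the fraction of raw p-values
#' below `alpha` for a chosen term — for a calibrated test it matches
#' `alpha`.
#'
#' @param n_features Number of noise features.
#' @param n_cats_per_arm Cats per arm.
#' @param term Term whose p-values are tallied (default the linear dose
#'   contrast).
#' @param alpha Nominal level.
#' @param sigma_cat,sigma_e Random-intercept and residual SDs.
#' @param df_method Passed to [fit_feature_models()].
#' @param seed Seed.
#' @return List: `p_values`, `fraction_below_alpha`.
#' @export
simulate_lmm_type1 <- function(n_features = 1000, n_cats_per_arm = 7,
                               term = "dose_lin", alpha = 0.05,
                               sigma_cat = 0.5, sigma_e = 0.5,
                               df_method = "residual", seed = 1L) {
  with_preserved_rng(seed, {
    design <- null_design(n_cats_per_arm)
    n <- nrow(design)
    n_cats <- length(unique(design$cat_id))
    b <- stats::rnorm(n_cats * n_features, 0, sigma_cat)
    dim(b) <- c(n_cats, n_features)
    values <- b[match(design$cat_id, unique(design$cat_id)), ] +
      stats::rnorm(n * n_features, 0, sigma_e)
    rownames(values) <- design$sample_id
    colnames(values) <- sprintf("f%04d", seq_len(n_features))
    fits <- fit_feature_models(values, design, df_method = df_method)
    p <- fits$p_value[fits$term == term]
    list(p_values = p, fraction_below_alpha = mean(p < alpha))
  })
}

# Distinct reproducible sub-seeds per study (k) and replicate (r), kept
# inside the 32-bit integer range whatever the base seed.
derive_seed <- function(seed, k, r) {
  as.integer((as.numeric(seed) * 7919 + k * 104729 + r * 7) %% 2147483647)
}

# Minimal balanced 3-arm, 3-timepoint design for feature-model simulations.
null_design <- function(n_cats_per_arm) {
  arms <- c(CD = 0, T150 = 150, T300 = 300)
  cats <- sprintf("cat%03d", seq_len(3 * n_cats_per_arm))
  arm_of <- rep(names(arms), each = n_cats_per_arm)
  out <- do.call(rbind, lapply(seq_along(cats), function(i)
    data.frame(cat_id = cats[i], sex = if (i %% 2) "F" else "M",
               diet = arm_of[i], dose_mg_per_kg = unname(arms[arm_of[i]]),
               timepoint_day = c(0, 21, 42), body_weight_kg = 4.4,
               sample_id = sprintf("%s_d%02d", cats[i], c(0, 21, 42)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
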