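test_that("the ration formula matches its closed form", {
  expect_equal(ration_kcal(1), 100)
  expect_equal(ration_kcal(4.4), 100 * exp(0.67 * log(4.4)), tolerance = 1e-9)
  expect_error(ration_kcal(0), "positive")
  expect_error(ration_kcal(-2), "positive")
})

test_that("the default cohort echoes the trial design", {
  b <- generate_trial(cohort_config(), seed = 1)
  expect_equal(length(unique(b$design$cat_id)), 63)
  expect_equal(nrow(b$design), 189)
  expect_equal(dim(b$abundance$counts), c(189, 560))
  expect_equal(unname(table(b$design$diet[!duplicated(b$design$cat_id)])),
               rep(21L, 3), ignore_attr = TRUE)
  expect_equal(sum(b$design$sex[!duplicated(b$design$cat_id)] == "F"), 38)
  expect_equal(length(unique(b$palatability$cat_id)), 20)
  expect_length(b$truth$producers, 30)
  depths <- rowSums(b$abundance$counts)
  expect_true(all(depths >= 89217 & depths <= 1527695))
})

test_that("generation is deterministic given the seed", {
  cfg <- reduced_cohort_config(n_cats_per_arm = 3, n_species = 40,
                               n_butyrate_producers = 8, n_trend_taxa = 3)
  b1 <- generate_trial(cfg, seed = 99)
  b2 <- generate_trial(cfg, seed = 99)
  expect_identical(b1$abundance$counts, b2$abundance$counts)
  expect_identical(b1$palatability, b2$palatability)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_trial(cfg, seed = 100)
  expect_false(identical(b1$abundance$counts, b3$abundance$counts))
})

test_that("bundles satisfy the core validation contracts", {
  cfg <- reduced_cohort_config(n_cats_per_arm = 4, n_species = 60,
                               n_butyrate_producers = 10, n_trend_taxa = 3)
  b <- generate_trial(cfg, seed = 17)
  expect_silent(validate_trial_design(b$design))
  expect_true(all(b$design$sample_id %in% sample_ids(b$abundance)))
  expect_silent(validate_palatability(b$palatability))
  expect_silent(validate_digestibility(b$digestibility))
  # every planted producer is recoverable from its annotations
  calls <- classify_species(b$annotations)
  expect_setequal(calls$species_id[calls$likelihood == "high"],
                  b$truth$producers)
  # planted trend taxa are producers in the configured arm
  expect_true(all(b$truth$planted_trend$taxon_id %in% b$truth$producers))
  expect_equal(unique(b$truth$planted_trend$arm), "T300")
  expect_error(cohort_config(n_species = 10, n_butyrate_producers = 11),
               "cannot exceed")
})

test_that("multinomial sampling preserves the expected composition", {
  set.seed(83)
  p <- c(0.5, 0.3, 0.15, 0.05)
  reps <- 400
  draws <- rmultinom(reps, 5000, p) / 5000
  expect_equal(rowMeans(draws), p, tolerance = 3 * sqrt(max(p) / (5000 * reps)))

  # cohort-level: relative abundances average to the per-sample compositions
  cfg <- reduced_cohort_config(n_cats_per_arm = 3, n_species = 30,
                               n_butyrate_producers = 5, n_trend_taxa = 2,
                               sigma_sample = 0, shannon_decline_slope = 0)
  b <- generate_trial(cfg, seed = 3)
  rel <- relative_abundance(b$abundance)
  expect_equal(unname(rowSums(rel)), rep(1, nrow(rel)))
})

test_that("with no preference effect the two bowls are exchangeable", {
  cfg <- reduced_cohort_config(preference_effect = 0, abstention_prob = 0,
                               pal_n_cats = 20, n_cats_per_arm = 2,
                               n_species = 20, n_butyrate_producers = 4,
                               n_trend_taxa = 2)
  shares <- c(); chooses <- 0; n_choices <- 0
  for (s in 1:25) {
    b <- generate_trial(cfg, seed = 1000 + s)
    pair <- b$palatability[b$palatability$diet_a == "CD" &
                             b$palatability$diet_b == "T300", ]
    shares <- c(shares, sum(pair$grams_b) / sum(pair$grams_a + pair$grams_b))
    chooses <- chooses + sum(pair$first_choice == "T300")
    n_choices <- n_choices + nrow(pair)
  }
  # consumption centred on a 1:1 split
  expect_equal(mean(shares), 0.5, tolerance = 0.03)
  # first choices consistent with Binomial(n, 1/2) at alpha = 0.01
  expect_gt(binom.test(chooses, n_choices, 0.5)$p.value, 0.01)
})

test_that("genus aggregation conserves reads and sample sets", {
  cfg <- reduced_cohort_config(n_cats_per_arm = 3, n_species = 50,
                               n_genera = 12, n_butyrate_producers = 6,
                               n_trend_taxa = 2)
  b <- generate_trial(cfg, seed = 21)
  gen <- aggregate_taxa(b$abundance, b$genus_map, rank = "genus")
  expect_equal(gen$rank, "genus")
  expect_equal(unname(rowSums(gen$counts)),
               unname(rowSums(b$abundance$counts)))
  expect_lte(ncol(gen$counts), 12)
})

test_that("bundles round-trip through the plain-text writers", {
  cfg <- reduced_cohort_config(n_cats_per_arm = 2, n_species = 25,
                               n_genera = 8, n_butyrate_producers = 4,
                               n_trend_taxa = 2, pal_n_cats = 4)
  b <- generate_trial(cfg, seed = 29)
  dir <- withr::local_tempdir()
  write_trial_bundle(b, dir)
  back <- read_abundance_table(file.path(dir, "abundance.tsv"), "long")
  expect_identical(back$counts, b$abundance$counts)
  anns <- read_genome_annotations(file.path(dir, "annotations.tsv"))
  expect_identical(annotations_to_frame(anns),
                   annotations_to_frame(b$annotations))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$producers, b$truth$producers)
})
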