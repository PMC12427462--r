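# Synthetic trial bundle emulating the feeding-trial design: 3 arms x 21
# cats x 3 timepoints, log-normal species abundances sampled multinomially at
# heterogeneous depth, a planted linear Shannon decline in the control arm,
# planted monotone log-abundance trends in selected butyrate producers of the
# high-dose arm, genome annotations carrying the butyrate routes, and
# two-bowl palatability records with a configurable preference effect.
# Every stochastic choice flows from one integer seed.

#' Configuration for the synthetic cohort
#'
#' Defaults mirror the trial: 21 cats per arm over doses 0/150/300 mg/kg BW,
#' fecal samples at days 0/21/42, 560 species collapsing to 198 genera,
#' per-sample sequencing depth uniform on 89,217-1,527,695 reads, 30
#' butyrate-producer species, a -0.07 per-step Shannon decline planted in the
#' control arm, and 5 producer species with monotone CLR trends of magnitude
#' 0.4 per step (3 decreasing, 2 increasing) planted in the high-dose arm.
#'
#' @param n_cats_per_arm Cats per diet arm.
#' @param arms Named dose vector (mg SCFP per kg body weight).
#' @param timepoints Sampling days.
#' @param n_species,n_genera Taxon pool sizes.
#' @param depth_range Per-sample read depth bounds (uniform draw).
#' @param lognormal_mu,lognormal_sigma Log-normal parameters of the base
#'   species abundance profile.
#' @param sigma_cat SD of the per-cat log-abundance offsets (a cat's
#'   persistent community signature).
#' @param sigma_sample SD of the per-sample log-abundance jitter
#'   (day-to-day compositional noise).
#' @param shannon_decline_slope Planted control-arm Shannon change per
#'   timepoint step (natural-log units).
#' @param n_butyrate_producers Number of producer species.
#' @param n_trend_taxa Number of producers given planted trends.
#' @param trend_slope Magnitude of the planted per-step log-fold trend.
#' @param trend_arm Arm receiving the planted taxon trends.
#' @param pal_n_cats,pal_offered_g Palatability panel size and grams offered
#'   per bowl.
#' @param preference_effect Log-odds shift in favour of the supplemented
#'   bowl (consumption share and first choice).
#' @param abstention_prob Probability a cat makes no first choice on a day.
#' @param female_fraction Fraction of female cats (38/63 in the trial).
#' @param bw_mean,bw_sd Body-weight distribution (kg).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cats_per_arm = 21,
                          arms = c(CD = 0, T150 = 150, T300 = 300),
                          timepoints = c(0, 21, 42),
                          n_species = 560,
                          n_genera = 198,
                          depth_range = c(89217, 1527695),
                          lognormal_mu = 0,
                          lognormal_sigma = 1.5,
                          sigma_cat = 0.5,
                          sigma_sample = 0.3,
                          shannon_decline_slope = -0.07,
                          n_butyrate_producers = 30,
                          n_trend_taxa = 5,
                          trend_slope = 0.4,
                          trend_arm = "T300",
                          pal_n_cats = 20,
                          pal_offered_g = 100,
                          preference_effect = 0.8,
                          abstention_prob = 0.025,
                          female_fraction = 38 / 63,
                          bw_mean = 4.4,
                          bw_sd = 0.8) {
  cfg <- as.list(environment())
  if (cfg$n_butyrate_producers > cfg$n_species)
    stop("n_butyrate_producers cannot exceed n_species")
  if (cfg$n_trend_taxa > cfg$n_butyrate_producers)
    stop("n_trend_taxa cannot exceed n_butyrate_producers")
  if (cfg$depth_range[1] > cfg$depth_range[2])
    stop("depth_range lower bound exceeds upper bound")
  if (anyDuplicated(cfg$arms)) stop("arms must map to distinct doses")
  if (cfg$n_cats_per_arm < 1 || cfg$n_species < 2) stop("counts must be positive")
  structure(cfg, class = "cohort_config")
}

#' Daily energy ration
#'
#' Maintenance energy requirement used to set the daily food offer:
#' 100 x (body weight in kg)^0.67 kcal/day.
#'
#' @param body_weight_kg Positive body weight in kg.
#' @return kcal per day.
#' @examples
#' ration_kcal(4.4)
#' @export
ration_kcal <- function(body_weight_kg) {
  if (any(!is.finite(body_weight_kg)) || any(body_weight_kg <= 0))
    stop("body weight must be positive")
  100 * body_weight_kg^0.67
}

#' Generate a synthetic trial bundle
#'
#' Produces every input the analysis chain consumes, together with a `truth`
#' record of the planted parameters sufficient to score their recovery.
#'
#' The control arm's Shannon decline is planted as a progressive power tilt
#' of each cat's composition, \eqn{p_i \propto p_i^{1+\epsilon t}}, with
#' \eqn{\epsilon} solved per cat so that the expected ordinary-least-squares
#' Shannon slope over the three equally spaced timepoints equals the target.
#' Planted trend taxa receive linear log-abundance trends in their arm.
#' Producer genomes carry a complete butyrate route; for producers with
#' several genomes only one genome carries the route, exercising the
#' any-genome species rule.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; bundles are identical for identical seeds.
#' @return List of class `trial_bundle`: `abundance` (species-rank
#'   [abundance_table()]), `annotations` (`genome_annotation_set`), `design`
#'   (trial design frame), `palatability`, `digestibility`, `genus_map`
#'   (species -> genus), and `truth` (planted parameters: producer ids,
#'   planted trend table, Shannon slope, preference effect, per-cat tilt
#'   epsilons).
#' @export
generate_trial <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_preserved_rng(seed, generate_trial_impl(config))
}

generate_trial_impl <- function(cfg) {
  arms <- names(cfg$arms)
  n_cats <- cfg$n_cats_per_arm * length(arms)
  cats <- sprintf("cat%03d", seq_len(n_cats))
  species <- sprintf("sp%03d", seq_len(cfg$n_species))
  genera <- sprintf("gen%03d", seq_len(cfg$n_genera))

  ## --- design ---------------------------------------------------------
  n_f <- round(n_cats * cfg$female_fraction)
  sex <- sample(c(rep("F", n_f), rep("M", n_cats - n_f)))
  # randomisation stratified by sex: shuffle within sex, deal arms round-robin
  arm_of <- character(n_cats)
  for (s in c("F", "M")) {
    i <- sample(which(sex == s))
    arm_of[i] <- rep(arms, length.out = length(i))
  }
  # trim to exact balance: reassign surplus cats to deficient arms
  tab <- table(factor(arm_of, levels = arms))
  while (any(tab != cfg$n_cats_per_arm)) {
    over <- names(tab)[which.max(tab)]
    under <- names(tab)[which.min(tab)]
    i <- which(arm_of == over)[1]
    arm_of[i] <- under
    tab <- table(factor(arm_of, levels = arms))
  }
  bw <- pmin(pmax(stats::rnorm(n_cats, cfg$bw_mean, cfg$bw_sd), 2.6), 6.4)
  design <- do.call(rbind, lapply(seq_len(n_cats), function(i)
    data.frame(cat_id = cats[i], sex = sex[i], diet = arm_of[i],
               dose_mg_per_kg = unname(cfg$arms[arm_of[i]]),
               timepoint_day = cfg$timepoints,
               body_weight_kg = bw[i],
               sample_id = sprintf("%s_d%02d", cats[i], cfg$timepoints),
               stringsAsFactors = FALSE)))
  rownames(design) <- NULL
  validate_trial_design(design)

  ## --- composition ----------------------------------------------------
  base_log <- stats::rnorm(cfg$n_species, cfg$lognormal_mu, cfg$lognormal_sigma)
  names(base_log) <- species
  base_p <- exp(base_log - max(base_log))
  base_p <- base_p / sum(base_p)

  producers <- sort(sample(species, cfg$n_butyrate_producers))
  # plant trends in the most abundant producers so trends are identifiable
  prod_by_ab <- producers[order(base_p[producers], decreasing = TRUE)]
  trend_taxa <- sort(prod_by_ab[seq_len(cfg$n_trend_taxa)])
  n_down <- ceiling(cfg$n_trend_taxa / 2)
  trend <- data.frame(
    taxon_id = trend_taxa,
    arm = cfg$trend_arm,
    slope = cfg$trend_slope *
      c(rep(-1, n_down), rep(1, cfg$n_trend_taxa - n_down)),
    stringsAsFactors = FALSE)

  cat_log <- vapply(seq_len(n_cats), function(i)
    base_log + stats::rnorm(cfg$n_species, 0, cfg$sigma_cat),
    numeric(cfg$n_species))  # species x cats

  steps <- (cfg$timepoints - cfg$timepoints[1]) /
    diff(cfg$timepoints[1:2])  # 0, 1, 2 for equally spaced days
  max_step <- max(steps)

  eps <- numeric(n_cats)
  names(eps) <- cats
  counts <- matrix(0, nrow = nrow(design), ncol = cfg$n_species,
                   dimnames = list(design$sample_id, species))
  for (i in seq_len(n_cats)) {
    p_cat <- exp(cat_log[, i] - max(cat_log[, i]))
    p_cat <- p_cat / sum(p_cat)
    if (arm_of[i] == "CD" && cfg$shannon_decline_slope != 0) {
      eps[i] <- solve_tilt_epsilon(p_cat, cfg$shannon_decline_slope, max_step)
    }
    for (k in seq_along(cfg$timepoints)) {
      t_step <- steps[k]
      p <- p_cat
      if (eps[i] != 0) {
        p <- p^(1 + eps[i] * t_step)
        p <- p / sum(p)
      }
      j <- trend$arm == arm_of[i]
      if (any(j)) {
        p[trend$taxon_id[j]] <- p[trend$taxon_id[j]] * exp(trend$slope[j] * t_step)
        p <- p / sum(p)
      }
      if (cfg$sigma_sample > 0) {
        p <- p * exp(stats::rnorm(cfg$n_species, 0, cfg$sigma_sample))
        p <- p / sum(p)
      }
      depth <- round(stats::runif(1, cfg$depth_range[1], cfg$depth_range[2]))
      sid <- sprintf("%s_d%02d", cats[i], cfg$timepoints[k])
      counts[sid, ] <- stats::rmultinom(1, depth, p)[, 1]
    }
  }
  abundance <- abundance_table(counts, rank = "species")
  genus_map <- stats::setNames(sample(genera, cfg$n_species, replace = TRUE),
                               species)

  ## --- genome annotations --------------------------------------------
  annotations <- synth_annotations(species, producers)

  ## --- palatability ---------------------------------------------------
  pairs <- list(c("CD", "T150"), c("CD", "T300"), c("T150", "T300"))
  palatability <- do.call(rbind, lapply(pairs, function(pr)
    synth_palatability(pr[1], pr[2], cfg)))
  rownames(palatability) <- NULL
  validate_palatability(palatability, offered_g = cfg$pal_offered_g)

  ## --- digestibility --------------------------------------------------
  nutrients <- c("dry_matter", "protein", "fat", "energy")
  digestibility <- do.call(rbind, lapply(nutrients, function(nu) {
    intake <- pmax(stats::rnorm(n_cats, 16, 2), 5)
    attd <- stats::rnorm(n_cats, 82, 2)
    data.frame(cat_id = cats, nutrient = nu,
               intake_g_per_day = intake,
               fecal_output_g_per_day = intake * (1 - attd / 100),
               stringsAsFactors = FALSE)
  }))
  rownames(digestibility) <- NULL
  validate_digestibility(digestibility)

  structure(list(
    abundance = abundance,
    annotations = annotations,
    design = design,
    palatability = palatability,
    digestibility = digestibility,
    genus_map = genus_map,
    truth = list(producers = producers,
                 planted_trend = trend,
                 shannon_slope = cfg$shannon_decline_slope,
                 preference_effect = cfg$preference_effect,
                 tilt_epsilon = eps)),
    class = "trial_bundle")
}

# Solve the tilt exponent so that the OLS Shannon slope over equally spaced
# steps 0..max_step equals `slope`. With equally spaced steps the OLS slope
# is (H(max_step) - H(0)) / max_step, so a single root-find suffices.
solve_tilt_epsilon <- function(p, slope, max_step) {
  h0 <- shannon(p)
  f <- function(eps) {
    q <- p^(1 + eps * max_step)
    shannon(q / sum(q)) - h0 - slope * max_step
  }
  lo <- -0.4; hi <- 2
  if (f(lo) * f(hi) > 0) stop("cannot calibrate tilt for target slope ", slope)
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

# Genome annotations: producers carry one complete butyrate route in exactly
# one genome; a share of non-producers carries an incomplete route subset so
# the completeness rules are actually exercised. Background features avoid
# all catalog ECs.
synth_annotations <- function(species, producers) {
  catalog <- butyrate_pathway_catalog()
  route_ecs <- lapply(catalog$routes, `[[`, "ecs")
  all_route_ecs <- unique(unlist(route_ecs))
  bg_ec_pool <- setdiff(sprintf("%d.%d.%d.%d",
                                sample(1:6, 300, TRUE), sample(1:9, 300, TRUE),
                                sample(1:9, 300, TRUE), sample(1:99, 300, TRUE)),
                        all_route_ecs)
  ko_pool <- sprintf("K%05d", sample(2000:9999, 400))
  pw_pool <- sprintf("map%05d", sample(100:1100, 150))
  cz_pool <- c(sprintf("GH%d", 1:60), sprintf("GT%d", 1:30), sprintf("PL%d", 1:15))

  rows <- list()
  gi <- 0L
  for (sp in species) {
    n_gen <- sample(1:3, 1)
    is_prod <- sp %in% producers
    route_genome <- if (is_prod) sample(n_gen, 1) else 0L
    for (g in seq_len(n_gen)) {
      gi <- gi + 1L
      gid <- sprintf("gm%04d", gi)
      ecs <- sample(bg_ec_pool, sample(3:10, 1))
      kos <- sample(ko_pool, sample(5:15, 1))
      pws <- sample(pw_pool, sample(3:8, 1))
      czs <- sample(cz_pool, sample(2:6, 1))
      if (is_prod && g == route_genome) {
        route <- catalog$routes[[sample(names(catalog$routes), 1)]]
        ecs <- c(ecs, if (route$rule == "terminal_pair") catalog$terminal_ecs
                      else route$ecs)
        kos <- c(kos, sample(unname(catalog$terminal_kos), sample(1:3, 1)))
      } else if (!is_prod && stats::runif(1) < 0.15) {
        # incomplete route: drop at least one required gene
        route <- catalog$routes[[sample(names(catalog$routes), 1)]]
        req <- if (route$rule == "terminal_pair") catalog$terminal_ecs else route$ecs
        ecs <- c(ecs, sample(req, length(req) - 1))
      }
      feat <- rbind(
        data.frame(feature_type = "EC", feature_id = unique(ecs)),
        data.frame(feature_type = "KO", feature_id = unique(kos)),
        data.frame(feature_type = "PATHWAY", feature_id = unique(pws)),
        data.frame(feature_type = "CAZY", feature_id = unique(czs)))
      rows[[gi]] <- data.frame(genome_id = gid, species_id = sp, feat,
                               stringsAsFactors = FALSE)
    }
  }
  annotations_from_frame(do.call(rbind, rows))
}

# Two-bowl records for one diet pairing. The supplemented (higher-dose) bowl
# gets a logit shift of `preference_effect` in both the consumption share
# and the first-choice probability; between two supplemented diets the
# shift is zero.
synth_palatability <- function(diet_a, diet_b, cfg) {
  dose <- c(CD = 0, T150 = 1, T300 = 2)
  effect <- if (xor(diet_a == "CD", diet_b == "CD")) cfg$preference_effect else 0
  shift_b <- if (dose[diet_b] > dose[diet_a]) effect else -effect
  phi <- 6  # Beta concentration of the consumption share
  out <- list()
  r <- 0L
  for (cat in sprintf("pal%02d", seq_len(cfg$pal_n_cats))) {
    cat_pref <- stats::rnorm(1, 0, 0.6)  # per-cat taste, shared across days
    for (day in 1:2) {
      mu_b <- stats::plogis(shift_b + cat_pref)
      share_b <- stats::rbeta(1, mu_b * phi, (1 - mu_b) * phi)
      total <- cfg$pal_offered_g * stats::rbeta(1, 5, 3)
      grams_b <- min(total * share_b, cfg$pal_offered_g)
      grams_a <- min(total - grams_b, cfg$pal_offered_g)
      first <- if (stats::runif(1) < cfg$abstention_prob) "none"
               else if (stats::runif(1) < stats::plogis(shift_b + cat_pref)) diet_b
               else diet_a
      r <- r + 1L
      out[[r]] <- data.frame(cat_id = cat, day = day,
                             diet_a = diet_a, diet_b = diet_b,
                             grams_a = grams_a, grams_b = grams_b,
                             first_choice = first, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Aggregate a species table to a coarser rank
#'
#' @param table An [abundance_table()].
#' @param mapping Named character vector: taxon id -> parent taxon id.
#' @param rank Rank label of the aggregated table.
#' @return An [abundance_table()] at the coarser rank.
#' @export
aggregate_taxa <- function(table, mapping, rank = "genus") {
  stopifnot(inherits(table, "abundance_table"))
  miss <- setdiff(taxon_ids(table), names(mapping))
  if (length(miss))
    stop("mapping lacks taxa: ", paste(utils::head(miss, 5), collapse = ", "))
  parent <- mapping[taxon_ids(table)]
  agg <- t(rowsum(t(table$counts), group = parent))
  abundance_table(agg, rank = rank)
}

#' Write a trial bundle as plain-text files
#'
#' Writes the abundance table (long TSV), annotations, design, palatability
#' and digestibility tables plus a `truth.json` into a directory.
#'
#' @param bundle A `trial_bundle` from [generate_trial()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_result_table(bundle$abundance, file.path(dir, "abundance.tsv"))
  write_result_table(annotations_to_frame(bundle$annotations),
                     file.path(dir, "annotations.tsv"))
  write_result_table(bundle$design, file.path(dir, "design.tsv"))
  write_result_table(bundle$palatability, file.path(dir, "palatability.tsv"))
  write_result_table(bundle$digestibility, file.path(dir, "digestibility.tsv"))
  write_result_table(
    data.frame(taxon_id = names(bundle$genus_map),
               genus_id = unname(bundle$genus_map)),
    file.path(dir, "genus_map.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
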