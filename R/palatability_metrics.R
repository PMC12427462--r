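# Two-bowl palatability analytics and the apparent total tract
# digestibility (ATTD) calculation.
#
# Conventions, frozen against the trial's printed worked examples:
#  * consumption ratio reports the larger-consumed diet first (ratio >= 1);
#    2:1 is the standard clear-preference criterion;
#  * the first-choice chi-square expects n_cats * n_days / 2 choices per
#    diet — abstaining cats do NOT reduce the expectation.

#' Summarise two-bowl consumption for one diet pair
#'
#' Totals, percentages and the consumption ratio across all cats and days,
#' with the larger-consumed diet reported first.
#'
#' @param records Palatability records (see [validate_palatability()]) for a
#'   single diet pair.
#' @return List of class `consumption_summary`: `diets` (larger-consumed
#'   first), `totals_g`, `percents`, `ratio` (>= 1), `grand_total_g`,
#'   `clear_preference` (ratio >= 2).
#' @export
consumption_summary <- function(records) {
  records <- validate_pair(records)
  diets <- c(records$diet_a[1], records$diet_b[1])
  totals <- c(sum(records$grams_a), sum(records$grams_b))
  if (sum(totals) <= 0) stop("no consumption recorded for either diet")
  ord <- order(totals, decreasing = TRUE)
  diets <- diets[ord]; totals <- totals[ord]
  ratio <- if (totals[2] > 0) totals[1] / totals[2] else Inf
  structure(list(diets = diets,
                 totals_g = stats::setNames(totals, diets),
                 percents = stats::setNames(100 * totals / sum(totals), diets),
                 ratio = ratio,
                 grand_total_g = sum(totals),
                 clear_preference = clear_preference(ratio)),
            class = "consumption_summary")
}

validate_pair <- function(records) {
  if (nrow(records) == 0L) stop("no palatability records")
  if (length(unique(records$diet_a)) != 1L ||
      length(unique(records$diet_b)) != 1L)
    stop("records must cover a single diet pair")
  records
}

#' Per-cat intake ratios
#'
#' A diet's intake ratio (IR) for a cat is its share of the cat's total
#' two-bowl consumption, pooled over days; the two IRs of a cat sum to 1.
#' Cats that consumed nothing are excluded (with a message).
#'
#' @param records Palatability records for a single diet pair.
#' @return List of class `intake_ratios`: `per_cat` (data frame `cat_id`,
#'   `ir_a`, `ir_b`), `mean_ir` (named by diet), `diets`.
#' @export
intake_ratio_per_cat <- function(records) {
  records <- validate_pair(records)
  diets <- c(records$diet_a[1], records$diet_b[1])
  a <- tapply(records$grams_a, records$cat_id, sum)
  b <- tapply(records$grams_b, records$cat_id, sum)
  tot <- a + b
  zero <- tot <= 0
  if (any(zero)) {
    message("excluding cat(s) with zero total consumption: ",
            paste(names(tot)[zero], collapse = ", "))
    a <- a[!zero]; b <- b[!zero]; tot <- tot[!zero]
  }
  per_cat <- data.frame(cat_id = names(tot), ir_a = as.numeric(a / tot),
                        ir_b = as.numeric(b / tot), stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(list(per_cat = per_cat,
                 mean_ir = stats::setNames(c(mean(per_cat$ir_a),
                                             mean(per_cat$ir_b)), diets),
                 diets = diets),
            class = "intake_ratios")
}

#' First-choice chi-square test
#'
#' Goodness-of-fit of the first-choice counts against indifference. The
#' expected count per diet is `n_cats * n_days / 2` regardless of
#' abstentions (a cat that approaches neither bowl still contributes to the
#' expectation), df = 1, no continuity correction.
#'
#' @param counts Length-2 vector of first-choice counts (one per diet).
#' @param n_cats Number of cats tested.
#' @param n_days Number of test days covered by `counts`.
#' @return List: `statistic` (X^2), `p_value`, `expected` (per diet).
#' @export
first_choice_test <- function(counts, n_cats, n_days = 1) {
  if (length(counts) != 2L || any(counts < 0))
    stop("`counts` must be two non-negative first-choice counts")
  if (sum(counts) > n_cats * n_days)
    stop("counts exceed the number of cat-days")
  expected <- n_cats * n_days / 2
  if (expected < 1) stop("expected count below 1; test not applicable")
  x2 <- sum((counts - expected)^2 / expected)
  list(statistic = x2,
       p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Clear-preference criterion
#'
#' The standard 2:1 consumption rule: a consumption ratio of at least 2
#' indicates a clear preference.
#'
#' @param ratio Consumption ratio (>= 1 by the reporting convention).
#' @return `TRUE` iff `ratio >= 2`.
#' @export
clear_preference <- function(ratio) {
  if (any(ratio < 1)) stop("ratio must be >= 1 (larger total first)")
  ratio >= 2
}

#' Paired t-test of daily consumption
#'
#' Two-sided paired t-test comparing per-cat consumption of the two diets
#' within one test day (the t computation is delegated to
#' [stats::t.test()]; pairing and day stratification happen here). With
#' zero-variance differences the test is degenerate: p is reported as 0
#' when the mean difference is nonzero and 1 when it is zero.
#'
#' @param records Palatability records for a single diet pair.
#' @param day Which test day to compare.
#' @return List: `day`, `diets`, `means` (per-diet mean grams), `statistic`,
#'   `p_value`, `n` (pairs), `degenerate` (logical).
#' @export
daily_consumption_test <- function(records, day) {
  records <- validate_pair(records)
  d <- records[records$day == day, , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least two paired observations")
  diets <- c(d$diet_a[1], d$diet_b[1])
  diffs <- d$grams_a - d$grams_b
  if (stats::sd(diffs) == 0) {
    return(list(day = day, diets = diets,
                means = stats::setNames(c(mean(d$grams_a), mean(d$grams_b)),
                                        diets),
                statistic = NA_real_,
                p_value = if (mean(diffs) == 0) 1 else 0,
                n = nrow(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d$grams_a, d$grams_b, paired = TRUE)
  list(day = day, diets = diets,
       means = stats::setNames(c(mean(d$grams_a), mean(d$grams_b)), diets),
       statistic = unname(tt$statistic), p_value = tt$p.value,
       n = nrow(d), degenerate = FALSE)
}

#' Full palatability report for one diet pair
#'
#' Runs the whole two-bowl battery: consumption summary, per-cat intake
#' ratios with the Wilcoxon signed-rank validation, first-choice chi-square
#' per day and overall, and the paired t-test per day.
#'
#' @param records Palatability records for a single diet pair.
#' @return List of class `palatability_report` with elements `consumption`,
#'   `intake_ratios`, `wilcoxon_p` (signed-rank on per-cat IR differences),
#'   `first_choice` (per day and overall), `daily_t` (per day).
#' @export
palatability_report <- function(records) {
  records <- validate_pair(records)
  diets <- c(records$diet_a[1], records$diet_b[1])
  cons <- consumption_summary(records)
  ir <- intake_ratio_per_cat(records)
  wx <- stats::wilcox.test(ir$per_cat$ir_a, ir$per_cat$ir_b, paired = TRUE,
                           exact = FALSE)
  n_cats <- length(unique(records$cat_id))
  days <- sort(unique(records$day))
  fc_day <- lapply(days, function(dy) {
    d <- records[records$day == dy, , drop = FALSE]
    counts <- c(sum(d$first_choice == diets[1]),
                sum(d$first_choice == diets[2]))
    c(list(day = dy, counts = stats::setNames(counts, diets)),
      first_choice_test(counts, n_cats = n_cats, n_days = 1))
  })
  overall_counts <- c(sum(records$first_choice == diets[1]),
                      sum(records$first_choice == diets[2]))
  fc_overall <- c(list(counts = stats::setNames(overall_counts, diets)),
                  first_choice_test(overall_counts, n_cats = n_cats,
                                    n_days = length(days)))
  structure(list(diets = diets,
                 consumption = cons,
                 intake_ratios = ir,
                 wilcoxon_p = wx$p.value,
                 first_choice = list(daily = fc_day, overall = fc_overall),
                 daily_t = lapply(days, daily_consumption_test,
                                  records = records)),
            class = "palatability_report")
}

#' Mixed-effects acceptance model
#'
#' Acceptability is a cat's feed intake divided by the feed offered.
#' The proportion is modelled on the logit scale with treatment as fixed
#' effect and a random intercept per cat (fitting delegated to
#' \pkg{lme4}); the odds ratio of acceptance (treated vs control) is
#' extracted with a Wald interval.
#'
#' @param data Data frame with columns `cat_id`, `treatment` (factor-like;
#'   first sorted level = control), `intake_g`, `offered_g`, and optionally
#'   `period` (included with its treatment interaction) and `sex`
#'   (adjustment).
#' @param conf_level Wald confidence level.
#' @return Data frame: one row per non-control treatment level with
#'   `odds_ratio`, `lower`, `upper`, `p_value`.
#' @export
acceptance_model <- function(data, conf_level = 0.95) {
  need <- c("cat_id", "treatment", "intake_g", "offered_g")
  miss <- setdiff(need, colnames(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (any(data$offered_g <= 0)) stop("offered_g must be positive")
  prop <- data$intake_g / data$offered_g
  if (any(prop < 0 | prop > 1)) stop("intake exceeds offered feed")
  d <- data
  d$treatment <- factor(d$treatment)
  # squeeze exact 0/1 off the boundary for the logit-scale weights
  eps <- 0.5 / max(d$offered_g)
  d$prop <- pmin(pmax(prop, eps), 1 - eps)
  rhs <- "treatment"
  if ("period" %in% colnames(d)) rhs <- "treatment * factor(period)"
  if ("sex" %in% colnames(d)) rhs <- paste(rhs, "+ sex")
  fml <- stats::as.formula(paste("prop ~", rhs, "+ (1 | cat_id)"))
  # proportion outcome with offered-gram weights; glm's integer-successes
  # warning is expected and uninformative here
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = d, family = stats::binomial(),
                weights = d$offered_g),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lev <- levels(d$treatment)[-1]
  out <- do.call(rbind, lapply(lev, function(g) {
    nm <- paste0("treatment", g)
    est <- beta[[nm]]; se <- sqrt(vc[nm, nm])
    data.frame(treatment = g, odds_ratio = exp(est),
               lower = exp(est - z * se), upper = exp(est + z * se),
               p_value = 2 * stats::pnorm(-abs(est / se)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apparent total tract digestibility
#'
#' ATTD (%) = (nutrient intake - fecal output) / nutrient intake x 100.
#' Negative values (output exceeding intake) are permitted but flagged.
#'
#' @param records Digestibility records (see [validate_digestibility()]),
#'   or a single intake/output pair via `intake` and `output`.
#' @param intake,output Scalar shortcut, g/day.
#' @return Data frame: `cat_id`, `nutrient`, `digestibility_pct`,
#'   `flagged` (TRUE when negative).
#' @export
attd <- function(records = NULL, intake = NULL, output = NULL) {
  if (is.null(records)) {
    records <- data.frame(cat_id = "cat", nutrient = "nutrient",
                          intake_g_per_day = intake,
                          fecal_output_g_per_day = output)
  }
  validate_digestibility(records)
  pct <- 100 * (records$intake_g_per_day - records$fecal_output_g_per_day) /
    records$intake_g_per_day
  data.frame(cat_id = records$cat_id, nutrient = records$nutrient,
             digestibility_pct = pct, flagged = pct < 0,
             stringsAsFactors = FALSE, row.names = NULL)
}
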