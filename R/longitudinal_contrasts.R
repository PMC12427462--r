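# Longitudinal statistics: orthogonal polynomial dose/time contrasts,
# per-feature linear mixed models with a random intercept per cat,
# compositional bias correction of the coefficient distribution (the
# LinDA idea: under CLR, a shared compositional shift contaminates every
# feature's coefficient by the same offset, estimated by a robust location
# of the per-feature coefficients and subtracted), Benjamini-Hochberg FDR,
# and day-ratio contrasts for count outcomes on the log-link scale.
#
# Mixed-model fitting is delegated to lme4/lmerTest; contrast construction,
# model stacking across features, and extraction are implemented here.

#' Orthogonal polynomial contrasts for ordered levels
#'
#' Orthonormal linear and quadratic trend codings for ordered numeric
#' levels. Equally spaced levels reproduce the classical coefficients,
#' e.g. linear (-1, 0, 1)/sqrt(2) and quadratic (1, -2, 1)/sqrt(6) for three
#' levels; unequally spaced levels are handled by orthogonalising powers of
#' the centered level values. Codings are invariant to affine rescaling of
#' the levels.
#'
#' @param levels Ordered numeric vector of distinct factor levels
#'   (e.g. doses `c(0, 150, 300)` or days `c(0, 21, 42)`).
#' @return Matrix with one row per level (rownames = levels) and columns
#'   `linear` (and `quadratic` when 3+ levels are supplied); columns are
#'   unit-norm and mutually orthogonal, each orthogonal to the intercept.
#' @export
polynomial_contrasts <- function(levels) {
  if (anyDuplicated(levels)) stop("levels must be distinct")
  if (is.unsorted(levels)) stop("levels must be ordered")
  k <- length(levels)
  if (k < 2) stop("need at least two levels")
  degree <- min(2L, k - 1L)
  cm <- unclass(stats::poly(levels, degree = degree))
  colnames(cm) <- c("linear", "quadratic")[seq_len(degree)]
  rownames(cm) <- levels
  attr(cm, "degree") <- NULL
  attr(cm, "coefs") <- NULL
  cm
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()]), with input validation.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Robust compositional bias correction of per-feature coefficients
#'
#' Under the CLR transform a compositional shift common to all taxa shows up
#' as a constant offset added to every feature's regression coefficient for
#' the affected term. Assuming most features are null, the offset is
#' estimated by a robust location of the coefficient vector (median by
#' default, or the kernel-density mode) and subtracted.
#'
#' @param coefficients Numeric vector, one coefficient per feature, for one
#'   model term.
#' @param mode `"median"` (default) or `"mode"` (kernel density argmax).
#' @return List: `corrected` (vector) and `offset` (the location removed).
#'   With fewer than 5 features a warning is issued and no correction is
#'   applied (offset 0).
#' @export
bias_correct <- function(coefficients, mode = c("median", "mode")) {
  mode <- match.arg(mode)
  if (length(coefficients) < 5) {
    warning("fewer than 5 features; compositional bias not corrected")
    return(list(corrected = coefficients, offset = 0))
  }
  offset <- if (mode == "median") {
    stats::median(coefficients)
  } else {
    d <- stats::density(coefficients)
    d$x[which.max(d$y)]
  }
  list(corrected = coefficients - offset, offset = offset)
}

# Model frame with explicit orthonormal contrast covariates.
# coding "ordered": dose_lin/dose_quad from the dose levels;
# coding "binary": scfp = 1 for any supplemented arm, centered.
build_contrast_frame <- function(design, coding = c("ordered", "binary"),
                                 adjust_sex = FALSE) {
  coding <- match.arg(coding)
  need <- c("cat_id", "dose_mg_per_kg", "timepoint_day", "sample_id")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  tp <- sort(unique(design$timepoint_day))
  if (length(tp) < 2) stop("need at least two timepoints")
  tc <- polynomial_contrasts(tp)
  mf <- data.frame(cat_id = factor(design$cat_id),
                   sample_id = design$sample_id,
                   time_lin = tc[match(design$timepoint_day, tp), "linear"],
                   stringsAsFactors = FALSE)
  attr(mf, "time_contrasts") <- tc
  mf$time_quad <- if (ncol(tc) > 1) tc[match(design$timepoint_day, tp), "quadratic"] else NULL
  doses <- sort(unique(design$dose_mg_per_kg))
  if (coding == "ordered") {
    if (length(doses) < 2) stop("need at least two dose levels")
    dc <- polynomial_contrasts(doses)
    mf$dose_lin <- dc[match(design$dose_mg_per_kg, doses), "linear"]
    if (ncol(dc) > 1)
      mf$dose_quad <- dc[match(design$dose_mg_per_kg, doses), "quadratic"]
    attr(mf, "dose_contrasts") <- dc
    attr(mf, "dose_levels") <- doses
    arm_names <- if ("diet" %in% colnames(design))
      vapply(doses, function(d) design$diet[design$dose_mg_per_kg == d][1],
             character(1))
    else as.character(doses)
    attr(mf, "arm_names") <- arm_names
  } else {
    mf$scfp <- as.numeric(design$dose_mg_per_kg > 0)
    attr(mf, "arm_names") <- c("CD", "SCFP")
  }
  if (adjust_sex) {
    if (!"sex" %in% colnames(design)) stop("design lacks `sex`")
    mf$sex <- factor(design$sex)
  }
  attr(mf, "coding") <- coding
  mf
}

# Fixed-effect formula string for the contrast frame.
contrast_formula <- function(mf) {
  time_terms <- intersect(c("time_lin", "time_quad"), colnames(mf))
  trt_terms <- intersect(c("dose_lin", "dose_quad", "scfp"), colnames(mf))
  rhs <- sprintf("(%s) * (%s)", paste(trt_terms, collapse = " + "),
                 paste(time_terms, collapse = " + "))
  if ("sex" %in% colnames(mf)) rhs <- paste(rhs, "+ sex")
  rhs
}

# Per-arm linear-time-trend contrast vectors (named by coefficient), one per
# arm: d/d(step) of the fitted surface at that arm's dose coding. The
# orthonormal linear time contrast increases by a constant step increment
# between consecutive (equally spaced) timepoints; scaling by it expresses
# the trend per timepoint step rather than per contrast unit.
arm_trend_contrasts <- function(mf, coef_names) {
  arms <- attr(mf, "arm_names")
  tc <- attr(mf, "time_contrasts")
  step_scale <- tc[2, "linear"] - tc[1, "linear"]
  out <- list()
  if (attr(mf, "coding") == "ordered") {
    dc <- attr(mf, "dose_contrasts")
    for (i in seq_along(arms)) {
      l <- stats::setNames(numeric(length(coef_names)), coef_names)
      l["time_lin"] <- 1
      if ("dose_lin:time_lin" %in% coef_names)
        l["dose_lin:time_lin"] <- dc[i, "linear"]
      if ("dose_quad:time_lin" %in% coef_names)
        l["dose_quad:time_lin"] <- dc[i, "quadratic"]
      out[[paste0("time_linear@", arms[i])]] <- l * step_scale
    }
  } else {
    for (i in seq_along(arms)) {
      l <- stats::setNames(numeric(length(coef_names)), coef_names)
      l["time_lin"] <- 1
      if ("scfp:time_lin" %in% coef_names)
        l["scfp:time_lin"] <- i - 1  # CD = 0, SCFP = 1
      out[[paste0("time_linear@", arms[i])]] <- l * step_scale
    }
  }
  out
}

#' Per-feature linear mixed models with polynomial contrasts
#'
#' Fits, for every feature (row or column of `values`), the study's
#' longitudinal model: fixed effects for treatment, timepoint and their
#' interaction coded with orthonormal polynomial (or binary) contrasts, an
#' optional sex adjustment, and a random intercept per cat. Fitting is
#' delegated to \pkg{lme4}/\pkg{lmerTest} via a single prototype model that
#' is refit per feature; contrast construction and extraction are done here.
#'
#' In addition to the model coefficients, the per-arm linear time trend
#' (the trend-over-time-stratified-by-diet contrast) is extracted for every
#' arm, expressed per timepoint step so a planted slope of b response units
#' per step is estimated as b.
#'
#' @param values Numeric matrix of responses on a linear-model scale (e.g.
#'   CLR values): samples x features with rownames = sample ids (a
#'   features x samples matrix is accepted and transposed when its colnames
#'   match the design instead).
#' @param design Trial design frame (see [validate_trial_design()]); only
#'   rows matching the value matrix's samples are used.
#' @param coding `"ordered"` (polynomial dose contrasts) or `"binary"`
#'   (control vs pooled SCFP).
#' @param adjust_sex Include a fixed sex adjustment.
#' @param df_method `"satterthwaite"` (default, via \pkg{lmerTest}) or
#'   `"residual"` (t with n - p degrees of freedom; much faster for large
#'   simulation studies).
#' @param reml Fit by REML (default) or ML.
#' @return Long data frame of class `feature_fits`: `feature_id`, `term`
#'   (fixed-effect coefficients plus `time_linear@<arm>` contrasts),
#'   `estimate`, `se`, `df`, `t_value`, `p_value`. Features that are
#'   constant are skipped; their ids and reasons are in
#'   `attr(, "skipped")`.
#' @export
fit_feature_models <- function(values, design,
                               coding = c("ordered", "binary"),
                               adjust_sex = FALSE,
                               df_method = c("satterthwaite", "residual"),
                               reml = TRUE) {
  coding <- match.arg(coding)
  df_method <- match.arg(df_method)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) ||
      !all(rownames(values) %in% design$sample_id)) {
    if (!is.null(colnames(values)) &&
        all(colnames(values) %in% design$sample_id)) {
      values <- t(values)
    } else stop("value matrix samples do not match design sample ids")
  }
  design <- design[match(rownames(values), design$sample_id), , drop = FALSE]
  mf <- build_contrast_frame(design, coding = coding, adjust_sex = adjust_sex)
  rhs <- contrast_formula(mf)

  x <- stats::model.matrix(stats::as.formula(paste("~", rhs)), mf)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- colnames(x)[setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient fixed effects; offending term(s): ",
         paste(drop, collapse = ", "))
  }

  feats <- colnames(values)
  if (is.null(feats)) feats <- paste0("feature", seq_len(ncol(values)))
  keep <- apply(values, 2, function(v) stats::sd(v) > 0)
  skipped <- if (any(!keep))
    data.frame(feature_id = feats[!keep], reason = "constant feature")
  else NULL

  fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | cat_id)"))
  mf$y <- values[, which(keep)[1]]
  proto <- lmerTest::lmer(fml, data = mf, REML = reml,
                          control = lme4::lmerControl(calc.derivs = FALSE))
  coef_names <- names(lme4::fixef(proto))
  trend_l <- arm_trend_contrasts(mf, coef_names)
  n <- nrow(values)
  df_res <- n - length(coef_names)

  extract_one <- function(fit, feature) {
    beta <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    rows <- list()
    if (df_method == "satterthwaite") {
      ct <- stats::coef(summary(fit))
      rows[[1]] <- data.frame(feature_id = feature, term = rownames(ct),
                              estimate = ct[, "Estimate"],
                              se = ct[, "Std. Error"], df = ct[, "df"],
                              t_value = ct[, "t value"],
                              p_value = ct[, "Pr(>|t|)"],
                              stringsAsFactors = FALSE)
      for (nm in names(trend_l)) {
        cc <- lmerTest::contest1D(fit, trend_l[[nm]], confint = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(feature_id = feature, term = nm,
                     estimate = cc$Estimate, se = cc$`Std. Error`,
                     df = cc$df, t_value = cc$`t value`,
                     p_value = cc$`Pr(>|t|)`, stringsAsFactors = FALSE)
      }
    } else {
      se <- sqrt(diag(vc))
      tv <- beta / se
      rows[[1]] <- data.frame(feature_id = feature, term = names(beta),
                              estimate = unname(beta), se = unname(se),
                              df = df_res, t_value = unname(tv),
                              p_value = 2 * stats::pt(-abs(tv), df_res),
                              stringsAsFactors = FALSE)
      for (nm in names(trend_l)) {
        l <- trend_l[[nm]]
        est <- sum(l * beta)
        s <- sqrt(drop(t(l) %*% vc %*% l))
        tv1 <- est / s
        rows[[length(rows) + 1L]] <-
          data.frame(feature_id = feature, term = nm, estimate = est,
                     se = s, df = df_res, t_value = tv1,
                     p_value = 2 * stats::pt(-abs(tv1), df_res),
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  res <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    j <- j + 1L
    fit <- if (i == which(keep)[1]) proto
           else suppressMessages(lme4::refit(proto, newresp = values[, i]))
    if (df_method == "satterthwaite" && !inherits(fit, "lmerModLmerTest"))
      fit <- lmerTest::as_lmerModLmerTest(fit)
    res[[j]] <- extract_one(fit, feats[i])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "df_method") <- df_method
  attr(out, "coding") <- coding
  class(out) <- c("feature_fits", "data.frame")
  out
}

#' LinDA-style differential abundance
#'
#' The full differential-abundance chain: CLR transform (when a count table
#' is supplied), per-feature linear mixed models via
#' [fit_feature_models()], compositional bias correction of every
#' non-intercept term's coefficient distribution via [bias_correct()],
#' recomputed test statistics, and Benjamini-Hochberg adjustment within
#' term.
#'
#' @param x An [abundance_table()] (CLR-transformed internally) or a numeric
#'   samples x features matrix already on a linear scale.
#' @param design Trial design frame.
#' @param pseudocount CLR pseudocount for count input.
#' @param bias_mode `"median"` or `"mode"`, see [bias_correct()].
#' @param ... Passed to [fit_feature_models()] (`coding`, `adjust_sex`,
#'   `df_method`, `reml`).
#' @return Data frame of class `da_result`: `feature_id`, `term`,
#'   `estimate` (bias-corrected), `estimate_raw`, `se`, `df`, `p_value`,
#'   `q_value`, `bias_offset`.
#' @export
differential_abundance <- function(x, design, pseudocount = 0.5,
                                   bias_mode = "median", ...) {
  values <- if (inherits(x, "abundance_table"))
    clr_transform(x, pseudocount = pseudocount)
  else x
  fits <- fit_feature_models(values, design, ...)
  out <- do.call(rbind, lapply(split(fits, fits$term), function(d) {
    correct <- d$term[1] != "(Intercept)"
    bc <- if (correct && nrow(d) >= 5) bias_correct(d$estimate, mode = bias_mode)
          else list(corrected = d$estimate, offset = 0)
    tv <- bc$corrected / d$se
    p <- 2 * stats::pt(-abs(tv), d$df)
    data.frame(feature_id = d$feature_id, term = d$term,
               estimate = bc$corrected, estimate_raw = d$estimate,
               se = d$se, df = d$df, p_value = p, q_value = bh_adjust(p),
               bias_offset = bc$offset, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "skipped") <- attr(fits, "skipped")
  class(out) <- c("da_result", "data.frame")
  out
}

#' Day-ratio contrasts for longitudinal count outcomes
#'
#' Fits a log-link mixed model (Poisson, or Gaussian on log-transformed
#' values) with group, timepoint and their interaction as fixed effects and
#' a random intercept per cat, then extracts for every group the
#' response-scale ratio between the two focal days (ratio < 1: higher at
#' the first day; > 1: higher at the second), along with pairwise
#' between-group comparisons of the ratios and polynomial dose contrasts on
#' the log-ratios. Fitting is delegated to \pkg{lme4}; all contrast algebra
#' is computed from the fixed-effect estimates and their covariance.
#'
#' @param data Data frame with columns `cat_id`, `group`, `timepoint_day`,
#'   `value` (plus optionally `dose` for the polynomial contrasts; when
#'   absent, groups are assumed ordered by their sorted labels and coded
#'   with equally spaced scores).
#' @param family `"poisson"` or `"gaussian_log"`.
#' @param day_pair The two days whose ratio is estimated (default first and
#'   last observed).
#' @param conf_level Confidence level for the Wald intervals.
#' @return List of class `ratio_contrast`: `ratios` (per group: `ratio`,
#'   `lower`, `upper`, `p_value` testing ratio = 1), `pairwise` (ratio of
#'   ratios between groups with Wald p), `polynomial` (linear/quadratic
#'   dose contrasts on the log-ratios).
#' @export
timepoint_ratio_contrast <- function(data, family = c("poisson", "gaussian_log"),
                                     day_pair = NULL, conf_level = 0.95) {
  family <- match.arg(family)
  need <- c("cat_id", "group", "timepoint_day", "value")
  miss <- setdiff(need, colnames(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  days <- sort(unique(data$timepoint_day))
  if (length(days) < 2) stop("need at least two timepoints per cat")
  if (is.null(day_pair)) day_pair <- c(days[1], days[length(days)])
  d <- data[data$timepoint_day %in% day_pair, , drop = FALSE]
  d$tp <- factor(d$timepoint_day, levels = day_pair)
  d$group <- factor(d$group)
  groups <- levels(d$group)

  one_group <- length(groups) == 1L
  rhs <- if (one_group) "tp + (1 | cat_id)" else "group * tp + (1 | cat_id)"
  if (family == "poisson") {
    cell <- tapply(d$value, list(d$group, d$tp), sum)
    if (any(cell == 0))
      stop("a whole group x timepoint cell has zero counts; ",
           "Poisson log-link ratio undefined")
    fit <- lme4::glmer(stats::as.formula(paste("value ~", rhs)), data = d,
                       family = stats::poisson())
  } else {
    if (any(d$value <= 0)) stop("gaussian_log requires positive values")
    d$logy <- log(d$value)
    fit <- lme4::lmer(stats::as.formula(paste("logy ~", rhs)), data = d)
  }
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  cn <- names(beta)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  tp_term <- paste0("tp", day_pair[2])
  lvec <- function(g) {
    l <- stats::setNames(numeric(length(cn)), cn)
    l[tp_term] <- 1
    inter <- paste0("group", g, ":", tp_term)
    if (inter %in% cn) l[inter] <- 1
    l
  }
  wald <- function(l) {
    est <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% vc %*% l))
    c(est = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
  }
  per_group <- t(vapply(groups, function(g) wald(lvec(g)), numeric(3)))
  ratios <- data.frame(
    group = groups,
    ratio = exp(per_group[, "est"]),
    lower = exp(per_group[, "est"] - z * per_group[, "se"]),
    upper = exp(per_group[, "est"] + z * per_group[, "se"]),
    p_value = per_group[, "p"], stringsAsFactors = FALSE, row.names = NULL)

  pairs <- if (one_group) list() else utils::combn(groups, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    l <- lvec(pr[2]) - lvec(pr[1])
    w <- wald(l)
    data.frame(contrast = paste(pr[2], "/", pr[1]),
               ratio_of_ratios = exp(w[["est"]]), p_value = w[["p"]],
               stringsAsFactors = FALSE)
  }))

  scores <- if ("dose" %in% colnames(data)) {
    vapply(groups, function(g) data$dose[data$group == g][1], numeric(1))
  } else seq_along(groups)
  polynomial <- NULL
  if (length(groups) >= 3) {
    pc <- polynomial_contrasts(sort(scores))
    ord <- order(scores)
    polynomial <- do.call(rbind, lapply(colnames(pc), function(cnm) {
      l <- Reduce(`+`, Map(function(g, w) w * lvec(g),
                           groups[ord], pc[, cnm]))
      w <- wald(l)
      data.frame(contrast = cnm, estimate = w[["est"]], p_value = w[["p"]],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(ratios = ratios, pairwise = pairwise,
                 polynomial = polynomial, family = family,
                 day_pair = day_pair),
            class = "ratio_contrast")
}
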