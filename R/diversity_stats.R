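# Alpha diversity, compositional (Aitchison) beta diversity and PERMANOVA.
# Shannon, CLR, the distance and the PERMANOVA partition are implemented
# here; only the eigendecomposition behind the PCA is delegated to
# stats::prcomp.

#' Shannon diversity of one sample
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the sample's taxon proportions,
#' natural-log units; zero counts are ignored.
#'
#' @param counts Non-negative numeric vector of one sample's taxon counts
#'   (or proportions).
#' @return H in `[0, ln(richness)]`.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Alpha diversity per sample
#'
#' Shannon index for every sample of a table, optionally after rarefaction
#' to a common depth (the default for count data, so that unequal sequencing
#' depth does not masquerade as diversity differences).
#'
#' @param table An [abundance_table()].
#' @param rarefy_depth Depth for rarefaction; `NULL` = minimum per-sample
#'   total; `NA` = no rarefaction.
#' @param seed Seed for the rarefaction draw.
#' @param subset_label Label recorded in the output (`"all"` or e.g.
#'   `"butyrate_producers"`).
#' @return Data frame: `sample_id`, `metric` (= `"shannon"`), `value`,
#'   `rank`, `subset`.
#' @export
alpha_diversity <- function(table, rarefy_depth = NULL, seed = 1L,
                            subset_label = "all") {
  stopifnot(inherits(table, "abundance_table"))
  tab <- if (length(rarefy_depth) == 1L && is.na(rarefy_depth)) table
         else rarefy(table, depth = rarefy_depth, seed = seed)
  data.frame(sample_id = sample_ids(tab),
             metric = "shannon",
             value = apply(tab$counts, 1, shannon),
             rank = tab$rank,
             subset = subset_label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Centered log-ratio transform
#'
#' Per sample: \eqn{\log(x + c) - \mathrm{mean}(\log(x + c))} with
#' pseudocount c. Rows of the result sum to zero.
#'
#' @param table An [abundance_table()] or a counts matrix (samples x taxa).
#' @param pseudocount Positive constant added to every count before the log;
#'   default 0.5.
#' @return Numeric matrix (samples x taxa) with zero-sum rows.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  m <- if (inherits(table, "abundance_table")) table$counts else table
  if (pseudocount <= 0 && any(m == 0))
    stop("pseudocount must be positive when zeros are present")
  lg <- log(m + pseudocount)
  lg - rowMeans(lg)
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed compositions.
#'
#' @param clr Numeric matrix of CLR rows (samples x taxa), from
#'   [clr_transform()].
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
aitchison_distance <- function(clr) {
  as.matrix(stats::dist(clr, method = "euclidean"))
}

#' Principal-component ordination of CLR data
#'
#' Centered PCA of the CLR matrix. Pairwise Euclidean distances among the
#' full-dimensional coordinates equal the Aitchison distances.
#'
#' @param clr Numeric matrix of CLR rows (samples x taxa).
#' @return List of class `ordination`: `coordinates` (samples x PCs),
#'   `variance_explained` (proportion per PC, non-increasing), `clr` (the
#'   input matrix).
#' @export
pca_ordination <- function(clr) {
  if (nrow(clr) < 2L) stop("ordination needs at least two samples")
  pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x,
                 variance_explained = ve,
                 clr = clr),
            class = "ordination")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: sequential (Type I)
#' partition of the Gower-centered distance matrix by the model terms, with
#' significance assessed by permutation of sample labels (pseudo-F reference
#' distribution). Matches the sequential sums of squares of `vegan::adonis2`.
#'
#' @param dist Square symmetric distance matrix with rownames = sample ids.
#' @param design Data frame of covariates, one row per sample. Rows are
#'   matched to `dist` by a `sample_id` column when present, else by order.
#' @param terms Character vector of term labels, in the order they enter the
#'   model, e.g. `c("diet", "timepoint_day", "diet:timepoint_day")`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional column name in `design`; permutations are then
#'   restricted to shuffles within each stratum (e.g. within cat for
#'   repeated measures).
#' @return Data frame of class `permanova`: per term `df`, `ss`, `r2`,
#'   `pseudo_f`, `p_value`, plus `Residual` and `Total` rows; attributes
#'   `n_perm` and `seed`.
#' @export
permanova <- function(dist, design, terms, n_perm = 999, seed = 1L,
                      strata = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (ncol(d) != n) stop("`dist` must be square")
  if (!is.null(rownames(d)) && "sample_id" %in% colnames(design)) {
    if (!all(rownames(d) %in% design$sample_id))
      stop("design does not cover all samples in `dist`")
    design <- design[match(rownames(d), design$sample_id), , drop = FALSE]
  }
  if (nrow(design) != n) stop("design rows do not match distance matrix")

  # Gower-centered inner-product matrix G = -(1/2) J A J, A = d^2
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)

  # Sequential projections: hat matrix after adding each term
  for (v in colnames(design))
    if (is.character(design[[v]])) design[[v]] <- factor(design[[v]])
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L  # intercept
  for (k in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = " + ")))
    x <- stats::model.matrix(fml, design)
    qx <- qr(x)
    if (qx$rank < ncol(x))
      stop("singular design at term '", terms[k], "'")
    q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(q)
    dfs[k] <- qx$rank - prev_rank
    prev_rank <- qx$rank
  }
  if (any(dfs == 0L))
    stop("singular design: term '", terms[which(dfs == 0L)[1]],
         "' adds no estimable columns")
  df_resid <- n - prev_rank
  if (df_resid <= 0) stop("no residual degrees of freedom")

  ss_total <- sum(diag(g))
  partition <- function(gmat) {
    cum <- vapply(hats, function(h) sum(h * gmat), numeric(1))
    ss <- diff(c(0, cum))
    ss_res <- sum(diag(gmat)) - cum[length(cum)]
    f <- (ss / dfs) / (ss_res / df_resid)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- partition(g)

  exceed <- numeric(length(terms))
  with_preserved_rng(seed, {
    strat <- if (!is.null(strata)) as.factor(design[[strata]]) else NULL
    for (b in seq_len(n_perm)) {
      perm <- permute_indices(n, strat)
      pf <- partition(g[perm, perm])$f
      exceed <- exceed + (pf >= obs$f - 1e-12)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_resid, n - 1L),
    ss = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova", "data.frame")
  out
}

# A label permutation, optionally restricted within strata.
permute_indices <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (lev in levels(strata)) {
    i <- which(strata == lev)
    idx[i] <- i[sample.int(length(i))]
  }
  idx
}
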