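# Compositional preprocessing: proportions, the rare-taxon filter, and
# rarefaction. Filtering precedes any statistics; rarefaction is used for
# alpha diversity only (CLR handles beta diversity without rarefying).

#' Per-sample relative abundance
#'
#' @param table An [abundance_table()].
#' @return A numeric matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- rowSums(table$counts)
  if (any(tot <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(table$counts)[tot <= 0], collapse = ", "))
  sweep(table$counts, 1, tot, "/")
}

#' Remove rare taxa from a count table
#'
#' A taxon is retained when its relative abundance, summarised across samples
#' on the chosen basis, is at least `threshold` (default 1e-5, the study-wide
#' rarity cutoff). The sample set is unchanged. Idempotent for bases `mean`
#' and `max`.
#'
#' @param table An [abundance_table()].
#' @param threshold Proportion in (0, 1).
#' @param basis `"mean"` (default): mean relative abundance across samples;
#'   `"max"`: maximum across samples; `"per_sample"`: retain taxa reaching
#'   the threshold in every sample in which they occur is ill-posed, so this
#'   basis zeroes sub-threshold entries within each sample and then drops
#'   taxa that are zero everywhere.
#' @return A filtered [abundance_table()].
#' @export
filter_rare_taxa <- function(table, threshold = 1e-5,
                             basis = c("mean", "max", "per_sample")) {
  stopifnot(inherits(table, "abundance_table"))
  basis <- match.arg(basis)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly between 0 and 1")
  rel <- relative_abundance(table)
  counts <- table$counts
  if (basis == "per_sample") {
    counts[rel < threshold] <- 0
    keep <- colSums(counts) > 0
  } else {
    stat <- if (basis == "mean") colMeans(rel) else apply(rel, 2, max)
    keep <- stat >= threshold
  }
  if (!any(keep)) stop("all taxa fall below the rarity threshold")
  abundance_table(counts[, keep, drop = FALSE], rank = table$rank)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (multivariate hypergeometric draw). Deterministic given `seed`.
#'
#' @param table An [abundance_table()].
#' @param depth Target reads per sample; default is the minimum per-sample
#'   total. Must not exceed any sample's total.
#' @param seed Integer seed for the subsampling draw.
#' @return A rarefied [abundance_table()] whose rows all sum to `depth`.
#'   Taxa that lose all reads are retained as zero columns so that sample
#'   alignment is preserved.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(tot)
  depth <- as.integer(depth)
  if (depth <= 0) stop("`depth` must be a positive integer")
  low <- tot < depth
  if (any(low))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(rownames(table$counts)[low], collapse = ", "))
  out <- with_preserved_rng(seed, {
    t(apply(table$counts, 1, subsample_counts, depth = depth))
  })
  dimnames(out) <- dimnames(table$counts)
  abundance_table(out, rank = table$rank)
}

# One multivariate hypergeometric draw: depth reads without replacement from
# a vector of per-taxon counts. Sequential conditional rhyper draws, O(k).
subsample_counts <- function(counts, depth) {
  counts <- round(counts)
  k <- length(counts)
  out <- numeric(k)
  remaining <- sum(counts)
  need <- depth
  for (i in seq_len(k)) {
    if (need == 0) break
    ci <- counts[i]
    remaining <- remaining - ci
    if (remaining == 0) { out[i] <- need; need <- 0; break }
    x <- stats::rhyper(1, ci, remaining, need)
    out[i] <- x
    need <- need - x
  }
  out
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
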