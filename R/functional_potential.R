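# Abundance-weighted functional potential: each species present above an
# inclusion threshold contributes its relative abundance to every KO, KEGG
# pathway and CAZy family its genomes carry (presence is binary; no copy
# number). The result is the per-sample accumulated potential per feature.

#' Union of feature sets per species
#'
#' Collapses a genome annotation set to the species level: per species and
#' feature type, the union over its genomes' feature sets.
#'
#' @param annotations A `genome_annotation_set`.
#' @return Named list (by species id, lexicographic) of lists with elements
#'   `KO`, `PATHWAY`, `CAZY` (character vectors, sorted).
#' @export
species_feature_union <- function(annotations) {
  species <- vapply(annotations, `[[`, character(1), "species_id")
  out <- lapply(sort(unique(species)), function(sp) {
    anns <- annotations[species == sp]
    list(
      KO = sort(unique(unlist(lapply(anns, `[[`, "kegg_kos")))),
      PATHWAY = sort(unique(unlist(lapply(anns, `[[`, "kegg_pathways")))),
      CAZY = sort(unique(unlist(lapply(anns, `[[`, "cazy_families")))))
  })
  names(out) <- sort(unique(species))
  out
}

#' Compile abundance-weighted functional potential
#'
#' For every sample, species whose relative abundance in that sample exceeds
#' `inclusion_threshold` contribute that relative abundance to each feature
#' they carry. The threshold is applied per sample (community membership is
#' sample-specific), and weights are the raw relative abundances — no
#' re-closure after the threshold cut. Species without annotations contribute
#' nothing.
#'
#' @param table A species-rank [abundance_table()].
#' @param features Species-to-feature-set mapping from
#'   [species_feature_union()].
#' @param inclusion_threshold Relative-abundance threshold in `[0, 1)`;
#'   default 1e-4.
#' @param feature_types Which feature types to compile.
#' @return Object of class `functional_potential`: list of numeric matrices
#'   (samples x features), one per feature type, values in `[0, 1]`.
#' @export
compile_potential <- function(table, features, inclusion_threshold = 1e-4,
                              feature_types = c("KO", "PATHWAY", "CAZY")) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(inclusion_threshold) || inclusion_threshold < 0 ||
      inclusion_threshold >= 1)
    stop("`inclusion_threshold` must lie in [0, 1)")
  feature_types <- match.arg(feature_types, several.ok = TRUE)
  rel <- relative_abundance(table)
  annotated <- intersect(colnames(rel), names(features))
  out <- lapply(feature_types, function(ty) {
    # species x feature indicator, then weighted matrix product
    feats <- lapply(features[annotated], `[[`, ty)
    universe <- sort(unique(unlist(feats)))
    if (length(universe) == 0L)
      return(matrix(0, nrow = nrow(rel), ncol = 0,
                    dimnames = list(rownames(rel), character())))
    ind <- matrix(0, nrow = length(annotated), ncol = length(universe),
                  dimnames = list(annotated, universe))
    for (sp in annotated) ind[sp, feats[[sp]]] <- 1
    w <- rel[, annotated, drop = FALSE]
    w[w <= inclusion_threshold] <- 0
    w %*% ind
  })
  names(out) <- feature_types
  structure(out, class = "functional_potential")
}

#' Functional potential as a long data frame
#'
#' @param potential A `functional_potential` from [compile_potential()].
#' @return Data frame with columns `sample_id`, `feature_type`, `feature_id`,
#'   `value`, sorted for deterministic output.
#' @export
potential_to_frame <- function(potential) {
  rows <- lapply(names(potential), function(ty) {
    m <- potential[[ty]]
    if (ncol(m) == 0L) return(NULL)
    data.frame(sample_id = rep(rownames(m), times = ncol(m)),
               feature_type = ty,
               feature_id = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_type, out$feature_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
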