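# Rule-based identification of butyrate-producing species from genome
# annotations. Three routes to butyryl-CoA are screened by EC number:
#
#   acetyl-CoA route   2.3.1.9, 2.8.3.5, 1.1.1.35, 1.1.1.36, 1.1.1.157,
#                      1.3.1.86, 1.3.1.44
#                      rule: the two terminal enzymes (1.3.1.86 crotonyl-CoA
#                      reductase, 1.3.1.44 trans-2-enoyl-CoA reductase) must
#                      both be present ("both" default; "either" optional,
#                      since the two ECs catalyse alternative final steps)
#   glutarate route    2.8.3.12, 4.1.1.70           rule: all genes
#   4-aminobutyrate    1.1.1.6, 4.2.1.120, 5.3.3.3  rule: all genes
#
# Terminal-reaction KOs (buk K00929, ptb K00634, atoD K01034) are carried in
# the catalog for the downstream KO-level differential abundance; they play
# no part in species classification.

#' The butyrate pathway catalog
#'
#' Enzyme requirements for the three butyrate-production routes screened in
#' genome annotations, plus the KEGG KOs of the terminal butyrate-forming
#' reactions (butyrate kinase, phosphate butyryltransferase, acetate
#' CoA/acetoacetate CoA-transferase).
#'
#' @return An object of class `butyrate_catalog`: list with `routes` (each a
#'   list of `name`, `ecs` — full EC list — and `rule`, either
#'   `"terminal_pair"` or `"all_genes"`), `terminal_ecs` (the acetyl-CoA
#'   terminal pair) and `terminal_kos` (named KO vector).
#' @export
butyrate_pathway_catalog <- function() {
  structure(list(
    routes = list(
      acetyl_coa = list(
        name = "acetyl_coa",
        ecs = c("2.3.1.9", "2.8.3.5", "1.1.1.35", "1.1.1.36", "1.1.1.157",
                "1.3.1.86", "1.3.1.44"),
        rule = "terminal_pair"),
      glutarate = list(
        name = "glutarate",
        ecs = c("2.8.3.12", "4.1.1.70"),
        rule = "all_genes"),
      aminobutyrate = list(
        name = "aminobutyrate",
        ecs = c("1.1.1.6", "4.2.1.120", "5.3.3.3"),
        rule = "all_genes")),
    terminal_ecs = c("1.3.1.86", "1.3.1.44"),
    terminal_kos = c(buk = "K00929", ptb = "K00634", atoD = "K01034")),
    class = "butyrate_catalog")
}

#' Catalog as a serialisable data frame
#'
#' @param catalog A [butyrate_pathway_catalog()].
#' @return Data frame with columns `route`, `ec`, `rule`.
#' @export
catalog_to_frame <- function(catalog = butyrate_pathway_catalog()) {
  do.call(rbind, lapply(catalog$routes, function(r)
    data.frame(route = r$name, ec = r$ecs, rule = r$rule,
               stringsAsFactors = FALSE, row.names = NULL)))
}

#' Classify one genome's butyrate routes
#'
#' @param annotation A `genome_annotation` record.
#' @param catalog A [butyrate_pathway_catalog()].
#' @param acetyl_rule `"both"` (default): both terminal enzymes 1.3.1.86 and
#'   1.3.1.44 are required for the acetyl-CoA route; `"either"`: one
#'   suffices.
#' @return Named logical vector over routes
#'   (`acetyl_coa`, `glutarate`, `aminobutyrate`).
#' @export
classify_genome <- function(annotation, catalog = butyrate_pathway_catalog(),
                            acetyl_rule = c("both", "either")) {
  acetyl_rule <- match.arg(acetyl_rule)
  ecs <- annotation$ec_numbers
  vapply(catalog$routes, function(r) {
    if (r$rule == "terminal_pair") {
      hit <- catalog$terminal_ecs %in% ecs
      if (acetyl_rule == "both") all(hit) else any(hit)
    } else {
      all(r$ecs %in% ecs)
    }
  }, logical(1))
}

#' Classify species as butyrate producers
#'
#' A species' route flag is the OR over the flags of all genomes assigned to
#' it: any genome carrying a complete route lifts the whole species.
#' Likelihood is `"high"` when at least one route is complete, otherwise
#' `"none"`.
#'
#' @param annotations A `genome_annotation_set`
#'   (see [read_genome_annotations()]).
#' @param catalog A [butyrate_pathway_catalog()].
#' @param acetyl_rule Passed to [classify_genome()].
#' @return Data frame (class `butyrate_calls`) with one row per species:
#'   `species_id`, logical `acetyl_coa`, `glutarate`, `aminobutyrate`,
#'   `likelihood` (`high`/`none`), `supporting_genomes` (comma-joined ids of
#'   the genomes with at least one complete route; empty when none).
#' @export
classify_species <- function(annotations, catalog = butyrate_pathway_catalog(),
                             acetyl_rule = "both") {
  if (length(annotations) == 0L)
    return(structure(
      data.frame(species_id = character(), acetyl_coa = logical(),
                 glutarate = logical(), aminobutyrate = logical(),
                 likelihood = character(), supporting_genomes = character(),
                 stringsAsFactors = FALSE),
      class = c("butyrate_calls", "data.frame")))
  flags <- t(vapply(annotations, classify_genome, logical(3),
                    catalog = catalog, acetyl_rule = acetyl_rule))
  species <- vapply(annotations, `[[`, character(1), "species_id")
  genome <- vapply(annotations, `[[`, character(1), "genome_id")
  # duplicate genome records must not change the call: collapse first
  dup <- duplicated(genome)
  flags <- flags[!dup, , drop = FALSE]
  species <- species[!dup]
  genome <- genome[!dup]
  out <- do.call(rbind, lapply(sort(unique(species)), function(sp) {
    i <- species == sp
    f <- apply(flags[i, , drop = FALSE], 2, any)
    supp <- genome[i][rowSums(flags[i, , drop = FALSE]) > 0]
    data.frame(species_id = sp,
               acetyl_coa = f[["acetyl_coa"]],
               glutarate = f[["glutarate"]],
               aminobutyrate = f[["aminobutyrate"]],
               likelihood = if (any(f)) "high" else "none",
               supporting_genomes = paste(sort(supp), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("butyrate_calls", "data.frame"))
}

#' Restrict an abundance table to butyrate producers
#'
#' Taxa without a call are treated as likelihood `"none"`.
#'
#' @param table A species-rank [abundance_table()].
#' @param calls A `butyrate_calls` frame from [classify_species()].
#' @return The table restricted to species called `"high"`; sample set
#'   unchanged.
#' @export
producer_subset <- function(table, calls) {
  stopifnot(inherits(table, "abundance_table"))
  high <- calls$species_id[calls$likelihood == "high"]
  keep <- intersect(taxon_ids(table), high)
  if (length(keep) == 0L)
    stop("no butyrate producers present in the abundance table")
  abundance_table(table$counts[, keep, drop = FALSE], rank = table$rank)
}
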