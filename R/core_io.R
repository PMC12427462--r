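# Shared domain containers and tabular IO.
#
# All tables are tab-separated UTF-8 with a header row. The central object is
# the abundance table: a samples x taxa matrix of non-negative integer counts
# with a taxonomic rank label. Canonical ordering of both samples and taxa is
# lexicographic, so parses and writes are deterministic.

VALID_RANKS <- c("species", "genus", "family", "phylum")

#' Construct and validate an abundance table
#'
#' A samples x taxa matrix of non-negative integer read counts at a single
#' taxonomic rank, the central object of the pipeline. Rows are samples,
#' columns are taxa; both are sorted lexicographically by id on construction
#' so that downstream output is deterministic.
#'
#' @param counts Numeric matrix (samples x taxa) of non-negative integers with
#'   rownames (sample ids) and colnames (taxon ids).
#' @param rank Taxonomic rank label, one of `"species"`, `"genus"`,
#'   `"family"`, `"phylum"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer-valued matrix), `rank`, and accessors via
#'   [sample_ids()] and [taxon_ids()].
#' @examples
#' m <- matrix(c(5, 0, 1, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' tab <- abundance_table(m, rank = "species")
#' rowSums(tab$counts)
#' @export
abundance_table <- function(counts, rank = "species") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry sample ids as rownames and taxon ids as colnames")
  rank <- match.arg(rank, VALID_RANKS)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts))
    stop("missing values are not permitted in count tables")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total counts: ",
         paste(rownames(counts)[tot <= 0], collapse = ", "))
  counts <- counts[order(rownames(counts)), order(colnames(counts)), drop = FALSE]
  storage.mode(counts) <- "double"
  structure(list(counts = counts, rank = rank), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d %s, total reads %s\n",
              nrow(x$counts), ncol(x$counts), x$rank,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname abundance_table
#' @param x An `abundance_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname abundance_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' Read an abundance table from TSV
#'
#' Supports three dialects:
#' \describe{
#'   \item{`wide`}{first column = sample id, remaining columns = taxa counts.}
#'   \item{`long`}{columns `sample_id`, `taxon_id`, `count`; missing
#'     (sample, taxon) pairs are zeros.}
#'   \item{`bracken`}{Bracken report columns `name`, `taxonomy_id`,
#'     `taxonomy_lvl`, `new_est_reads`, `fraction_total_reads`, plus a
#'     `sample_id` column when several per-sample reports are merged into one
#'     file. `new_est_reads` is the count; `fraction_total_reads` is ignored
#'     and recomputable from counts.}
#' }
#' Duplicate (sample, taxon) pairs are an error; rows are accepted in any
#' order and canonicalised lexicographically.
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"wide"`, `"long"`, `"bracken"`.
#' @param rank Taxonomic rank label for the resulting table.
#' @param sample_id Sample id to use for a single-sample Bracken report that
#'   lacks a `sample_id` column.
#' @return A validated [abundance_table()].
#' @export
read_abundance_table <- function(path, dialect = c("wide", "long", "bracken"),
                                 rank = "species", sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  long <- switch(dialect,
    wide = {
      samples <- as.character(df[[1]])
      taxa <- colnames(df)[-1]
      data.frame(
        sample_id = rep(samples, times = length(taxa)),
        taxon_id = rep(taxa, each = nrow(df)),
        count = unlist(df[-1], use.names = FALSE),
        stringsAsFactors = FALSE)
    },
    long = {
      need <- c("sample_id", "taxon_id", "count")
      if (!all(need %in% colnames(df)))
        stop("long dialect requires columns: ", paste(need, collapse = ", "))
      df[need]
    },
    bracken = {
      need <- c("name", "new_est_reads")
      if (!all(need %in% colnames(df)))
        stop("bracken dialect requires columns: ", paste(need, collapse = ", "))
      sid <- if ("sample_id" %in% colnames(df)) as.character(df$sample_id)
             else if (!is.null(sample_id)) rep(sample_id, nrow(df))
             else stop("bracken report lacks a sample_id column; supply `sample_id`")
      data.frame(sample_id = sid, taxon_id = as.character(df$name),
                 count = df$new_est_reads, stringsAsFactors = FALSE)
    })
  long_to_abundance(long, rank = rank)
}

# long (sample_id, taxon_id, count) -> abundance_table
long_to_abundance <- function(long, rank = "species") {
  if (anyNA(long$count)) stop("missing counts are not permitted")
  neg <- long$count < 0
  if (any(neg))
    stop(sprintf("negative count for sample '%s', taxon '%s'",
                 long$sample_id[neg][1], long$taxon_id[neg][1]))
  key <- paste(long$sample_id, long$taxon_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate entry for sample '%s', taxon '%s'",
                 d$sample_id[1], d$taxon_id[1]))
  }
  samples <- sort(unique(long$sample_id))
  taxa <- sort(unique(long$taxon_id))
  m <- matrix(0, nrow = length(samples), ncol = length(taxa),
              dimnames = list(samples, taxa))
  m[cbind(match(long$sample_id, samples), match(long$taxon_id, taxa))] <- long$count
  abundance_table(m, rank = rank)
}

#' Read genome annotations from TSV
#'
#' Expects columns `genome_id`, `species_id`, `feature_type`, `feature_id`,
#' with `feature_type` one of `EC`, `KO`, `PATHWAY`, `CAZY`. Duplicate feature
#' rows collapse (set semantics). A genome assigned to two species is an
#' error. Genomes with no feature rows may be declared with an empty
#' `feature_id` (features for that row are ignored).
#'
#' @param path Path to a TSV file.
#' @return A `genome_annotation_set`: a named list (one entry per genome, in
#'   lexicographic genome id order) of `genome_annotation` records with
#'   fields `genome_id`, `species_id`, `ec_numbers`, `kegg_kos`,
#'   `kegg_pathways`, `cazy_families`.
#' @export
read_genome_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species_id", "feature_type", "feature_id")
  if (!all(need %in% colnames(df)))
    stop("annotation table requires columns: ", paste(need, collapse = ", "))
  annotations_from_frame(df)
}

#' Build a genome annotation set from a long data frame
#'
#' @param df Data frame with columns `genome_id`, `species_id`,
#'   `feature_type` (`EC`/`KO`/`PATHWAY`/`CAZY`), `feature_id`.
#' @return A `genome_annotation_set` (see [read_genome_annotations()]).
#' @export
annotations_from_frame <- function(df) {
  types <- c("EC", "KO", "PATHWAY", "CAZY")
  bad <- setdiff(unique(df$feature_type), types)
  if (length(bad)) stop("unknown feature_type: ", paste(bad, collapse = ", "))
  if (any(!nzchar(df$species_id) | is.na(df$species_id)))
    stop("species_id must be nonempty")
  sp_per_genome <- tapply(df$species_id, df$genome_id,
                          function(s) length(unique(s)))
  if (any(sp_per_genome > 1))
    stop("genome(s) assigned to multiple species: ",
         paste(names(sp_per_genome)[sp_per_genome > 1], collapse = ", "))
  genomes <- sort(unique(df$genome_id))
  out <- lapply(genomes, function(g) {
    rows <- df[df$genome_id == g, , drop = FALSE]
    feat <- function(ty) {
      v <- rows$feature_id[rows$feature_type == ty]
      sort(unique(v[nzchar(v) & !is.na(v)]))
    }
    structure(list(genome_id = g,
                   species_id = rows$species_id[1],
                   ec_numbers = feat("EC"),
                   kegg_kos = feat("KO"),
                   kegg_pathways = feat("PATHWAY"),
                   cazy_families = feat("CAZY")),
              class = "genome_annotation")
  })
  names(out) <- genomes
  structure(out, class = "genome_annotation_set")
}

#' Convert a genome annotation set to a long data frame
#'
#' Inverse of [annotations_from_frame()]; used by [write_result_table()]
#' round trips.
#' @param anns A `genome_annotation_set`.
#' @return Data frame with columns `genome_id`, `species_id`, `feature_type`,
#'   `feature_id`.
#' @export
annotations_to_frame <- function(anns) {
  rows <- lapply(anns, function(a) {
    f <- rbind(
      if (length(a$ec_numbers)) data.frame(feature_type = "EC", feature_id = a$ec_numbers),
      if (length(a$kegg_kos)) data.frame(feature_type = "KO", feature_id = a$kegg_kos),
      if (length(a$kegg_pathways)) data.frame(feature_type = "PATHWAY", feature_id = a$kegg_pathways),
      if (length(a$cazy_families)) data.frame(feature_type = "CAZY", feature_id = a$cazy_families))
    if (is.null(f)) return(NULL)
    data.frame(genome_id = a$genome_id, species_id = a$species_id, f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate trial design metadata
#'
#' The design binds every longitudinal analysis: one row per (cat, timepoint)
#' with diet arm, SCFP dose, sex, body weight and the fecal sample id taken
#' at that visit.
#'
#' @param design Data frame with columns `cat_id`, `sex` (`F`/`M`), `diet`
#'   (`CD`/`T150`/`T300`), `dose_mg_per_kg` (0/150/300), `timepoint_day`
#'   (0/21/42), `body_weight_kg`, `sample_id`.
#' @return The design, invisibly, with factors normalised; errors describe
#'   the first violated invariant.
#' @export
validate_trial_design <- function(design) {
  need <- c("cat_id", "sex", "diet", "dose_mg_per_kg", "timepoint_day",
            "body_weight_kg", "sample_id")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  if (!all(design$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!all(design$diet %in% c("CD", "T150", "T300")))
    stop("diet must be CD, T150 or T300")
  if (!all(design$dose_mg_per_kg %in% c(0, 150, 300)))
    stop("dose must be 0, 150 or 300 mg/kg")
  if (!all(design$timepoint_day %in% c(0, 21, 42)))
    stop("timepoint_day must be 0, 21 or 42")
  if (any(design$body_weight_kg <= 0)) stop("body weight must be positive")
  if (anyDuplicated(design[c("cat_id", "timepoint_day")]))
    stop("duplicate (cat_id, timepoint_day) rows")
  if (anyDuplicated(design$sample_id[!is.na(design$sample_id)]))
    stop("a sample_id maps to more than one design row")
  diets <- tapply(design$diet, design$cat_id, function(d) length(unique(d)))
  if (any(diets > 1))
    stop("diet changes within cat: ",
         paste(names(diets)[diets > 1], collapse = ", "))
  invisible(design)
}

#' Validate palatability records
#'
#' One row per cat per test day of a two-bowl test: grams consumed from each
#' bowl and the diet approached first (`"none"` marks an abstention).
#'
#' @param records Data frame with columns `cat_id`, `day` (1/2), `diet_a`,
#'   `diet_b`, `grams_a`, `grams_b`, `first_choice`.
#' @param offered_g Grams offered per bowl (consumption upper bound).
#' @return The records, invisibly.
#' @export
validate_palatability <- function(records, offered_g = 100) {
  need <- c("cat_id", "day", "diet_a", "diet_b", "grams_a", "grams_b",
            "first_choice")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (!all(records$day %in% c(1, 2))) stop("day must be 1 or 2")
  if (any(records$grams_a < 0 | records$grams_b < 0))
    stop("negative consumption")
  if (any(records$grams_a > offered_g | records$grams_b > offered_g))
    stop("consumption exceeds offered amount (", offered_g, " g)")
  ok <- records$first_choice == records$diet_a |
    records$first_choice == records$diet_b |
    records$first_choice == "none"
  if (!all(ok)) stop("first_choice must be one of the two diets or 'none'")
  invisible(records)
}

#' Validate digestibility records
#'
#' @param records Data frame with columns `cat_id`, `nutrient`,
#'   `intake_g_per_day` (> 0), `fecal_output_g_per_day` (>= 0).
#' @return The records, invisibly.
#' @export
validate_digestibility <- function(records) {
  need <- c("cat_id", "nutrient", "intake_g_per_day", "fecal_output_g_per_day")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (any(records$intake_g_per_day <= 0)) stop("intake must be strictly positive")
  if (any(records$fecal_output_g_per_day < 0)) stop("fecal output must be >= 0")
  invisible(records)
}

#' Write a result table as deterministic TSV
#'
#' Plain tab-separated output with a header row, no quoting of numerics, and
#' stable column order; two writes of the same table are byte-identical.
#'
#' @param table Non-empty data frame, or an [abundance_table()] (written in
#'   long dialect).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  if (inherits(table, "abundance_table")) {
    m <- table$counts
    table <- data.frame(
      sample_id = rep(rownames(m), times = ncol(m)),
      taxon_id = rep(colnames(m), each = nrow(m)),
      count = as.vector(m), stringsAsFactors = FALSE)
    table <- table[order(table$sample_id, table$taxon_id), , drop = FALSE]
  }
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("refusing to write an empty table")
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
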