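# Fixture builders shared across test files; everything is generated in
# code so the suite carries no data files.

toy_counts <- function(values = c(5, 0, 1, 3), nrow = 2,
                       samples = sprintf("s%d", seq_len(nrow)),
                       taxa = sprintf("tax%s", LETTERS[seq_len(length(values) / nrow)])) {
  matrix(values, nrow = nrow, byrow = TRUE,
         dimnames = list(samples, taxa))
}

toy_table <- function(...) abundance_table(toy_counts(...), rank = "species")

# annotation frame for one genome with the given EC numbers
ec_genome <- function(genome, species, ecs) {
  data.frame(genome_id = genome, species_id = species,
             feature_type = "EC", feature_id = ecs,
             stringsAsFactors = FALSE)
}

random_annotation_frame <- function(n_species, max_genomes = 3,
                                    ec_pool = all_catalog_ecs()) {
  rows <- list()
  gi <- 0
  for (s in seq_len(n_species)) {
    for (g in seq_len(sample(max_genomes, 1))) {
      gi <- gi + 1
      ecs <- sample(ec_pool, sample(0:length(ec_pool), 1))
      if (length(ecs) == 0) ecs <- ""
      rows[[gi]] <- ec_genome(sprintf("g%03d", gi), sprintf("sp%02d", s), ecs)
    }
  }
  do.call(rbind, rows)
}

all_catalog_ecs <- function() {
  cat <- butyrate_pathway_catalog()
  unique(unlist(lapply(cat$routes, `[[`, "ecs")))
}

# Independent brute-force oracle for the species-level butyrate call:
# literal re-statement of the rules, one explicit loop per genome.
oracle_species_calls <- function(frame, acetyl_rule = "both") {
  species <- unique(frame$species_id)
  out <- lapply(species, function(sp) {
    genomes <- unique(frame$genome_id[frame$species_id == sp])
    flags <- c(acetyl_coa = FALSE, glutarate = FALSE, aminobutyrate = FALSE)
    for (g in genomes) {
      ecs <- frame$feature_id[frame$genome_id == g & frame$feature_type == "EC"]
      has <- function(e) e %in% ecs
      ac <- if (acetyl_rule == "both") has("1.3.1.86") && has("1.3.1.44")
            else has("1.3.1.86") || has("1.3.1.44")
      gl <- has("2.8.3.12") && has("4.1.1.70")
      am <- has("1.1.1.6") && has("4.2.1.120") && has("5.3.3.3")
      flags <- flags | c(acetyl_coa = ac, glutarate = gl, aminobutyrate = am)
    }
    data.frame(species_id = sp, acetyl_coa = flags[["acetyl_coa"]],
               glutarate = flags[["glutarate"]],
               aminobutyrate = flags[["aminobutyrate"]],
               likelihood = if (any(flags)) "high" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$species_id), , drop = FALSE]
}

# Independent brute-force BH step-up oracle (literal definition).
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    k <- which(ord == i)  # rank of p[i]
    q[i] <- min(vapply(k:n, function(m) p[ord[m]] * n / m, numeric(1)), 1)
  }
  q
}

tiny_design <- function(n_cats_per_arm = 4) {
  scfptrial:::null_design(n_cats_per_arm)
}
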