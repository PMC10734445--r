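# Seeded generators for every input the pipeline consumes, with planted
# ground truth: annotation tables from a planted trait matrix, BGC
# records with known siderophore types, genome sequence pairs at target
# identity, read-count tables with a dominant host, and peptide tables
# with planted mapping fractions. At zero noise every downstream module
# must reproduce the planted truth exactly.

#' Simulation configuration
#'
#' Defaults emulate the structure of a Trichodesmium consortium data set:
#' 52 genomes, one dominant diazotroph host receiving ~71% of reads
#' (with +/-6 percentage-point between-sample jitter), three samples, and
#' a configurable planted trait matrix.
#'
#' @param n_genomes Number of genomes (genome 1 is the host).
#' @param n_samples Number of read-count samples.
#' @param host_fraction Target read fraction of genome 1.
#' @param host_jitter_sd Between-sample sd of the host fraction.
#' @param total_reads Reads per sample.
#' @param dropout_rate Probability that a truly present gene is omitted
#'   from the annotation (annotation noise), in [0, 1].
#' @param decoy_rate Expected number of decoy KEGG ids per genome
#'   (ids outside every catalog module).
#' @param trait_truth Optional planted status matrix (genomes x traits,
#'   values `present`/`putative`/`absent`). When `NULL`, statuses are
#'   sampled per trait with `prevalence`/`putative_prevalence`.
#' @param prevalence Probability of planting `present` for a trait.
#' @param putative_prevalence Probability of planting `putative` (applied
#'   only where a putative call is achievable for the trait).
#' @param seed Mandatory integer seed; every generator derives its stream
#'   from it.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_genomes = 52, n_samples = 3, host_fraction = 0.71,
                       host_jitter_sd = 0.06, total_reads = 200000,
                       dropout_rate = 0, decoy_rate = 0,
                       trait_truth = NULL, prevalence = 0.35,
                       putative_prevalence = 0.05, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop_fmt("a seed is mandatory for reproducible simulation")
  for (r in c(dropout_rate, decoy_rate))
    if (r < 0) stop_fmt("rates must be non-negative")
  if (dropout_rate > 1) stop_fmt("dropout_rate must lie in [0, 1]")
  if (host_fraction <= 0 || host_fraction >= 1)
    stop_fmt("host_fraction must lie in (0, 1)")
  structure(
    list(n_genomes = as.integer(n_genomes), n_samples = as.integer(n_samples),
         host_fraction = host_fraction, host_jitter_sd = host_jitter_sd,
         total_reads = as.integer(total_reads),
         dropout_rate = dropout_rate, decoy_rate = decoy_rate,
         trait_truth = trait_truth, prevalence = prevalence,
         putative_prevalence = putative_prevalence,
         seed = as.integer(seed)),
    class = "sim_config")
}

sim_genome_ids <- function(n) sprintf("MAG_%02d", seq_len(n))

# Largest distinct-gene count that stays strictly below the threshold.
max_below_threshold <- function(trait) {
  m <- length(module_denominator(trait))
  as.integer(ceiling(trait$completeness_threshold * m - 1e-9) - 1)
}

# Can a putative status be planted for this trait?
putative_achievable <- function(trait) {
  m <- length(trait$module_genes)
  if (length(trait$marker_genes) > 0 && m > 1 &&
      (m - 1) / m >= trait$completeness_threshold) return(TRUE)
  if (length(trait$pfam_markers) > 0 && m > 0) return(TRUE)
  if (trait$report_partial && max_below_threshold(trait) >= 1) return(TRUE)
  FALSE
}

# Functional ids (KEGG + PFAM) to emit for one planted status.
planted_trait_ids <- function(trait, status) {
  kegg <- trait$module_genes
  pfam <- trait$pfam_markers
  if (status == "present") return(list(kegg = kegg, pfam = pfam))
  if (status == "putative") {
    m <- length(kegg)
    if (length(trait$marker_genes) > 0 && m > 1 &&
        (m - 1) / m >= trait$completeness_threshold) {
      drop <- sample(trait$marker_genes, 1)
      return(list(kegg = setdiff(kegg, drop), pfam = pfam))
    }
    if (length(pfam) > 0 && m > 0)
      return(list(kegg = kegg, pfam = character(0)))
    if (trait$report_partial) {
      smax <- max_below_threshold(trait)
      size <- sample.int(smax, 1)
      return(list(kegg = sample(kegg, size), pfam = character(0)))
    }
    stop_fmt("putative status is not achievable for trait '%s'",
             trait$trait_id)
  }
  # absent: a random strictly-below-threshold subset (possibly empty);
  # report_partial traits must stay empty or they would read as putative
  smax <- if (trait$report_partial) 0L else max_below_threshold(trait)
  size <- if (smax > 0L) sample.int(smax + 1L, 1) - 1L else 0L
  denom <- module_denominator(trait)
  pick <- if (size > 0L) sample(denom, size) else character(0)
  list(kegg = intersect(pick, kegg), pfam = intersect(pick, pfam))
}

sample_truth_matrix <- function(config, catalog) {
  gids <- sim_genome_ids(config$n_genomes)
  tids <- names(catalog)
  truth <- matrix("absent", length(gids), length(tids),
                  dimnames = list(gids, tids))
  for (tr in tids) {
    p_put <- if (putative_achievable(catalog[[tr]]))
      config$putative_prevalence else 0
    probs <- c(config$prevalence, p_put,
               1 - config$prevalence - p_put)
    truth[, tr] <- sample(trait_statuses(), length(gids), replace = TRUE,
                          prob = probs)
  }
  truth
}

#' Generate genome annotations from a planted trait matrix
#'
#' For each planted-present trait all module genes (and PFAM markers) are
#' emitted; planted-putative traits emit an above-threshold gene set
#' missing one marker; planted-absent traits emit a random strictly
#' below-threshold subset (possibly empty). Per-gene dropout and decoy
#' KEGG ids (drawn from outside every catalog module) model annotation
#' noise. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param catalog Trait catalog (default bundled). Generation requires the
#'   catalog's trait gene sets to be pairwise disjoint, which holds for
#'   the bundled catalog.
#' @param dir Optional output directory; when given, `annotations.tsv` and
#'   `trait_truth.tsv` are written there.
#' @return List with `annotations` (named list of [genome_annotation()]),
#'   `truth` (status matrix) and `config`.
#' @export
generate_annotations <- function(config, catalog = default_catalog(),
                                 dir = NULL) {
  set.seed(config$seed)
  gids <- sim_genome_ids(config$n_genomes)
  truth <- config$trait_truth
  if (is.null(truth)) {
    truth <- sample_truth_matrix(config, catalog)
  } else {
    truth <- as.matrix(truth)
    if (is.null(rownames(truth))) rownames(truth) <- gids
    unknown <- setdiff(colnames(truth), names(catalog))
    if (length(unknown) > 0)
      stop_fmt("trait_truth references unknown trait(s): %s",
               paste(unknown, collapse = ", "))
    assert_status(as.vector(truth), "trait_truth")
    full <- matrix("absent", length(gids), length(catalog),
                   dimnames = list(gids, names(catalog)))
    full[rownames(truth), colnames(truth)] <- truth
    truth <- full
  }

  all_catalog_ids <- unique(unlist(lapply(catalog, trait_id_universe)))
  decoy_pool <- setdiff(sprintf("K99%03d", 0:999), all_catalog_ids)

  annotations <- vector("list", length(gids))
  for (i in seq_along(gids)) {
    kegg <- character(0); pfam <- character(0)
    for (tr in names(catalog)) {
      ids <- planted_trait_ids(catalog[[tr]], truth[i, tr])
      kegg <- c(kegg, ids$kegg)
      pfam <- c(pfam, ids$pfam)
    }
    if (config$dropout_rate > 0) {
      kegg <- kegg[stats::runif(length(kegg)) >= config$dropout_rate]
      pfam <- pfam[stats::runif(length(pfam)) >= config$dropout_rate]
    }
    if (config$decoy_rate > 0) {
      n_decoy <- stats::rpois(1, config$decoy_rate)
      if (n_decoy > 0)
        kegg <- c(kegg, sample(decoy_pool, min(n_decoy, length(decoy_pool))))
    }
    n_genes <- length(kegg) + length(pfam)
    starts <- 1L + (seq_len(n_genes) - 1L) * 1000L
    genes <- if (n_genes == 0) empty_gene_table() else data.frame(
      gene_id = sprintf("%s_g%04d", gids[i], seq_len(n_genes)),
      contig = "contig_1",
      start = starts, end = starts + 899L,
      strand = rep(c("+", "-"), length.out = max(n_genes, 1))[seq_len(n_genes)],
      kegg_ids = c(kegg, rep("", length(pfam))),
      pfam_ids = c(rep("", length(kegg)), pfam),
      stringsAsFactors = FALSE)
    annotations[[i]] <- genome_annotation(
      gids[i], genes,
      completeness_pct = 95, redundancy_pct = if (i == 1) 1 else 3)
  }
  names(annotations) <- gids

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_annotations(annotations, file.path(dir, "annotations.tsv"))
    write_truth_matrix(truth, file.path(dir, "trait_truth.tsv"))
  }
  list(annotations = annotations, truth = truth, config = config)
}

write_truth_matrix <- function(truth, path) {
  df <- data.frame(genome_id = rownames(truth), stringsAsFactors = FALSE)
  for (tr in colnames(truth)) df[[tr]] <- unname(STATUS_CODE[truth[, tr]])
  write_tsv(df, path)
}

read_truth_matrix <- function(path) {
  df <- read_tsv(path)
  truth <- as.matrix(df[, setdiff(names(df), "genome_id"), drop = FALSE])
  truth[] <- CODE_STATUS[truth]
  rownames(truth) <- df$genome_id
  truth
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_aa <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate BGC records with planted siderophore truth
#'
#' Plants NIS clusters (PF04183-bearing genes plus a synthetase sequence
#' mutated from a panel reference at `mutation_rate`), putative NRPS
#' siderophore clusters (receptor tag co-located), plain NRPS clusters
#' (no receptor) and non-siderophore clusters, distributed over the
#' non-host genomes.
#'
#' @param config A [sim_config()].
#' @param panel NIS reference panel (default bundled).
#' @param n_nis,n_nrps_siderophore,n_nrps_plain,n_other Cluster counts
#'   (defaults 4/6/2/2, matching the reported repertoire structure).
#' @param mutation_rate Amino-acid substitution rate applied to the panel
#'   sequence of each planted NIS cluster.
#' @param dir Optional output directory (`bgcs.json`, `bgc_truth.tsv`).
#' @return List with `bgcs`, `truth` (data.frame cluster_id, genome_id,
#'   kind, reference) and `config`.
#' @export
generate_bgcs <- function(config, panel = nis_reference_panel(),
                          n_nis = 4, n_nrps_siderophore = 6,
                          n_nrps_plain = 2, n_other = 2,
                          mutation_rate = 0.1, dir = NULL) {
  set.seed(config$seed + 1L)
  gids <- sim_genome_ids(config$n_genomes)
  hosts <- gids[-1]  # the host carries no known siderophore BGC
  n_total <- n_nis + n_nrps_siderophore + n_nrps_plain + n_other
  carriers <- sample(hosts, n_total, replace = n_total > length(hosts))
  bgcs <- list(); truth <- list()
  idx <- 0L
  mk_cluster <- function(genome, kind, ref_row = NULL) {
    idx <<- idx + 1L
    cid <- sprintf("BGC_%03d", idx)
    genes <- list()
    synth <- NULL
    cls <- switch(kind, NIS = "NIS", NRPS_putative = "NRPS",
                  NRPS_plain = "NRPS", other = "other")
    if (kind == "NIS") {
      n_iuc <- sample(1:2, 1)
      for (g in seq_len(n_iuc))
        genes[[g]] <- list(gene_id = sprintf("%s_iuc%d", cid, g),
                           start = 100L + (g - 1L) * 1500L,
                           end = 1400L + (g - 1L) * 1500L,
                           pf04183_count = 1L, tags = character(0))
      synth <- mutate_aa(ref_row$sequence, mutation_rate)
    } else {
      for (g in 1:2)
        genes[[g]] <- list(gene_id = sprintf("%s_nrps%d", cid, g),
                           start = 100L + (g - 1L) * 1500L,
                           end = 1400L + (g - 1L) * 1500L,
                           pf04183_count = 0L, tags = character(0))
      if (kind == "NRPS_putative")
        genes[[3]] <- list(gene_id = sprintf("%s_rec", cid),
                           start = 3200L, end = 4000L, pf04183_count = 0L,
                           tags = "TBDT_siderophore_receptor")
    }
    bgc <- bgc_record(genome, cid, "contig_1", 1L, 10000L, cls, genes,
                      synthetase_sequence = synth)
    truth[[idx]] <<- data.frame(
      cluster_id = cid, genome_id = genome,
      kind = if (kind == "NRPS_plain" || kind == "other") "none" else kind,
      reference = if (kind == "NIS") ref_row$name else NA_character_,
      stringsAsFactors = FALSE)
    bgc
  }
  k <- 0L
  for (i in seq_len(n_nis)) {
    k <- k + 1L
    ref <- panel[((i - 1L) %% nrow(panel)) + 1L, ]
    bgcs[[k]] <- mk_cluster(carriers[k], "NIS", ref)
  }
  for (i in seq_len(n_nrps_siderophore)) {
    k <- k + 1L; bgcs[[k]] <- mk_cluster(carriers[k], "NRPS_putative")
  }
  for (i in seq_len(n_nrps_plain)) {
    k <- k + 1L; bgcs[[k]] <- mk_cluster(carriers[k], "NRPS_plain")
  }
  for (i in seq_len(n_other)) {
    k <- k + 1L; bgcs[[k]] <- mk_cluster(carriers[k], "other")
  }
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bgc_json(bgcs, file.path(dir, "bgcs.json"))
    write_tsv(truth, file.path(dir, "bgc_truth.tsv"))
  }
  list(bgcs = bgcs, truth = truth, config = config)
}

#' Generate genome sequence pairs at target identity
#'
#' Each pair is a random DNA sequence plus a copy mutated by uniform
#' substitution at rate 1 - identity; the realized per-site identity is
#' returned as truth (the oracle for ANI estimation).
#'
#' @param pairs data.frame with `name_a`, `name_b`, `identity` (fractions
#'   in (0, 1]).
#' @param seed Integer seed.
#' @param length Sequence length in bases (default 20000).
#' @return List with `seqs_a`, `seqs_b` (named character vectors) and
#'   `truth` (pairs plus `realized_identity_pct`).
#' @export
generate_sequences <- function(pairs, seed, length = 20000) {
  if (any(pairs$identity <= 0 | pairs$identity > 1))
    stop_fmt("target identity must lie in (0, 1]")
  set.seed(seed)
  seqs_a <- character(nrow(pairs)); seqs_b <- character(nrow(pairs))
  realized <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- random_dna(length)
    b <- mutate_dna(a, 1 - pairs$identity[i])
    seqs_a[i] <- a; seqs_b[i] <- b
    realized[i] <- 100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  truth <- pairs
  truth$realized_identity_pct <- realized
  list(seqs_a = stats::setNames(seqs_a, pairs$name_a),
       seqs_b = stats::setNames(seqs_b, pairs$name_b),
       truth = truth)
}

#' Generate a sample-by-genome read-count table
#'
#' The host genome draws `host_fraction` of reads per sample (with
#' Gaussian between-sample jitter); the remainder is split over the other
#' genomes by a symmetric Dirichlet. Counts are multinomial draws of
#' `total_reads`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (`counts.tsv`, `count_truth.tsv`).
#' @return List with `counts` (data.frame), `truth` (intended per-sample
#'   host fractions) and `config`.
#' @export
generate_counts <- function(config, dir = NULL) {
  set.seed(config$seed + 2L)
  gids <- sim_genome_ids(config$n_genomes)
  rows <- list(); host_f <- numeric(config$n_samples)
  for (s in seq_len(config$n_samples)) {
    f <- stats::rnorm(1, config$host_fraction, config$host_jitter_sd)
    f <- min(max(f, 0.05), 0.95)
    host_f[s] <- f
    w <- stats::rgamma(config$n_genomes - 1L, shape = 1)
    probs <- c(f, (1 - f) * w / sum(w))
    counts <- as.vector(stats::rmultinom(1, config$total_reads, probs))
    rows[[s]] <- c(list(sample = sprintf("sample_%d", s)),
                   stats::setNames(as.list(counts), gids))
  }
  counts <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  truth <- data.frame(sample = counts$sample, host_fraction = host_f,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(counts, file.path(dir, "counts.tsv"))
    write_tsv(truth, file.path(dir, "count_truth.tsv"))
  }
  list(counts = counts, truth = truth, config = config)
}

#' Generate a peptide table and protein FASTA with planted mapping truth
#'
#' Plants exact peptide-ambiguity fractions: `unique_fraction` of peptides
#' match one protein, `single_genome_fraction` match proteins of a single
#' genome (multi-protein same-genome peptides fill the gap), and the rest
#' match proteins of two genomes.
#'
#' @param config A [sim_config()].
#' @param n_peptides,n_proteins Table sizes.
#' @param unique_fraction,single_genome_fraction Planted fractions
#'   (defaults mirror the ~0.916/~0.927 structure typical of
#'   colony proteomes dominated by one host genome).
#' @param host_protein_weight Fraction of proteins assigned to the host
#'   genome (host-dominated proteome).
#' @param dir Optional output directory (`peptides.tsv`,
#'   `proteins.fasta`, `peptide_truth.tsv`).
#' @return List with `peptides`, `proteins`, `truth` and `config`.
#' @export
generate_peptides <- function(config, n_peptides = 500, n_proteins = 60,
                              unique_fraction = 0.916,
                              single_genome_fraction = 0.927,
                              host_protein_weight = 0.6, dir = NULL) {
  if (single_genome_fraction < unique_fraction)
    stop_fmt("single_genome_fraction must be >= unique_fraction (unique peptides are single-genome)")
  set.seed(config$seed + 3L)
  gids <- sim_genome_ids(config$n_genomes)
  n_host <- max(2L, round(host_protein_weight * n_proteins))
  genome_of <- c(rep(gids[1], n_host),
                 sample(gids[-1], n_proteins - n_host, replace = TRUE))
  proteins <- data.frame(
    protein_id = sprintf("prot_%03d", seq_len(n_proteins)),
    genome_id = genome_of,
    length = sample(150:600, n_proteins, replace = TRUE),
    stringsAsFactors = FALSE)
  proteins$sequence <- vapply(proteins$length, random_aa, character(1))

  n_unique <- round(n_peptides * unique_fraction)
  n_single <- round(n_peptides * single_genome_fraction)
  n_multi_same <- n_single - n_unique
  n_multi_cross <- n_peptides - n_single

  by_genome <- split(proteins$protein_id, proteins$genome_id)
  multi_genomes <- names(by_genome)[lengths(by_genome) >= 2]

  match_sets <- vector("list", n_peptides)
  for (i in seq_len(n_unique))
    match_sets[[i]] <- sample(proteins$protein_id, 1)
  for (i in seq_len(n_multi_same)) {
    g <- sample(multi_genomes, 1)
    match_sets[[n_unique + i]] <- sample(by_genome[[g]], 2)
  }
  for (i in seq_len(n_multi_cross)) {
    gs <- sample(names(by_genome), 2)
    match_sets[[n_single + i]] <- c(sample(by_genome[[gs[1]]], 1),
                                    sample(by_genome[[gs[2]]], 1))
  }
  peptides <- data.frame(
    peptide = vapply(seq_len(n_peptides), function(i)
      random_aa(sample(8:20, 1)), character(1)),
    spectral_count = sample(1:10, n_peptides, replace = TRUE),
    stringsAsFactors = FALSE)
  peptides$protein_ids <- match_sets

  truth <- list(unique_protein_fraction = n_unique / n_peptides,
                single_genome_fraction = n_single / n_peptides)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pep_out <- peptides
    pep_out$protein_ids <- vapply(match_sets, collapse_ids, character(1))
    write_tsv(pep_out, file.path(dir, "peptides.tsv"))
    aa <- Biostrings::AAStringSet(proteins$sequence)
    names(aa) <- paste0(proteins$genome_id, "|", proteins$protein_id)
    Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"))
    write_tsv(data.frame(stat = names(truth),
                         value = unlist(truth),
                         stringsAsFactors = FALSE),
              file.path(dir, "peptide_truth.tsv"))
  }
  list(peptides = peptides, proteins = proteins, truth = truth,
       config = config)
}

#' Simulate a full consortium fixture set
#'
#' Runs every generator from one config and (optionally) writes all file
#' contracts plus truth sidecars into a directory: annotations, trait
#' truth, BGC JSON, counts, peptides and protein FASTA.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with the outputs of all generators.
#' @export
simulate_consortium <- function(config, dir = NULL) {
  ann <- generate_annotations(config, dir = dir)
  bgc <- generate_bgcs(config, dir = dir)
  cnt <- generate_counts(config, dir = dir)
  pep <- generate_peptides(config, dir = dir)
  list(annotations = ann$annotations, trait_truth = ann$truth,
       bgcs = bgc$bgcs, bgc_truth = bgc$truth,
       counts = cnt$counts, count_truth = cnt$truth,
       peptides = pep$peptides, proteins = pep$proteins,
       peptide_truth = pep$truth, config = config)
}

#' Demonstration preset: one dominant diazotroph host plus epibionts
#'
#' Builds a [sim_config()] whose planted trait matrix mirrors the
#' qualitative structure of a Trichodesmium-like consortium: the host
#' (genome 1) carries the full nitrogen-fixation module, phosphate and
#' phosphonate/phosphite transporters with both a C-P lyase and phosphite
#' dehydrogenase, alkaline phosphatases phoA/phoX, all three B-vitamin
#' biosynthesis pathways, ferrous/ferric uptake only (no organic-Fe
#' receptors), assimilation-linked nirA with norB, and an AHL synthase.
#' Epibionts receive trait statuses sampled with per-category prevalences
#' (no epibiont can fix N2; vitamin uptake is common while full
#' biosynthesis is rare, so most epibionts are auxotrophic for at least
#' one vitamin). Intended for demonstrations and qualitative checks, not
#' numeric reproduction.
#'
#' @param seed Integer seed.
#' @param n_genomes Consortium size (default 52).
#' @return A `sim_config` with `trait_truth` filled in.
#' @export
consortium_preset <- function(seed, n_genomes = 52) {
  catalog <- default_catalog()
  gids <- sim_genome_ids(n_genomes)
  truth <- matrix("absent", n_genomes, length(catalog),
                  dimnames = list(gids, names(catalog)))

  host_present <- c("n2_fixation", "fe2_uptake", "fe3_uptake", "fe_storage",
                    "pst_transporter", "phn_transporter", "cp_lyase",
                    "ptxD", "phoA", "phoX", "vitB1_biosynthesis",
                    "vitB7_biosynthesis", "vitB12_biosynthesis",
                    "nirA", "norBC", "ahl_biosynthesis",
                    "ammonium_transporter", "glutamine_synthetase",
                    "pilus_assembly", "secretion_sec_srp")
  truth[1, host_present] <- "present"

  prevalence <- c(
    fe2_uptake = 0.8, fe3_uptake = 0.8, heme_uptake = 0.55,
    citrate_uptake = 0.5, siderophore_receptor = 0.6, tonb_system = 0.75,
    fe_storage = 0.5, fe_complex_tbdt = 0.5,
    pst_transporter = 0.7, pit_transporter = 0.4, phn_transporter = 0.45,
    cp_lyase = 0.3, ptxD = 0.08, aep_hydrolysis = 0.05, phoA = 0.3,
    phoX = 0.3, phoD = 0.2,
    n2_fixation = 0, napAB = 0.15, narGHI = 0.1, narB = 0.1, nasA = 0.35,
    nrfAH = 0.02, nirA = 0.2, nirBD = 0.35, nirS = 0.04, nirK = 0.08,
    norBC = 0.1, nosZ = 0.06, ammonium_transporter = 0.8,
    glutamine_synthetase = 0.9,
    vitB1_biosynthesis = 0.3, vitB1_uptake = 0.6,
    vitB7_biosynthesis = 0.35, vitB7_uptake = 0.6,
    vitB12_biosynthesis = 0.25, vitB12_uptake = 0.65,
    ahl_biosynthesis = 0.28, quorum_sensing_regulation = 0.4,
    secretion_t2ss = 0.5, secretion_sec_srp = 0.9, secretion_t6ss = 0.15,
    pilus_assembly = 0.5, flagellar_motility = 0.45, chemotaxis = 0.4,
    copper_efflux = 0.5, arsenic_resistance = 0.35,
    mercury_resistance = 0.15, zinc_transporter = 0.6)

  set.seed(seed)
  for (tr in names(catalog)) {
    p <- unname(prevalence[tr])
    if (is.na(p)) p <- 0.3
    if (n_genomes > 1)
      truth[-1, tr] <- sample(c("present", "absent"), n_genomes - 1,
                              replace = TRUE, prob = c(p, 1 - p))
  }
  sim_config(n_genomes = n_genomes, trait_truth = truth, seed = seed)
}
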