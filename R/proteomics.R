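# Peptide-to-protein-to-genome mapping statistics and NSAF normalization
# of spectral counts. Upstream spectral search and FDR filtering are out
# of scope; the peptide table contract assumes a filtered input.

#' Read a peptide-spectral table
#'
#' TSV with columns `peptide`, `spectral_count` (positive integer) and
#' `protein_ids` (semicolon-separated, non-empty).
#'
#' @param path Input TSV path.
#' @return data.frame with a list-column `protein_ids`.
#' @export
read_peptide_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("peptide", "spectral_count", "protein_ids"), path)
  df$spectral_count <- as.integer(df$spectral_count)
  if (any(is.na(df$spectral_count)) || any(df$spectral_count < 1L))
    stop_fmt("peptide table '%s': spectral_count must be a positive integer",
             path)
  ids <- split_ids(df$protein_ids)
  if (any(lengths(ids) == 0))
    stop_fmt("peptide table '%s': every peptide must match at least one protein",
             path)
  df$protein_ids <- ids
  df
}

#' Read a protein FASTA with genome-tagged headers
#'
#' Headers follow `genome_id|protein_id`; sequence lengths provide the
#' NSAF length normalization.
#'
#' @param path FASTA path.
#' @return data.frame with `protein_id`, `genome_id`, `length`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop_fmt("protein FASTA '%s': headers must follow 'genome_id|protein_id'",
             path)
  data.frame(
    protein_id = vapply(parts, `[`, character(1), 2),
    genome_id = vapply(parts, `[`, character(1), 1),
    length = Biostrings::width(seqs),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE)
}

#' Map peptides to proteins and genomes
#'
#' Computes the two ambiguity statistics of peptide-level taxonomic
#' attribution — the fraction of peptides matching exactly one protein,
#' and the fraction whose matched proteins all belong to one genome — and
#' attributes spectral counts to proteins. Default crediting is
#' specificity-unaware (each peptide's count credited to every matched
#' protein, encompassing the widest range of putative matches); the
#' `unique` mode credits single-match peptides only.
#'
#' @param peptides data.frame as from [read_peptide_table()].
#' @param proteins data.frame as from [read_protein_fasta()] (columns
#'   `protein_id`, `genome_id`, `length`).
#' @param mode `"all"` (specificity-unaware) or `"unique"`.
#' @return List with `stats` (`n_peptides`, `total_spectral_counts`,
#'   `unique_protein_fraction`, `single_genome_fraction`) and
#'   `protein_counts` (data.frame protein_id, genome_id, length,
#'   spectral_count_sum).
#' @export
map_peptides <- function(peptides, proteins, mode = c("all", "unique")) {
  mode <- match.arg(mode)
  ids <- if (is.list(peptides$protein_ids)) peptides$protein_ids
         else split_ids(peptides$protein_ids)
  dangling <- setdiff(unique(unlist(ids)), proteins$protein_id)
  if (length(dangling) > 0)
    stop_fmt("peptides reference unknown protein id(s): %s",
             paste(utils::head(dangling, 5), collapse = ", "))
  genome_of <- stats::setNames(proteins$genome_id, proteins$protein_id)

  n_match <- lengths(ids)
  unique_protein_fraction <- mean(n_match == 1L)
  single_genome_fraction <- mean(vapply(ids, function(p)
    length(unique(genome_of[p])) == 1L, logical(1)))

  counts <- stats::setNames(numeric(nrow(proteins)), proteins$protein_id)
  for (i in seq_len(nrow(peptides))) {
    if (mode == "unique" && n_match[i] != 1L) next
    counts[ids[[i]]] <- counts[ids[[i]]] + peptides$spectral_count[i]
  }
  protein_counts <- data.frame(
    protein_id = proteins$protein_id, genome_id = proteins$genome_id,
    length = proteins$length,
    spectral_count_sum = unname(counts[proteins$protein_id]),
    stringsAsFactors = FALSE)
  list(
    stats = list(
      n_peptides = nrow(peptides),
      total_spectral_counts = sum(peptides$spectral_count),
      unique_protein_fraction = unique_protein_fraction,
      single_genome_fraction = single_genome_fraction),
    protein_counts = protein_counts)
}

#' Normalized spectral abundance factor (NSAF)
#'
#' `saf_i = c_i / L_i` (spectral counts over protein length in residues),
#' `nsaf_i = saf_i / sum(saf)`; NSAF values sum to one per sample, making
#' them scale-invariant in the counts. Genome-level abundance is the sum
#' of a genome's protein NSAFs.
#'
#' @param protein_counts data.frame with `protein_id`, `length` (>= 1),
#'   `spectral_count_sum` (>= 0, at least one positive), and optionally
#'   `genome_id` for the genome rollup.
#' @return List with `proteins` (protein_id, genome_id, spectral_count_sum,
#'   length, saf, nsaf) and `genomes` (genome_id, nsaf) when genome labels
#'   are available.
#' @export
nsaf <- function(protein_counts) {
  pc <- protein_counts
  if (any(pc$length < 1))
    stop_fmt("protein lengths must be >= 1")
  if (any(pc$spectral_count_sum < 0))
    stop_fmt("spectral counts must be non-negative")
  if (all(pc$spectral_count_sum == 0))
    stop_fmt("all spectral counts are zero; nothing to normalize")
  saf <- pc$spectral_count_sum / pc$length
  nsaf_v <- saf / sum(saf)
  proteins <- data.frame(
    protein_id = pc$protein_id,
    genome_id = pc$genome_id %||% NA_character_,
    spectral_count_sum = pc$spectral_count_sum,
    length = pc$length, saf = saf, nsaf = nsaf_v,
    stringsAsFactors = FALSE)
  genomes <- NULL
  if (!is.null(pc$genome_id)) {
    agg <- stats::aggregate(nsaf ~ genome_id, data = proteins, FUN = sum)
    genomes <- agg[order(-agg$nsaf), , drop = FALSE]
    rownames(genomes) <- NULL
  }
  list(proteins = proteins, genomes = genomes)
}
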