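# In-code fixtures: toy genomes built from bare id vectors, and an
# independently written brute-force implementation of the generic
# calling rule used as the oracle for engine tests.

toy_genome <- function(id, kegg = character(0), pfam = character(0),
                       copies = 1L) {
  kegg <- rep(kegg, each = copies)
  n <- length(kegg) + length(pfam)
  if (n == 0) return(genome_annotation(id))
  starts <- 1L + (seq_len(n) - 1L) * 1000L
  genes <- data.frame(
    gene_id = sprintf("%s_g%03d", id, seq_len(n)),
    contig = "c1", start = starts, end = starts + 500L, strand = "+",
    kegg_ids = c(kegg, rep("", length(pfam))),
    pfam_ids = c(rep("", length(kegg)), pfam),
    stringsAsFactors = FALSE)
  genome_annotation(id, genes)
}

# Brute-force restatement of the calling rule, kept deliberately naive:
# count distinct module genes, compare to threshold, require markers.
oracle_status <- function(present_ids, trait) {
  denom <- if (length(trait$module_genes) > 0) trait$module_genes
           else trait$pfam_markers
  n_found <- 0
  for (g in denom) if (g %in% present_ids) n_found <- n_found + 1
  comp <- n_found / length(denom)
  markers <- unique(c(trait$marker_genes, trait$pfam_markers))
  markers_all <- TRUE
  for (m in markers) if (!(m %in% present_ids)) markers_all <- FALSE
  if (comp >= trait$completeness_threshold) {
    if (markers_all) "present" else "putative"
  } else if (trait$report_partial &&
             any(c(trait$module_genes, trait$pfam_markers) %in% present_ids)) {
    "putative"
  } else {
    "absent"
  }
}

# All subsets of a character vector (for exhaustive enumeration).
all_subsets <- function(ids) {
  n <- length(ids)
  lapply(seq_len(2^n) - 1L, function(mask)
    ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
}

# Build a toy genome carrying all genes of the selected N gene groups.
n_group_genome <- function(selected, id = "gN") {
  groups <- n_gene_groups()
  toy_genome(id, kegg = unlist(groups[selected], use.names = FALSE))
}
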