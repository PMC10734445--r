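# Genome annotation data model and TSV reader/writer.
#
# The package consumes tabular functional annotations (one row per predicted
# gene, with its KEGG ortholog and PFAM domain assignments) produced upstream
# by HMM/ortholog scanners; running those scanners is out of scope here.

#' Construct a genome annotation
#'
#' A genome annotation bundles one MAG's identifier, optional quality
#' metadata, and its per-gene functional annotations.
#'
#' @param genome_id Non-empty genome identifier.
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`+`/`-`), `kegg_ids`, `pfam_ids`. Coordinates are 1-based
#'   inclusive (GFF convention). `kegg_ids`/`pfam_ids` are semicolon-separated
#'   id strings; a gene may carry several ids (scanners can emit more than
#'   one hit) or none (empty string).
#' @param taxonomy Optional free-text taxonomy string.
#' @param completeness_pct,redundancy_pct Optional bin quality estimates
#'   (percent); completeness must lie in [0, 100], redundancy must be >= 0.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genes = empty_gene_table(),
                              taxonomy = NA_character_,
                              completeness_pct = NA_real_,
                              redundancy_pct = NA_real_) {
  if (!is.character(genome_id) || length(genome_id) != 1 || !nzchar(genome_id))
    stop_fmt("genome_id must be a single non-empty string")
  genes <- validate_gene_table(genes, genome_id)
  if (!is.na(completeness_pct) &&
      (completeness_pct < 0 || completeness_pct > 100))
    stop_fmt("completeness_pct must lie in [0, 100] (genome '%s')", genome_id)
  if (!is.na(redundancy_pct) && redundancy_pct < 0)
    stop_fmt("redundancy_pct must be >= 0 (genome '%s')", genome_id)
  structure(
    list(genome_id = genome_id,
         taxonomy = taxonomy,
         completeness_pct = as.numeric(completeness_pct),
         redundancy_pct = as.numeric(redundancy_pct),
         genes = genes),
    class = "genome_annotation")
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             kegg_ids = character(0), pfam_ids = character(0),
             stringsAsFactors = FALSE)
}

validate_gene_table <- function(genes, genome_id) {
  cols <- c("gene_id", "contig", "start", "end", "strand",
            "kegg_ids", "pfam_ids")
  missing <- setdiff(cols, names(genes))
  if (length(missing) > 0)
    stop_fmt("gene table for genome '%s' lacks column(s): %s",
             genome_id, paste(missing, collapse = ", "))
  genes <- genes[, cols, drop = FALSE]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  for (col in c("gene_id", "contig", "strand", "kegg_ids", "pfam_ids"))
    genes[[col]] <- as.character(genes[[col]])
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop_fmt("duplicate gene_id within genome '%s': %s",
             genome_id, paste(unique(dup), collapse = ", "))
  bad <- which(genes$start < 1L | genes$end < genes$start)
  if (length(bad) > 0)
    stop_fmt("invalid coordinates for gene '%s' in genome '%s' (start >= 1 and end >= start required)",
             genes$gene_id[bad[1]], genome_id)
  badstrand <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(badstrand) > 0)
    stop_fmt("invalid strand value(s) in genome '%s': %s",
             genome_id, paste(badstrand, collapse = ", "))
  rownames(genes) <- NULL
  genes
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes", x$genome_id, nrow(x$genes)))
  if (!is.na(x$completeness_pct))
    cat(sprintf(" (%.1f%% complete, %.1f%% redundant)",
                x$completeness_pct, x$redundancy_pct))
  cat("\n")
  invisible(x)
}

# Copy counts per functional id: number of gene records carrying each
# KEGG/PFAM id (multiple ids on one gene each count once for that gene).
id_counts <- function(genome) {
  ids <- c(unlist(split_ids(genome$genes$kegg_ids)),
           unlist(split_ids(genome$genes$pfam_ids)))
  if (length(ids) == 0) return(integer(0))
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

ids_present <- function(genome) names(id_counts(genome)) %||% character(0)

#' Read genome annotations from a TSV file
#'
#' Expects header columns `genome_id`, `gene_id`, `contig`, `start`, `end`,
#' `strand`, `kegg_ids`, `pfam_ids` (the last two semicolon-separated, may be
#' empty). Rows are grouped by `genome_id`; gene order within the file is
#' preserved per genome.
#'
#' @param path Path to a UTF-8 tab-delimited annotation file.
#' @return Named list of [genome_annotation()] objects (one per distinct
#'   genome id, in order of first appearance).
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path)
  cols <- c("genome_id", "gene_id", "contig", "start", "end", "strand",
            "kegg_ids", "pfam_ids")
  require_columns(df, cols, path)
  start_num <- suppressWarnings(as.integer(df$start))
  end_num <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start_num) | is.na(end_num) |
                 start_num < 1L | end_num < start_num)
  if (length(bad) > 0)
    stop_fmt("malformed coordinates at data row %d of '%s' (start >= 1 and end >= start required)",
             bad[1], path)
  df$start <- start_num
  df$end <- end_num
  # an all-empty id column is type-sniffed as logical NA; restore ""
  for (col in c("kegg_ids", "pfam_ids")) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  meta_col <- function(sub, col, default) {
    if (col %in% names(sub)) sub[[col]][1] else default
  }
  ids <- unique(df$genome_id)
  out <- lapply(ids, function(g) {
    sub <- df[df$genome_id == g, , drop = FALSE]
    genome_annotation(
      g, sub[, c("gene_id", "contig", "start", "end", "strand",
                 "kegg_ids", "pfam_ids"), drop = FALSE],
      taxonomy = (\(x) if (is.na(x) || !nzchar(x)) NA_character_ else x)(
        as.character(meta_col(sub, "taxonomy", NA_character_))),
      completeness_pct = as.numeric(meta_col(sub, "completeness_pct", NA)),
      redundancy_pct = as.numeric(meta_col(sub, "redundancy_pct", NA)))
  })
  stats::setNames(out, ids)
}

#' Write genome annotations to a TSV file
#'
#' Inverse of [read_annotations()]: genomes are concatenated into a single
#' long table, one row per gene.
#'
#' @param annotations Named list of [genome_annotation()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(g) {
    if (nrow(g$genes) == 0) return(NULL)
    cbind(data.frame(genome_id = g$genome_id, stringsAsFactors = FALSE),
          g$genes,
          data.frame(taxonomy = g$taxonomy,
                     completeness_pct = g$completeness_pct,
                     redundancy_pct = g$redundancy_pct,
                     stringsAsFactors = FALSE))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- cbind(data.frame(genome_id = character(0)),
                               empty_gene_table())
  write_tsv(df, path)
}

#' Flag a genome bin as high quality
#'
#' Two quality presets are bundled: the default requires >= 90% completeness
#' with <= 10% redundancy; the `strict` preset requires < 5% redundancy.
#' Both conventions circulate for MAG quality reporting, so the bound is
#' configurable.
#'
#' @param genome A [genome_annotation()] with quality metadata.
#' @param preset `"default"` (redundancy <= 10) or `"strict"` (redundancy < 5).
#' @param completeness_min Minimum completeness percent (default 90).
#' @return Logical; `NA` if quality metadata is missing.
#' @export
is_high_quality <- function(genome, preset = c("default", "strict"),
                            completeness_min = 90) {
  preset <- match.arg(preset)
  if (is.na(genome$completeness_pct) || is.na(genome$redundancy_pct))
    return(NA)
  ok_red <- if (preset == "strict") genome$redundancy_pct < 5
            else genome$redundancy_pct <= 10
  genome$completeness_pct >= completeness_min && ok_red
}

#' Read a trait-call override table
#'
#' Overrides replace the interactive "manual inspection" step of curation
#' workflows with an explicit, auditable file: each row forces one
#' (genome, trait) cell to a given status and must state a reason.
#'
#' @param path TSV with columns `genome_id`, `trait_id`, `forced_status`
#'   (`present`/`putative`/`absent`), `reason` (non-empty).
#' @return data.frame of overrides.
#' @export
read_overrides <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("genome_id", "trait_id", "forced_status", "reason"),
                  path)
  assert_status(df$forced_status, "forced_status")
  df$reason <- as.character(df$reason)
  df$reason[is.na(df$reason)] <- ""
  if (any(!nzchar(trimws(df$reason))))
    stop_fmt("override file '%s' contains empty reason fields; every override must be justified", path)
  df
}
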