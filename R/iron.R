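# Fe-uptake repertoire classification and siderophore BGC calling.
#
# NIS-type clusters are recognized by the iucA/iucC synthetase domain
# (PF04183) and typed by nearest-reference identity against a bundled
# exemplar panel; NRPS clusters are flagged as putative siderophore
# producers when a TonB-dependent siderophore receptor (SMCOG1082) is
# co-located within the cluster.

FE_RECEPTORS <- c(fe2 = "K04759", fe3 = "K02012", heme = "K16087",
                  citrate = "K16091", siderophore = "K02016")

#' Classify a genome's Fe-uptake repertoire
#'
#' Single-marker receptor calls for ferrous (feoB), ferric (afuA), heme
#' (hemR), citrate (fecA) and siderophore (fevS) uptake, plus the
#' TonB/ExbB/ExbD energizing system (complete at the generic 50% rule,
#' partial when only some genes are found). The siderophore receptor call
#' always carries an ambiguity flag: its KEGG annotation does not
#' distinguish siderophore from vitamin B12 substrates.
#'
#' @param genome A [genome_annotation()].
#' @param tonb_genes KEGG ids of the TonB system (default tonB/exbB/exbD).
#' @return An `fe_uptake_profile`.
#' @export
classify_fe_uptake <- function(genome,
                               tonb_genes = c("K03832", "K03561", "K03559")) {
  have <- ids_present(genome)
  status_of <- function(id) if (id %in% have) "present" else "absent"
  receptors <- vapply(FE_RECEPTORS, status_of, character(1))
  n_tonb <- length(intersect(tonb_genes, have))
  tonb <- if (n_tonb / length(tonb_genes) >= 0.5) "complete"
          else if (n_tonb > 0) "partial" else "absent"
  structure(
    list(genome_id = genome$genome_id,
         fe2 = receptors[["fe2"]], fe3 = receptors[["fe3"]],
         heme = receptors[["heme"]], citrate = receptors[["citrate"]],
         siderophore_receptor = receptors[["siderophore"]],
         ambiguity_flag = receptors[["siderophore"]] == "present",
         tonb_system = tonb),
    class = "fe_uptake_profile")
}

fe_profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id, fe2 = p$fe2, fe3 = p$fe3,
               heme = p$heme, citrate = p$citrate,
               siderophore_receptor = p$siderophore_receptor,
               receptor_ambiguous = p$ambiguity_flag,
               tonb_system = p$tonb_system, stringsAsFactors = FALSE)
  }))
}

#' Construct a BGC record
#'
#' A secondary-metabolite gene cluster as emitted (upstream) by cluster
#' screening: class, genomic span, member genes with their iucA/iucC
#' domain counts and functional tags, and optionally the synthetase
#' amino-acid sequence used for NIS typing.
#'
#' @param genome_id,cluster_id Identifiers.
#' @param contig Contig name.
#' @param start,end 1-based inclusive cluster span.
#' @param cluster_class `"NRPS"`, `"NIS"` or `"other"`.
#' @param genes List of member genes; each a list with `gene_id`, `start`,
#'   `end`, `pf04183_count` (>= 0) and `tags` (character vector; the tag
#'   `"TBDT_siderophore_receptor"` marks an SMCOG1082 hit).
#' @param synthetase_sequence Optional amino-acid sequence (single string).
#' @return An object of class `bgc_record`.
#' @export
bgc_record <- function(genome_id, cluster_id, contig, start, end,
                       cluster_class, genes = list(),
                       synthetase_sequence = NULL) {
  if (!cluster_class %in% c("NRPS", "NIS", "other"))
    stop_fmt("cluster '%s': unknown cluster_class '%s'",
             cluster_id, cluster_class)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop_fmt("cluster '%s': invalid span", cluster_id)
  genes <- lapply(genes, function(g) {
    g$start <- as.integer(g$start); g$end <- as.integer(g$end)
    g$pf04183_count <- as.integer(g$pf04183_count %||% 0L)
    g$tags <- as.character(unlist(g$tags) %||% character(0))
    if (g$pf04183_count < 0L)
      stop_fmt("cluster '%s': negative PF04183 count on gene '%s'",
               cluster_id, g$gene_id)
    if (g$start < start || g$end > end)
      stop_fmt("cluster '%s': gene '%s' falls outside the cluster span",
               cluster_id, g$gene_id)
    g
  })
  structure(
    list(genome_id = genome_id, cluster_id = cluster_id, contig = contig,
         start = start, end = end, cluster_class = cluster_class,
         genes = genes,
         synthetase_sequence = synthetase_sequence),
    class = "bgc_record")
}

#' Read BGC records from JSON
#'
#' The schema is a JSON array of objects with fields `genome_id`,
#' `cluster_id`, `contig`, `start`, `end`, `cluster_class`, `genes`
#' (array of {gene_id, start, end, pf04183_count, tags}) and optional
#' `synthetase_sequence`.
#'
#' @param path Path to a `.json` file.
#' @return List of [bgc_record()] objects.
#' @export
read_bgc_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    bgc_record(genome_id = r$genome_id, cluster_id = r$cluster_id,
               contig = r$contig %||% NA_character_,
               start = r$start, end = r$end,
               cluster_class = r$cluster_class,
               genes = r$genes %||% list(),
               synthetase_sequence = r$synthetase_sequence %||% NULL)
  })
}

#' Write BGC records to JSON
#'
#' @param bgcs List of [bgc_record()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bgc_json <- function(bgcs, path) {
  payload <- lapply(bgcs, function(b) {
    out <- list(genome_id = b$genome_id, cluster_id = b$cluster_id,
                contig = b$contig, start = b$start, end = b$end,
                cluster_class = b$cluster_class,
                genes = lapply(b$genes, function(g)
                  list(gene_id = g$gene_id, start = g$start, end = g$end,
                       pf04183_count = g$pf04183_count,
                       tags = as.list(g$tags))))
    if (!is.null(b$synthetase_sequence))
      out$synthetase_sequence <- b$synthetase_sequence
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.panel_cache <- new.env(parent = emptyenv())

#' The bundled NIS reference panel
#'
#' Exemplar NIS synthetase sequences with type metadata (petrobactin-,
#' vibrioferrin-, rhizoferrin- and aerobactin-type) used for
#' nearest-reference typing of NIS clusters. The first three types carry a
#' citrate moiety and are photolabile. The bundled sequences are
#' synthetic stand-ins (seeded random sequences, see the panel FASTA
#' header); a study-specific panel of curated synthetases can be supplied
#' in the same FASTA + metadata TSV format.
#'
#' @param fasta,metadata Optional paths overriding the bundled panel.
#' @return data.frame with `name`, `type`, `photolabile`, `membrane_bound`,
#'   `sequence`.
#' @export
nis_reference_panel <- function(fasta = NULL, metadata = NULL) {
  bundled <- is.null(fasta) && is.null(metadata)
  if (bundled && !is.null(.panel_cache$default)) return(.panel_cache$default)
  fasta <- fasta %||% system.file(
    "extdata", "nis_reference_panel_synthetic.fasta",
    package = "trichotraits", mustWork = TRUE)
  metadata <- metadata %||% system.file(
    "extdata", "nis_reference_panel_synthetic.tsv",
    package = "trichotraits", mustWork = TRUE)
  seqs <- Biostrings::readAAStringSet(fasta)
  meta <- read_tsv(metadata)
  require_columns(meta, c("name", "type", "photolabile", "membrane_bound"),
                  metadata)
  missing <- setdiff(meta$name, names(seqs))
  if (length(missing) > 0)
    stop_fmt("panel metadata names missing from FASTA: %s",
             paste(missing, collapse = ", "))
  meta$photolabile <- as.logical(meta$photolabile)
  meta$membrane_bound <- as.logical(meta$membrane_bound)
  meta$sequence <- as.character(seqs[meta$name])
  if (bundled) .panel_cache$default <- meta
  meta
}

#' Global pairwise amino-acid identity
#'
#' Needleman-Wunsch global alignment with pinned scoring (BLOSUM62, gap
#' opening 10, gap extension 0.5); identity is matches over alignment
#' length. Symmetric and deterministic.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return Percent identity in [0, 100].
#' @export
sequence_identity <- function(a, b) {
  if (!grepl("^[ARNDCQEGHILKMFPSTWYVX*]+$", a) ||
      !grepl("^[ARNDCQEGHILKMFPSTWYVX*]+$", b))
    stop_fmt("sequences contain characters outside the amino-acid alphabet")
  blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                            envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum, gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}

#' Call an NIS-type siderophore from a BGC record
#'
#' A cluster is NIS-type iff its member genes carry at least one
#' iucA/iucC (PF04183) domain in total. When a synthetase sequence is
#' available, the cluster is typed by its nearest reference in the panel
#' (maximum global identity; ties broken by panel order and flagged), and
#' photolability/membrane association are inherited from the reference
#' metadata.
#'
#' @param bgc A [bgc_record()] of class `NIS` or `other`.
#' @param references Reference panel (see [nis_reference_panel()]).
#' @return A `siderophore_call`: list with `kind` (`NIS` or `none`),
#'   `iuc_domain_count`, `nearest_reference`, `reference_identity_pct`,
#'   `reference_type`, `photolabile`, `membrane_bound`, `tie`.
#' @export
call_nis_siderophore <- function(bgc, references = nis_reference_panel()) {
  if (bgc$cluster_class == "NRPS")
    stop_fmt("cluster '%s' is NRPS-class; use call_nrps_siderophore()",
             bgc$cluster_id)
  iuc <- sum(vapply(bgc$genes, function(g) g$pf04183_count, integer(1)))
  call <- list(genome_id = bgc$genome_id, cluster_id = bgc$cluster_id,
               kind = if (iuc >= 1L) "NIS" else "none",
               iuc_domain_count = iuc,
               nearest_reference = NA_character_,
               reference_identity_pct = NA_real_,
               reference_type = NA_character_,
               photolabile = NA, membrane_bound = NA, tie = FALSE)
  if (call$kind == "NIS" && !is.null(bgc$synthetase_sequence)) {
    if (nrow(references) == 0)
      stop_fmt("synthetase sequence supplied but reference panel is empty")
    ids <- vapply(references$sequence, sequence_identity,
                  numeric(1), a = bgc$synthetase_sequence, USE.NAMES = FALSE)
    best <- which.max(ids)
    call$nearest_reference <- references$name[best]
    call$reference_identity_pct <- ids[best]
    call$reference_type <- references$type[best]
    call$photolabile <- references$photolabile[best]
    call$membrane_bound <- references$membrane_bound[best]
    call$tie <- sum(ids == ids[best]) > 1
  }
  structure(call, class = "siderophore_call")
}

#' Call a putative NRPS siderophore from a BGC record
#'
#' An NRPS cluster is a putative siderophore producer iff a member gene
#' within the cluster span is tagged as a TonB-dependent siderophore
#' receptor (`TBDT_siderophore_receptor`, the SMCOG1082 rule); any other
#' cluster class yields `none` regardless of tags.
#'
#' @param bgc A [bgc_record()].
#' @return A `siderophore_call` with `kind` `NRPS_putative` or `none`.
#' @export
call_nrps_siderophore <- function(bgc) {
  receptor <- any(vapply(bgc$genes, function(g)
    "TBDT_siderophore_receptor" %in% g$tags, logical(1)))
  kind <- if (bgc$cluster_class == "NRPS" && receptor) "NRPS_putative"
          else "none"
  structure(
    list(genome_id = bgc$genome_id, cluster_id = bgc$cluster_id,
         kind = kind, iuc_domain_count = 0L,
         nearest_reference = NA_character_,
         reference_identity_pct = NA_real_,
         reference_type = NA_character_, photolabile = NA,
         membrane_bound = NA, tie = FALSE),
    class = "siderophore_call")
}

#' Call siderophores for a collection of BGC records
#'
#' Dispatches each record to the NIS or NRPS rule by cluster class; every
#' cluster is reported (no genome-level collapsing, since one genome may
#' carry several clusters of different types).
#'
#' @param bgcs List of [bgc_record()] objects.
#' @param references NIS reference panel.
#' @return data.frame with one row per cluster.
#' @export
call_siderophores <- function(bgcs, references = nis_reference_panel()) {
  calls <- lapply(bgcs, function(b) {
    if (b$cluster_class == "NRPS") call_nrps_siderophore(b)
    else call_nis_siderophore(b, references)
  })
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(genome_id = cl$genome_id, cluster_id = cl$cluster_id,
               kind = cl$kind, iuc_domain_count = cl$iuc_domain_count,
               nearest_reference = cl$nearest_reference,
               reference_identity_pct = cl$reference_identity_pct,
               reference_type = cl$reference_type,
               photolabile = cl$photolabile,
               membrane_bound = cl$membrane_bound,
               tie = cl$tie, stringsAsFactors = FALSE)
  }))
}
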