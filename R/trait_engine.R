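# The generic trait-calling rule applied across all categories:
# pathway completeness with an inclusive threshold, individually required
# marker genes, an explicit three-valued status, and auditable overrides.

#' Module completeness of a trait in a genome
#'
#' Fraction of the trait's distinct module genes found in the genome.
#' Copy counts do not inflate the numerator: a gene in three copies counts
#' once. For domain-only traits the PFAM marker set is the denominator.
#'
#' @param genome A [genome_annotation()].
#' @param trait A [trait_definition()].
#' @return Fraction in [0, 1].
#' @export
module_completeness <- function(genome, trait) {
  denom <- module_denominator(trait)
  if (length(denom) == 0)
    stop_fmt("trait '%s' defines no module genes or PFAM markers",
             trait$trait_id)
  have <- ids_present(genome)
  length(intersect(denom, have)) / length(denom)
}

#' Call one trait in one genome
#'
#' Status logic:
#' * `present` — completeness >= threshold AND every marker gene (KEGG and
#'   PFAM) present;
#' * `putative` — completeness >= threshold with at least one marker
#'   missing, or (for traits flagged `report_partial`) any module gene
#'   present below threshold;
#' * `absent` — otherwise.
#'
#' A matching override replaces the computed status and sets
#' `override_applied`; evidence below threshold is still recorded so
#' reports can show partial pathways.
#'
#' @param genome A [genome_annotation()].
#' @param trait A [trait_definition()].
#' @param overrides Optional override data.frame (see [read_overrides()]).
#' @return A `trait_call`: list with `genome_id`, `trait_id`, `status`,
#'   `completeness`, `evidence` (data.frame id/copy count),
#'   `override_applied`, `note`.
#' @export
call_trait <- function(genome, trait, overrides = NULL) {
  counts <- id_counts(genome)
  universe <- trait_id_universe(trait)
  hit <- intersect(universe, names(counts) %||% character(0))
  evidence <- data.frame(id = as.character(hit),
                         copies = unname(counts[hit]),
                         stringsAsFactors = FALSE)
  evidence <- evidence[order(evidence$id), , drop = FALSE]
  rownames(evidence) <- NULL

  completeness <- module_completeness(genome, trait)
  markers <- unique(c(trait$marker_genes, trait$pfam_markers))
  markers_ok <- all(markers %in% names(counts))
  missing_markers <- setdiff(markers, names(counts))

  status <- "absent"
  note <- ""
  if (completeness >= trait$completeness_threshold) {
    if (markers_ok) {
      status <- "present"
    } else {
      status <- "putative"
      note <- sprintf("marker gene(s) missing: %s",
                      paste(missing_markers, collapse = ","))
    }
  } else if (trait$report_partial && nrow(evidence) > 0) {
    status <- "putative"
    note <- sprintf("partial pathway below threshold (%.2f < %.2f)",
                    completeness, trait$completeness_threshold)
  }

  override_applied <- FALSE
  if (!is.null(overrides) && nrow(overrides) > 0) {
    m <- which(overrides$genome_id == genome$genome_id &
                 overrides$trait_id == trait$trait_id)
    if (length(m) > 0) {
      ov <- overrides[m[1], ]
      status <- ov$forced_status
      override_applied <- TRUE
      note <- sprintf("override: %s", ov$reason)
    }
  }

  structure(
    list(genome_id = genome$genome_id, trait_id = trait$trait_id,
         status = status, completeness = completeness,
         evidence = evidence, override_applied = override_applied,
         note = note),
    class = "trait_call")
}

#' Build a genome-by-trait status matrix
#'
#' Applies [call_trait()] to every (genome, trait) pair. Deterministic
#' given its inputs; permuting the genome list only permutes rows.
#'
#' @param genomes Named list of [genome_annotation()] objects.
#' @param catalog A `trait_catalog`.
#' @param overrides Optional override data.frame; an override naming a
#'   trait absent from the catalog is an error.
#' @return A `trait_matrix`: list with character `status` matrix, numeric
#'   `completeness` matrix (genomes x traits), and the per-cell `calls`.
#' @export
build_trait_matrix <- function(genomes, catalog, overrides = NULL) {
  if (length(genomes) == 0) stop_fmt("no genomes supplied")
  gids <- unname(vapply(genomes, function(g) g$genome_id, character(1)))
  if (anyDuplicated(gids))
    stop_fmt("duplicate genome_id in collection: %s",
             paste(unique(gids[duplicated(gids)]), collapse = ", "))
  tids <- names(catalog)
  if (!is.null(overrides) && nrow(overrides) > 0) {
    unknown <- setdiff(unique(overrides$trait_id), tids)
    if (length(unknown) > 0)
      stop_fmt("override references unknown trait_id(s): %s",
               paste(unknown, collapse = ", "))
  }
  status <- matrix("absent", length(gids), length(tids),
                   dimnames = list(gids, tids))
  completeness <- matrix(0, length(gids), length(tids),
                         dimnames = list(gids, tids))
  calls <- vector("list", length(gids) * length(tids))
  k <- 0L
  for (i in seq_along(genomes)) {
    for (j in seq_along(catalog)) {
      tc <- call_trait(genomes[[i]], catalog[[j]], overrides)
      status[i, j] <- tc$status
      completeness[i, j] <- tc$completeness
      k <- k + 1L
      calls[[k]] <- tc
    }
  }
  structure(list(status = status, completeness = completeness, calls = calls),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d genomes x %d traits (P: %d, U: %d, A: %d)\n",
              nrow(x$status), ncol(x$status),
              sum(x$status == "present"), sum(x$status == "putative"),
              sum(x$status == "absent")))
  invisible(x)
}

#' Write a trait matrix to TSV
#'
#' Writes the status matrix (cells coded `P`/`U`/`A`, one row per genome,
#' one column per trait) and a companion completeness TSV alongside it
#' (suffix `_completeness.tsv`).
#'
#' @param matrix A `trait_matrix`.
#' @param path Output TSV path for the status matrix.
#' @return Invisibly, the two paths written.
#' @export
write_trait_matrix <- function(matrix, path) {
  st <- matrix$status
  df <- data.frame(genome_id = rownames(st), stringsAsFactors = FALSE)
  for (tr in colnames(st)) df[[tr]] <- unname(STATUS_CODE[st[, tr]])
  write_tsv(df, path)
  cpath <- sub("\\.tsv$", "_completeness.tsv", path)
  if (identical(cpath, path)) cpath <- paste0(path, "_completeness.tsv")
  cdf <- data.frame(genome_id = rownames(st), stringsAsFactors = FALSE)
  for (tr in colnames(st))
    cdf[[tr]] <- sprintf("%.6f", matrix$completeness[, tr])
  write_tsv(cdf, cpath)
  invisible(c(path, cpath))
}

#' Read a trait matrix written by [write_trait_matrix()]
#'
#' @param path Path of the status TSV (the companion completeness TSV is
#'   located by suffix).
#' @return A `trait_matrix` (without per-cell call objects).
#' @export
read_trait_matrix <- function(path) {
  df <- read_tsv(path)
  require_columns(df, "genome_id", path)
  traits <- setdiff(names(df), "genome_id")
  status <- as.matrix(df[, traits, drop = FALSE])
  bad <- setdiff(unique(as.vector(status)), names(CODE_STATUS))
  if (length(bad) > 0)
    stop_fmt("unknown status code(s) in '%s': %s", path,
             paste(bad, collapse = ", "))
  status[] <- CODE_STATUS[status]
  rownames(status) <- df$genome_id
  cpath <- sub("\\.tsv$", "_completeness.tsv", path)
  completeness <- matrix(NA_real_, nrow(status), ncol(status),
                         dimnames = dimnames(status))
  if (file.exists(cpath)) {
    cdf <- read_tsv(cpath)
    cm <- as.matrix(cdf[, traits, drop = FALSE])
    completeness[] <- as.numeric(cm)
  }
  structure(list(status = status, completeness = completeness, calls = NULL),
            class = "trait_matrix")
}

#' Export a trait matrix as an iTOL binary dataset
#'
#' Writes an iTOL-compatible `DATASET_BINARY` text file in which each trait
#' becomes one field; statuses are encoded numerically (default
#' present = 1, putative = 0.5, absent = 0), matching the convention of
#' presence/absence trait panels attached to phylogenetic trees.
#'
#' @param matrix A `trait_matrix`.
#' @param path Output text file path.
#' @param label Dataset label shown in iTOL.
#' @param encoding Named numeric vector mapping the three statuses to
#'   field values.
#' @return The path, invisibly.
#' @export
write_itol_binary <- function(matrix, path, label = "traits",
                              encoding = c(present = 1, putative = 0.5,
                                           absent = 0)) {
  assert_status(names(encoding), "encoding name")
  st <- matrix$status
  n <- ncol(st)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "DATASET_BINARY",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", label),
    "COLOR\t#2166ac",
    paste(c("FIELD_SHAPES", rep("2", n)), collapse = "\t"),
    paste(c("FIELD_LABELS", colnames(st)), collapse = "\t"),
    "DATA"), con)
  for (g in rownames(st)) {
    vals <- unname(encoding[st[g, ]])
    writeLines(paste(c(g, format(vals, trim = TRUE)), collapse = "\t"), con)
  }
  invisible(path)
}
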