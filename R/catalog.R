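# Trait catalog: machine-readable definitions of the gene sets, marker
# requirements and completeness thresholds used by the calling engine.

#' Construct a trait definition
#'
#' A trait is a named gene set (KEGG orthologs, optionally PFAM domains)
#' with a completeness threshold and an optional subset of individually
#' required marker genes. Markers encode the rule that substrate-specific
#' receptor/transporter genes are a determining factor for presence:
#' a pathway above threshold but missing a marker is only `putative`.
#'
#' @param trait_id Unique identifier.
#' @param category One of `iron`, `phosphorus`, `nitrogen`, `vitamin`,
#'   `interaction`, `other`.
#' @param module_genes Character vector of KEGG ortholog ids (K#####).
#'   May be empty only when `pfam_markers` is non-empty.
#' @param marker_genes Subset of `module_genes` individually required for a
#'   `present` call (may be empty).
#' @param pfam_markers PFAM accessions (PF#####) individually required
#'   (and, for KEGG-less traits, also the completeness denominator).
#' @param completeness_threshold Fraction in (0, 1]; the default 0.5
#'   implements the general 50% pathway-completeness cutoff, inclusive.
#' @param report_partial If `TRUE`, any module gene found below threshold
#'   yields a `putative` call instead of `absent` (used for substrate-
#'   specific pathways whose fragments are worth reporting).
#' @return An object of class `trait_definition`.
#' @export
trait_definition <- function(trait_id, category, module_genes = character(0),
                             marker_genes = character(0),
                             pfam_markers = character(0),
                             completeness_threshold = 0.5,
                             report_partial = FALSE) {
  categories <- c("iron", "phosphorus", "nitrogen", "vitamin",
                  "interaction", "other")
  if (!is.character(trait_id) || length(trait_id) != 1 || !nzchar(trait_id))
    stop_fmt("trait_id must be a single non-empty string")
  if (!category %in% categories)
    stop_fmt("trait '%s': unknown category '%s'", trait_id, category)
  module_genes <- as.character(module_genes %||% character(0))
  marker_genes <- as.character(marker_genes %||% character(0))
  pfam_markers <- as.character(pfam_markers %||% character(0))
  if (length(module_genes) == 0 && length(pfam_markers) == 0)
    stop_fmt("trait '%s': module_genes may be empty only when pfam_markers is non-empty",
             trait_id)
  if (anyDuplicated(module_genes))
    stop_fmt("trait '%s': duplicated module genes", trait_id)
  extra <- setdiff(marker_genes, module_genes)
  if (length(extra) > 0)
    stop_fmt("trait '%s': marker gene(s) not in module_genes: %s",
             trait_id, paste(extra, collapse = ", "))
  if (!is.numeric(completeness_threshold) ||
      completeness_threshold <= 0 || completeness_threshold > 1)
    stop_fmt("trait '%s': completeness_threshold must lie in (0, 1]", trait_id)
  structure(
    list(trait_id = trait_id, category = category,
         module_genes = module_genes, marker_genes = marker_genes,
         pfam_markers = pfam_markers,
         completeness_threshold = as.numeric(completeness_threshold),
         report_partial = isTRUE(report_partial)),
    class = "trait_definition")
}

# Completeness denominator: the KEGG module genes, or (for domain-only
# traits such as AHL synthase detection) the PFAM marker set.
module_denominator <- function(trait) {
  if (length(trait$module_genes) > 0) trait$module_genes else trait$pfam_markers
}

# Everything that may appear as evidence for the trait.
trait_id_universe <- function(trait) {
  unique(c(trait$module_genes, trait$pfam_markers))
}

#' Read a trait catalog from YAML or JSON
#'
#' The file must contain a top-level `traits` list; each entry declares
#' `trait_id`, `category`, `module_genes`, and optionally `marker_genes`,
#' `pfam_markers`, `completeness_threshold` (default 0.5) and
#' `report_partial`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` catalog file.
#' @return A named list of [trait_definition()] objects
#'   (class `trait_catalog`).
#' @export
read_trait_catalog <- function(path) {
  if (!file.exists(path)) stop_fmt("catalog file '%s' does not exist", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$traits %||% raw
  if (is.null(entries) || length(entries) == 0)
    stop_fmt("catalog file '%s' contains no trait definitions", path)
  defs <- lapply(entries, function(e) {
    trait_definition(
      trait_id = e$trait_id,
      category = e$category,
      module_genes = unlist(e$module_genes) %||% character(0),
      marker_genes = unlist(e$marker_genes) %||% character(0),
      pfam_markers = unlist(e$pfam_markers) %||% character(0),
      completeness_threshold = e$completeness_threshold %||% 0.5,
      report_partial = e$report_partial %||% FALSE)
  })
  ids <- vapply(defs, function(d) d$trait_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop_fmt("catalog '%s' contains duplicate trait_id(s): %s",
             path, paste(unique(dup), collapse = ", "))
  structure(stats::setNames(defs, ids), class = "trait_catalog")
}

.catalog_cache <- new.env(parent = emptyenv())

#' The bundled default trait catalog
#'
#' Loads the catalog shipped with the package: ~49 trait definitions
#' spanning iron, phosphorus, nitrogen, vitamin and interaction categories,
#' transcribing the published gene lists for Fe-uptake receptors,
#' phosphorus transport and reduced-P metabolism, nitrogen transformation
#' gene groups, vitamin B1/B7/B12 biosynthesis and uptake, and
#' config-driven interaction traits.
#'
#' @return A `trait_catalog`.
#' @export
default_catalog <- function() {
  if (is.null(.catalog_cache$default)) {
    path <- system.file("extdata", "trait_catalog.yaml",
                        package = "trichotraits", mustWork = TRUE)
    .catalog_cache$default <- read_trait_catalog(path)
  }
  .catalog_cache$default
}

#' @export
print.trait_catalog <- function(x, ...) {
  cats <- table(vapply(x, function(d) d$category, character(1)))
  cat(sprintf("<trait_catalog> %d traits (%s)\n", length(x),
              paste(sprintf("%s: %d", names(cats), cats), collapse = ", ")))
  invisible(x)
}

#' Write a trait catalog to YAML
#'
#' @param catalog A `trait_catalog`.
#' @param path Output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_trait_catalog <- function(catalog, path) {
  entries <- lapply(unname(catalog), function(d) {
    e <- list(trait_id = d$trait_id, category = d$category,
              module_genes = as.list(d$module_genes))
    if (length(d$marker_genes)) e$marker_genes <- as.list(d$marker_genes)
    if (length(d$pfam_markers)) e$pfam_markers <- as.list(d$pfam_markers)
    e$completeness_threshold <- d$completeness_threshold
    if (d$report_partial) e$report_partial <- TRUE
    e
  })
  yaml::write_yaml(list(traits = entries), path)
  invisible(path)
}
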