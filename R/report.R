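# End-to-end orchestration: trait matrix plus per-category reports,
# consortium summary, and a machine-readable run manifest.

#' Run the full trait-calling pipeline and write reports
#'
#' Builds the genome-by-trait status matrix through the generic engine and
#' derives the category-specific companion reports: nitrogen pathway
#' profiles, Fe-uptake profiles, siderophore calls (when BGC records are
#' supplied), vitamin classifications and phosphorus profiles. Writes all
#' tables, an iTOL export, a plain-text summary and a run manifest into
#' `out_dir`. Deterministic: identical inputs produce byte-identical
#' outputs.
#'
#' @param annotations Named list of [genome_annotation()] objects.
#' @param catalog Trait catalog (default bundled).
#' @param bgcs Optional list of [bgc_record()] objects.
#' @param overrides Optional override data.frame ([read_overrides()]).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param references NIS reference panel for siderophore typing.
#' @return Invisibly, a list with `matrix`, `n_profiles`, `fe_profiles`,
#'   `p_profiles`, `vitamins`, `interactions`, `siderophores`, `summary`.
#' @export
consortium_call <- function(annotations, catalog = default_catalog(),
                            bgcs = NULL, overrides = NULL, out_dir = NULL,
                            references = nis_reference_panel()) {
  if (length(annotations) == 0) stop_fmt("no genomes supplied")
  matrix <- build_trait_matrix(annotations, catalog, overrides)
  n_profiles <- lapply(annotations, assign_n_pathways)
  fe_profiles <- lapply(annotations, classify_fe_uptake)
  p_profiles <- lapply(annotations, call_p_profile)
  vitamins <- vitamin_status_table(annotations)
  interactions <- interaction_table(annotations, bgcs, catalog, overrides)
  siderophores <- if (!is.null(bgcs) && length(bgcs) > 0)
    call_siderophores(bgcs, references) else NULL
  summary <- consortium_summary(matrix, n_profiles, fe_profiles, p_profiles,
                                vitamins, siderophores)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_matrix(matrix, file.path(out_dir, "trait_matrix.tsv"))
    write_itol_binary(matrix, file.path(out_dir, "trait_matrix_itol.txt"))
    write_tsv(n_profile_table(n_profiles),
              file.path(out_dir, "nitrogen_profiles.tsv"))
    write_tsv(fe_profile_table(fe_profiles),
              file.path(out_dir, "fe_profiles.tsv"))
    write_tsv(p_profile_table(p_profiles),
              file.path(out_dir, "p_profiles.tsv"))
    write_tsv(vitamins, file.path(out_dir, "vitamin_status.tsv"))
    write_tsv(interactions, file.path(out_dir, "interaction_traits.tsv"))
    if (!is.null(siderophores))
      write_tsv(siderophores, file.path(out_dir, "siderophore_calls.tsv"))
    writeLines(summary$text, file.path(out_dir, "summary.txt"))
    write_run_manifest(
      file.path(out_dir, "run_manifest.json"),
      parameters = list(
        n_genomes = length(annotations),
        n_traits = length(catalog),
        n_bgcs = length(bgcs %||% list()),
        overrides = nrow(overrides %||% data.frame())),
      outputs = c("trait_matrix.tsv", "trait_matrix_completeness.tsv",
                  "trait_matrix_itol.txt", "nitrogen_profiles.tsv",
                  "fe_profiles.tsv", "p_profiles.tsv", "vitamin_status.tsv",
                  "interaction_traits.tsv",
                  if (!is.null(siderophores)) "siderophore_calls.tsv",
                  "summary.txt"))
  }
  invisible(list(matrix = matrix, n_profiles = n_profiles,
                 fe_profiles = fe_profiles, p_profiles = p_profiles,
                 vitamins = vitamins, interactions = interactions,
                 siderophores = siderophores, summary = summary))
}

#' Summarize a consortium run
#'
#' Headline counts over the computed profiles: genomes capable of N2
#' fixation, collective completeness of denitrification, vitamin
#' auxotrophy, phosphorus-transporter interpretations, siderophore
#' producers.
#'
#' @param matrix A `trait_matrix`.
#' @param n_profiles,fe_profiles,p_profiles Lists of per-genome profiles.
#' @param vitamins data.frame from [vitamin_status_table()].
#' @param siderophores Optional data.frame from [call_siderophores()].
#' @return List with `stats` (named numbers) and `text` (report lines).
#' @export
consortium_summary <- function(matrix, n_profiles, fe_profiles, p_profiles,
                               vitamins, siderophores = NULL) {
  n_genomes <- nrow(matrix$status)
  n_fixers <- sum(vapply(n_profiles, function(p)
    p$n2_fixation == "present", logical(1)))
  denit <- consortium_denitrification_completeness(n_profiles)
  aux <- stats::aggregate(classification ~ genome_id, data = vitamins,
                          FUN = function(x) any(x == "auxotroph"))
  n_auxotroph <- sum(aux$classification)
  interp <- vapply(p_profiles, function(p)
    p$phn_transporter_interpretation, character(1))
  n_phn <- sum(interp != "absent")
  n_phosphonate <- sum(interp %in% c("phosphonate_linked", "both"))
  n_phosphite <- sum(interp %in% c("phosphite_linked", "both"))
  n_sid_genomes <- if (is.null(siderophores)) 0L else
    length(unique(siderophores$genome_id[siderophores$kind != "none"]))

  stats <- list(
    n_genomes = n_genomes,
    n_n2_fixing = n_fixers,
    denitrification_collectively_complete = denit$collectively_complete,
    n_auxotrophic_any_vitamin = n_auxotroph,
    n_phn_transporter = n_phn,
    n_phosphonate_linked = n_phosphonate,
    n_phosphite_linked = n_phosphite,
    n_siderophore_producer_genomes = n_sid_genomes)

  text <- c(
    sprintf("genomes analyzed: %d", n_genomes),
    sprintf("genomes with full N2 fixation module: %d", n_fixers),
    sprintf("denitrification collectively complete: %s",
            if (denit$collectively_complete) "yes" else "no"),
    sprintf("genomes auxotrophic for >=1 vitamin: %d", n_auxotroph),
    sprintf("genomes with phosphonate/phosphite transporter: %d", n_phn),
    sprintf("  of which phosphonate-linked: %d", n_phosphonate),
    sprintf("  of which phosphite-linked: %d", n_phosphite),
    sprintf("genomes with siderophore BGC calls: %d", n_sid_genomes))
  list(stats = stats, text = text)
}

# Manifest for reproducibility; no timestamps or absolute paths, so
# repeated runs of the same inputs are byte-identical.
write_run_manifest <- function(path, parameters, outputs,
                               seed = NULL) {
  manifest <- list(
    tool = "trichotraits",
    version = as.character(utils::packageVersion("trichotraits")),
    parameters = parameters,
    outputs = as.list(outputs))
  if (!is.null(seed)) manifest$seed <- seed
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
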