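# Vitamin B1/B7/B12 biosynthesis, uptake, and auxotrophy classification.
#
# A genome is auxotrophic for a vitamin when it lacks the biosynthesis
# pathway but carries an uptake system for it: uptake without
# biosynthesis implies dependence on an external producer.

VITAMIN_GENE_SETS <- list(
  B1 = list(
    biosynthesis = c("K00946", "K00788", "K03149", "K00941", "K03147"),
    marker = "K02064",                      # thiB binding subunit
    companions = c("K02063", "K02062"),     # thiPQ permease/ATPase
    companion_required = TRUE),
  B7 = list(
    biosynthesis = c("K01012", "K01935", "K00833", "K00652"),
    marker = "K03523",                      # bioY binding subunit
    companions = c("K16783", "K16784",      # bioNM
                   "K16785", "K16786", "K16787"),  # efcTA1A2
    companion_required = TRUE),
  B12 = list(
    biosynthesis = c("K00798", "K19221", "K02232", "K00768", "K02225",
                     "K02227", "K02231", "K02233", "K02226"),
    marker = "K16092",                      # btuB TBDT receptor
    companions = c("K06858", "K25034",      # btuF
                   "K06074", "K06073"),     # btuCD
    companion_required = FALSE))            # btuB alone marks putative uptake

#' Classify a genome's status for one B vitamin
#'
#' Biosynthesis is called by the generic 50% completeness rule on the
#' vitamin's module; uptake is `present` iff the binding-subunit marker
#' gene is found and, for B1/B7, at least one companion transporter gene
#' accompanies it (for B12 the btuB receptor alone suffices, with
#' btuF/btuCD recorded as supporting evidence). Classification:
#' `prototroph` (biosynthesis only), `self_and_uptake` (both),
#' `auxotroph` (uptake without biosynthesis), `neither`.
#'
#' @param genome A [genome_annotation()].
#' @param vitamin `"B1"`, `"B7"` or `"B12"`.
#' @return A `vitamin_status`: vitamin, `biosynthesis`, `uptake`,
#'   `classification`, and the supporting `evidence` ids found.
#' @export
call_vitamin_status <- function(genome, vitamin) {
  if (!vitamin %in% names(VITAMIN_GENE_SETS))
    stop_fmt("unknown vitamin '%s' (expected B1, B7 or B12)", vitamin)
  def <- VITAMIN_GENE_SETS[[vitamin]]
  have <- ids_present(genome)

  bio_frac <- length(intersect(def$biosynthesis, have)) /
    length(def$biosynthesis)
  biosynthesis <- if (bio_frac >= 0.5) "present" else "absent"

  marker_ok <- def$marker %in% have
  companion_ok <- !def$companion_required || any(def$companions %in% have)
  uptake <- if (marker_ok && companion_ok) "present"
            else if (marker_ok || any(def$companions %in% have)) "putative"
            else "absent"

  classification <- classify_vitamin(biosynthesis, uptake)
  structure(
    list(genome_id = genome$genome_id, vitamin = vitamin,
         biosynthesis = biosynthesis, biosynthesis_completeness = bio_frac,
         uptake = uptake, classification = classification,
         evidence = intersect(c(def$biosynthesis, def$marker,
                                def$companions), have)),
    class = "vitamin_status")
}

# Pure function of the two statuses; auxotroph <=> biosynthesis not
# present AND uptake present.
classify_vitamin <- function(biosynthesis, uptake) {
  bio <- biosynthesis == "present"
  up <- uptake == "present"
  if (bio && up) "self_and_uptake"
  else if (bio) "prototroph"
  else if (up) "auxotroph"
  else "neither"
}

#' Vitamin status table for a genome collection
#'
#' @param genomes Named list of [genome_annotation()] objects.
#' @param vitamins Vitamins to classify (default all three).
#' @return data.frame with one row per (genome, vitamin).
#' @export
vitamin_status_table <- function(genomes, vitamins = c("B1", "B7", "B12")) {
  rows <- list()
  for (g in genomes) for (v in vitamins) {
    s <- call_vitamin_status(g, v)
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = s$genome_id, vitamin = v,
      biosynthesis = s$biosynthesis, uptake = s$uptake,
      classification = s$classification, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
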