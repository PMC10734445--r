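# Bacterial- and particle-interaction traits: AHL biosynthesis, quorum
# sensing regulation, secretion, motility/adhesion and metal response.
# All but the AHL rule are config-driven gene sets routed through the
# generic engine; AHL synthases are luxI-family proteins recognized by
# the PF00765 domain, which may sit inside a secondary-metabolite
# cluster rather than the primary annotation.

#' Call interaction traits for a genome
#'
#' Evaluates every `interaction`-category trait in the catalog through
#' the generic engine, then augments the AHL call with BGC evidence:
#' AHL biosynthesis is `present` iff a PF00765-bearing gene occurs in the
#' genome annotation or among the genes of any of its BGC records.
#'
#' @param genome A [genome_annotation()].
#' @param bgcs Optional list of [bgc_record()] objects for this genome
#'   (records belonging to other genomes are ignored).
#' @param catalog Trait catalog (default bundled).
#' @param overrides Optional override data.frame.
#' @return Named character vector of statuses, one per interaction trait.
#' @export
call_interaction_traits <- function(genome, bgcs = NULL,
                                    catalog = default_catalog(),
                                    overrides = NULL) {
  traits <- Filter(function(d) d$category == "interaction", catalog)
  status <- vapply(traits, function(tr)
    call_trait(genome, tr, overrides)$status, character(1))
  if ("ahl_biosynthesis" %in% names(status) && !is.null(bgcs)) {
    own <- Filter(function(b) b$genome_id == genome$genome_id, bgcs)
    in_bgc <- any(vapply(own, function(b)
      any(vapply(b$genes, function(g)
        "PF00765" %in% g$tags, logical(1))), logical(1)))
    if (in_bgc) status[["ahl_biosynthesis"]] <- "present"
  }
  status
}

interaction_table <- function(genomes, bgcs = NULL,
                              catalog = default_catalog(),
                              overrides = NULL) {
  rows <- lapply(genomes, function(g) {
    st <- call_interaction_traits(g, bgcs, catalog, overrides)
    cbind(data.frame(genome_id = g$genome_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(st), stringsAsFactors = FALSE,
                        check.names = FALSE))
  })
  do.call(rbind, rows)
}
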