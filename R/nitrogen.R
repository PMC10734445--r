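# Marker-gene assignment of nitrate/nitrite reductases to N2 fixation,
# assimilatory (ANRA) and dissimilatory (DNRA) nitrate reduction to
# ammonium, and the four denitrification steps.
#
# KEGG's pathway map largely follows E. coli gene-pathway associations,
# which are a poor guide for marine taxa; reductases shared between
# pathways are therefore re-assigned using marker genes: nirS/nirK mark
# denitrification, nrfA is diagnostic for DNRA, nasA (with narB, nirA)
# marks assimilatory nitrate reduction.

#' The twelve nitrogen gene groups
#'
#' KEGG ortholog ids of the gene groups used in N-pathway assignment.
#' narGHI is pinned to the dissimilatory subunits {K00370, K00371, K00374};
#' nasA is K00372 (the assimilatory reductase marker).
#'
#' @return Named list of character vectors.
#' @export
n_gene_groups <- function() {
  list(
    nif = c("K02588", "K02591", "K02586", "K00531"),
    napAB = c("K02567", "K02568"),
    narGHI = c("K00370", "K00371", "K00374"),
    narB = "K00367",
    nasA = "K00372",
    nrfAH = c("K15876", "K03385"),
    nirA = "K00366",
    nirBD = c("K00362", "K00363"),
    nirS = "K15864",
    nirK = "K00368",
    norBC = c("K04561", "K02305"),
    nosZ = "K00376")
}

#' Nitrogen gene inventory of a genome
#'
#' Per-gene copy counts for all N-cycle genes plus group-level presence.
#' A multi-gene group counts as present at >= 50% of its member genes
#' (the generic completeness rule); single-gene groups require their gene.
#'
#' @param genome A [genome_annotation()].
#' @return List with `counts` (named integer per gene), `gene_present`
#'   (named logical per gene) and `group_present` (named logical per group).
#' @export
n_gene_inventory <- function(genome) {
  groups <- n_gene_groups()
  all_genes <- unlist(groups, use.names = FALSE)
  counts <- id_counts(genome)
  gene_counts <- stats::setNames(integer(length(all_genes)), all_genes)
  hit <- intersect(all_genes, names(counts))
  gene_counts[hit] <- counts[hit]
  gene_present <- gene_counts > 0
  group_present <- vapply(groups, function(gs) {
    mean(gene_present[gs]) >= 0.5
  }, logical(1))
  list(counts = gene_counts, gene_present = gene_present,
       group_present = group_present)
}

#' Assign nitrogen pathways to a genome
#'
#' Deterministic rule order:
#' 1. N2 fixation is `present` only with the full nif module (all four
#'    ids; with `nif_strict = FALSE`, K00531 is treated as
#'    fixation-associated but not required).
#' 2. nirS or nirK mark denitrification: the nitrite-to-NO step becomes
#'    `present` and any napAB/narGHI group is assigned to denitrification
#'    (nitrate-to-nitrite step `present`).
#' 3. DNRA is `present` iff nrfA (K03385) is found; nrfH strengthens the
#'    evidence but is neither required nor sufficient. Without a
#'    denitrification marker, napAB/narGHI are attached to DNRA.
#' 4. ANRA: `present` with an assimilatory nitrate reductase (nasA or
#'    narB) plus a nitrite reductase (nirA or nirBD); `putative` when only
#'    nasA, narB or nirA occur. nirBD is assigned to ANRA when nasA is
#'    present; alone it remains unassigned putative nitrite reduction.
#' 5. norBC: NO-to-N2O `present` with a denitrification marker, `putative`
#'    without one (norB can serve assimilation-linked NO detoxification).
#' 6. nosZ alone marks the terminal N2O-to-N2 step (denitrification is
#'    modular; steps are independent).
#' 7. Nitrate reductases with no downstream marker stay unassigned
#'    (`putative` first step).
#'
#' @param genome A [genome_annotation()].
#' @param nif_strict Require all four nif module ids (default `TRUE`).
#' @return An `n_pathway_profile`: statuses for `n2_fixation`, `anra`,
#'   `dnra`, the 4-vector `denitrification_steps`
#'   (NO3->NO2, NO2->NO, NO->N2O, N2O->N2) and `reductase_assignments`.
#' @export
assign_n_pathways <- function(genome, nif_strict = TRUE) {
  inv <- n_gene_inventory(genome)
  gp <- inv$group_present
  gene <- inv$gene_present

  nif_ids <- if (nif_strict) n_gene_groups()$nif else
    c("K02588", "K02591", "K02586")
  n2_fixation <- if (all(gene[nif_ids])) "present" else "absent"

  denit_marker <- gp[["nirS"]] || gp[["nirK"]]
  nitrate_red <- gp[["napAB"]] || gp[["narGHI"]]
  nrfA <- gene[["K03385"]]

  assignments <- character(0)
  steps <- stats::setNames(rep("absent", 4),
                           c("NO3_to_NO2", "NO2_to_NO", "NO_to_N2O",
                             "N2O_to_N2"))

  if (denit_marker) {
    steps["NO2_to_NO"] <- "present"
    for (grp in c("nirS", "nirK")[c(gp[["nirS"]], gp[["nirK"]])])
      assignments[grp] <- "denitrification"
  }

  if (nitrate_red) {
    target <- if (denit_marker) "denitrification"
              else if (nrfA) "DNRA"
              else "unassigned_putative"
    for (grp in c("napAB", "narGHI")[c(gp[["napAB"]], gp[["narGHI"]])])
      assignments[grp] <- target
    steps["NO3_to_NO2"] <- if (denit_marker) "present"
                           else if (nrfA) "absent"
                           else "putative"
  }

  dnra <- if (nrfA) "present" else "absent"
  if (nrfA) assignments["nrfAH"] <- "DNRA"

  anra_nitrate <- gp[["nasA"]] || gp[["narB"]]
  anra_nitrite <- gp[["nirA"]] || gp[["nirBD"]]
  anra <- if (anra_nitrate && anra_nitrite) "present"
          else if (anra_nitrate || gp[["nirA"]]) "putative"
          else "absent"
  for (grp in c("nasA", "narB", "nirA")[c(gp[["nasA"]], gp[["narB"]],
                                          gp[["nirA"]])])
    assignments[grp] <- "ANRA"
  if (gp[["nirBD"]])
    assignments["nirBD"] <- if (gp[["nasA"]]) "ANRA" else "unassigned_putative"

  if (gp[["norBC"]]) {
    steps["NO_to_N2O"] <- if (denit_marker) "present" else "putative"
    assignments["norBC"] <- if (denit_marker) "denitrification"
                            else "unassigned_putative"
  }
  if (gp[["nosZ"]]) {
    steps["N2O_to_N2"] <- "present"
    assignments["nosZ"] <- "denitrification"
  }

  structure(
    list(genome_id = genome$genome_id,
         n2_fixation = unname(n2_fixation),
         anra = anra, dnra = dnra,
         denitrification_steps = steps,
         reductase_assignments = assignments,
         inventory = inv),
    class = "n_pathway_profile")
}

#' @export
print.n_pathway_profile <- function(x, ...) {
  cat(sprintf("<n_pathway_profile> %s: N2fix=%s ANRA=%s DNRA=%s denit=[%s]\n",
              x$genome_id, x$n2_fixation, x$anra, x$dnra,
              paste(substr(x$denitrification_steps, 1, 1), collapse = "")))
  invisible(x)
}

#' Consortium-level denitrification step coverage
#'
#' Denitrification is frequently modular: no single genome need carry the
#' whole pathway, but the consortium may still complete it collectively.
#'
#' @param profiles List of `n_pathway_profile` objects.
#' @param include_putative Count putative step calls as coverage
#'   (default `FALSE`).
#' @return List with `step_genomes` (genome ids per step),
#'   `collectively_complete` (all four steps covered by >= 1 genome), and
#'   `complete_in_single_genome` (any genome covering all four).
#' @export
consortium_denitrification_completeness <- function(profiles,
                                                    include_putative = FALSE) {
  if (length(profiles) == 0) stop_fmt("no pathway profiles supplied")
  ok <- if (include_putative) c("present", "putative") else "present"
  step_names <- names(profiles[[1]]$denitrification_steps)
  step_genomes <- lapply(step_names, function(s) {
    ids <- vapply(profiles, function(p) p$genome_id, character(1))
    ids[vapply(profiles, function(p) p$denitrification_steps[[s]] %in% ok,
               logical(1))]
  })
  names(step_genomes) <- step_names
  covered <- vapply(step_genomes, function(g) length(g) > 0, logical(1))
  single <- any(vapply(profiles, function(p)
    all(p$denitrification_steps %in% ok), logical(1)))
  list(step_genomes = step_genomes,
       collectively_complete = all(covered),
       complete_in_single_genome = single)
}

# Flat one-row-per-genome serialization used by report writers.
n_profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id,
               n2_fixation = p$n2_fixation,
               anra = p$anra, dnra = p$dnra,
               denit_NO3_to_NO2 = p$denitrification_steps[["NO3_to_NO2"]],
               denit_NO2_to_NO = p$denitrification_steps[["NO2_to_NO"]],
               denit_NO_to_N2O = p$denitrification_steps[["NO_to_N2O"]],
               denit_N2O_to_N2 = p$denitrification_steps[["N2O_to_N2"]],
               assignments = paste(sprintf("%s=%s",
                                           names(p$reductase_assignments),
                                           p$reductase_assignments),
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
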