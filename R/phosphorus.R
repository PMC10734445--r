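# Phosphorus metabolism: transporters, reduced-P metabolism and alkaline
# phosphatases, with disambiguation of the substrate-ambiguous
# phosphonate/phosphite transporter by adjacent metabolism genes.

P_GENE_SETS <- list(
  pstSCAB = c("K02036", "K02037", "K02038", "K02040"),
  pitA = "K03306",
  phn_transporter = c("K02041", "K02042", "K02044"),
  cp_lyase = c("K06162", "K06163", "K06164", "K06165", "K06166",
               "K05780", "K05781"),
  ptxD = "K18916",
  aep = c(phnA = "K19670", phnX = "K05306", phnW = "K03430"),
  ap = c(phoA = "K01077", phoX = "K07093", phoD = "K01113"))

#' Call a genome's phosphorus-metabolism profile
#'
#' Component statuses follow the generic 50% rule. KEGG annotation cannot
#' distinguish the phosphonate (phnCDE) from the phosphite (ptxABC)
#' transporter, so the transporter's substrate interpretation is inferred
#' from adjacent metabolism genes: phosphite dehydrogenase (ptxD) points
#' to phosphite, a C-P lyase or a complete 2-AEP hydrolysis route
#' (phnW plus phnX or phnA) to phosphonate, both together to `both`, and
#' a transporter with neither indicator stays `ambiguous`.
#'
#' @param genome A [genome_annotation()].
#' @return A `p_profile`: component statuses, `aep_partial` flag,
#'   per-gene alkaline phosphatase statuses and
#'   `phn_transporter_interpretation` in
#'   `{phosphonate_linked, phosphite_linked, both, ambiguous, absent}`.
#' @export
call_p_profile <- function(genome) {
  have <- ids_present(genome)
  frac <- function(ids) length(intersect(ids, have)) / length(ids)
  set_status <- function(ids) if (frac(ids) >= 0.5) "present" else "absent"

  pst <- set_status(P_GENE_SETS$pstSCAB)
  pit <- set_status(P_GENE_SETS$pitA)
  phn_t <- set_status(P_GENE_SETS$phn_transporter)
  cp <- set_status(P_GENE_SETS$cp_lyase)
  ptxd <- set_status(P_GENE_SETS$ptxD)

  aep <- P_GENE_SETS$aep
  aep_have <- intersect(aep, have)
  aep_complete <- ("K03430" %in% have) &&
    any(c("K05306", "K19670") %in% have)
  aep_partial <- length(aep_have) > 0 && !aep_complete
  aep_status <- if (aep_complete) "present"
                else if (aep_partial) "putative" else "absent"

  ap_status <- vapply(P_GENE_SETS$ap, function(id)
    if (id %in% have) "present" else "absent", character(1))

  phosphite <- ptxd == "present"
  phosphonate <- cp == "present" || aep_complete
  interp <- if (phn_t == "absent") "absent"
            else if (phosphite && phosphonate) "both"
            else if (phosphite) "phosphite_linked"
            else if (phosphonate) "phosphonate_linked"
            else "ambiguous"

  structure(
    list(genome_id = genome$genome_id,
         pstSCAB = pst, pitA = pit, phn_transporter = phn_t,
         phn_transporter_interpretation = interp,
         cp_lyase = cp, ptxD = ptxd,
         aep_hydrolysis = aep_status, aep_partial = aep_partial,
         alkaline_phosphatase = ap_status),
    class = "p_profile")
}

p_profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id, pstSCAB = p$pstSCAB, pitA = p$pitA,
               phn_transporter = p$phn_transporter,
               phn_interpretation = p$phn_transporter_interpretation,
               cp_lyase = p$cp_lyase, ptxD = p$ptxD,
               aep_hydrolysis = p$aep_hydrolysis,
               aep_partial = p$aep_partial,
               phoA = p$alkaline_phosphatase[["phoA"]],
               phoX = p$alkaline_phosphatase[["phoX"]],
               phoD = p$alkaline_phosphatase[["phoD"]],
               stringsAsFactors = FALSE)
  }))
}
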