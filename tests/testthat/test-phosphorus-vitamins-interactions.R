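phn <- c("K02041", "K02042", "K02044")
cp <- c("K06162", "K06163", "K06164", "K06165", "K06166", "K05780", "K05781")

test_that("the phn transporter is interpreted from adjacent metabolism genes", {
  lyase <- call_p_profile(toy_genome("g", kegg = c(phn, cp)))
  expect_equal(lyase$phn_transporter_interpretation, "phosphonate_linked")

  phosphite <- call_p_profile(toy_genome("g", kegg = c(phn, "K18916")))
  expect_equal(phosphite$phn_transporter_interpretation, "phosphite_linked")

  both <- call_p_profile(toy_genome("g", kegg = c(phn, cp, "K18916")))
  expect_equal(both$phn_transporter_interpretation, "both")

  alone <- call_p_profile(toy_genome("g", kegg = phn))
  expect_equal(alone$phn_transporter_interpretation, "ambiguous")

  none <- call_p_profile(toy_genome("g"))
  expect_equal(none$phn_transporter_interpretation, "absent")
})

test_that("partial 2-AEP pathways are flagged but not phosphonate-linked", {
  p <- call_p_profile(toy_genome("g", kegg = c(phn, "K03430")))  # phnW only
  expect_equal(p$aep_hydrolysis, "putative")
  expect_true(p$aep_partial)
  expect_equal(p$phn_transporter_interpretation, "ambiguous")

  complete <- call_p_profile(toy_genome("g", kegg = c(phn, "K03430",
                                                      "K05306")))
  expect_equal(complete$aep_hydrolysis, "present")
  expect_false(complete$aep_partial)
  expect_equal(complete$phn_transporter_interpretation, "phosphonate_linked")
})

test_that("interpretation is monotone: indicators never push toward ambiguous", {
  base <- call_p_profile(toy_genome("g", kegg = phn))
  expect_equal(base$phn_transporter_interpretation, "ambiguous")
  rank <- function(x) !x %in% c("ambiguous", "absent")
  expect_true(rank(call_p_profile(
    toy_genome("g", kegg = c(phn, "K18916")))$phn_transporter_interpretation))
  expect_true(rank(call_p_profile(
    toy_genome("g", kegg = c(phn, cp)))$phn_transporter_interpretation))
})

test_that("alkaline phosphatases are independent single-gene calls", {
  p <- call_p_profile(toy_genome("g", kegg = c("K01077", "K07093")))
  expect_equal(unname(p$alkaline_phosphatase["phoA"]), "present")
  expect_equal(unname(p$alkaline_phosphatase["phoX"]), "present")
  expect_equal(unname(p$alkaline_phosphatase["phoD"]), "absent")
})

b12_bio <- trichotraits:::VITAMIN_GENE_SETS$B12$biosynthesis

test_that("vitamin classification follows the auxotrophy definition", {
  # full biosynthesis for all three vitamins, no uptake -> prototroph x3
  host <- toy_genome("h", kegg = c(
    trichotraits:::VITAMIN_GENE_SETS$B1$biosynthesis,
    trichotraits:::VITAMIN_GENE_SETS$B7$biosynthesis, b12_bio))
  for (v in c("B1", "B7", "B12"))
    expect_equal(call_vitamin_status(host, v)$classification, "prototroph")

  # btuB + btuCD without biosynthesis -> B12 auxotroph
  aux <- call_vitamin_status(
    toy_genome("a", kegg = c("K16092", "K06074", "K06073")), "B12")
  expect_equal(aux$uptake, "present")
  expect_equal(aux$classification, "auxotroph")

  # neither biosynthesis nor uptake is NOT auxotrophy
  expect_equal(call_vitamin_status(toy_genome("n"), "B7")$classification,
               "neither")
  expect_error(call_vitamin_status(toy_genome("n"), "B9"), "unknown vitamin")
})

test_that("uptake marker rules differ between B1/B7 (companion required) and B12", {
  # thiB alone is not a B1 uptake system; thiB + one thiPQ gene is
  expect_false(call_vitamin_status(
    toy_genome("g", kegg = "K02064"), "B1")$uptake == "present")
  expect_equal(call_vitamin_status(
    toy_genome("g", kegg = c("K02064", "K02063")), "B1")$uptake, "present")
  # btuB alone marks putative B12 uptake
  expect_equal(call_vitamin_status(
    toy_genome("g", kegg = "K16092"), "B12")$uptake, "present")
})

test_that("the 2x2 biosynthesis-by-uptake table matches the classification invariant", {
  for (v in c("B1", "B7", "B12")) {
    def <- trichotraits:::VITAMIN_GENE_SETS[[v]]
    uptake_ids <- c(def$marker, def$companions[1])
    cases <- list(
      list(ids = c(def$biosynthesis, uptake_ids), exp = "self_and_uptake"),
      list(ids = def$biosynthesis, exp = "prototroph"),
      list(ids = uptake_ids, exp = "auxotroph"),
      list(ids = character(0), exp = "neither"))
    for (cs in cases) {
      s <- call_vitamin_status(toy_genome("g", kegg = cs$ids), v)
      expect_equal(s$classification, cs$exp,
                   info = sprintf("%s / %s", v, cs$exp))
      # invariant: auxotroph <=> no biosynthesis AND uptake present
      expect_equal(s$classification == "auxotroph",
                   s$biosynthesis != "present" && s$uptake == "present")
    }
  }
})

test_that("interaction traits: AHL via PF00765, quorum sensing via luxR homologs", {
  ahl <- call_interaction_traits(toy_genome("g", pfam = "PF00765"))
  expect_equal(unname(ahl["ahl_biosynthesis"]), "present")

  qs <- call_interaction_traits(toy_genome("g", kegg = "K07782"))
  expect_equal(unname(qs["quorum_sensing_regulation"]), "present")
  expect_equal(unname(qs["ahl_biosynthesis"]), "absent")

  none <- call_interaction_traits(toy_genome("g"))
  expect_true(all(none == "absent"))
})

test_that("a PF00765 domain inside a BGC also yields an AHL call", {
  bgc <- bgc_record("g", "c", "ctg", 1, 2000, "other", genes = list(
    list(gene_id = "a", start = 1, end = 900, pf04183_count = 0,
         tags = "PF00765")))
  st <- call_interaction_traits(toy_genome("g"), bgcs = list(bgc))
  expect_equal(unname(st["ahl_biosynthesis"]), "present")
  # records of other genomes do not leak
  st2 <- call_interaction_traits(toy_genome("other"), bgcs = list(bgc))
  expect_equal(unname(st2["ahl_biosynthesis"]), "absent")
})
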