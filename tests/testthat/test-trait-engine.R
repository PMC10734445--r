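cat49 <- default_catalog()

test_that("module completeness counts distinct genes, not copies", {
  b1 <- cat49$vitB1_biosynthesis
  expect_equal(module_completeness(
    toy_genome("g", kegg = c("K00946", "K00788")), b1), 0.4)
  expect_equal(module_completeness(toy_genome("g"), b1), 0)
  expect_equal(module_completeness(
    toy_genome("g", kegg = b1$module_genes, copies = 3L), b1), 1)
})

test_that("marker genes are a determining factor for transporter presence", {
  up <- cat49$vitB1_uptake
  with_all <- call_trait(toy_genome("g", kegg = c("K02064", "K02063",
                                                  "K02062")), up)
  expect_equal(with_all$status, "present")
  no_marker <- call_trait(toy_genome("g", kegg = c("K02063", "K02062")), up)
  expect_false(no_marker$status == "present")
  expect_equal(no_marker$status, "putative")
  expect_match(no_marker$note, "K02064")
})

test_that("overrides replace the computed status and are flagged", {
  ov <- data.frame(genome_id = "g", trait_id = "vitB1_uptake",
                   forced_status = "absent",
                   reason = "curated out", stringsAsFactors = FALSE)
  tc <- call_trait(toy_genome("g", kegg = c("K02064", "K02063", "K02062")),
                   cat49$vitB1_uptake, overrides = ov)
  expect_equal(tc$status, "absent")
  expect_true(tc$override_applied)
  expect_error(
    build_trait_matrix(list(toy_genome("g")), cat49,
                       overrides = data.frame(
                         genome_id = "g", trait_id = "no_such_trait",
                         forced_status = "absent", reason = "x")),
    "unknown trait_id")
})

test_that("the 50% threshold boundary is inclusive and matches brute force on a 4-gene module", {
  tr <- trait_definition("toy4", "other",
                         module_genes = c("K00001", "K00002", "K00003",
                                          "K00004"))
  for (subset in all_subsets(tr$module_genes)) {
    got <- call_trait(toy_genome("g", kegg = subset), tr)$status
    expect_equal(got, oracle_status(subset, tr),
                 info = paste("subset:", paste(subset, collapse = ",")))
  }
  # boundary: exactly 2 of 4 present, one fewer absent
  expect_equal(call_trait(toy_genome("g", kegg = c("K00001", "K00002")),
                          tr)$status, "present")
  expect_equal(call_trait(toy_genome("g", kegg = "K00001"), tr)$status,
               "absent")
})

test_that("evidence below threshold is still recorded", {
  aep <- cat49$aep_hydrolysis
  tc <- call_trait(toy_genome("g", kegg = "K03430"), aep)
  expect_equal(tc$status, "putative")  # report_partial trait
  expect_equal(tc$evidence$id, "K03430")
  # a non-partial trait records evidence but stays absent
  tc2 <- call_trait(toy_genome("g", kegg = "K02036"), cat49$pst_transporter)
  expect_equal(tc2$status, "absent")
  expect_equal(tc2$evidence$id, "K02036")
})

test_that("adding genes never decreases completeness nor demotes present to absent", {
  set.seed(7)
  traits <- cat49[sample(length(cat49), 12)]
  for (tr in traits) {
    universe <- trichotraits:::trait_id_universe(tr)
    for (rep in 1:5) {
      base_ids <- universe[stats::runif(length(universe)) < 0.5]
      extra <- union(base_ids, sample(universe, 1))
      g_base <- toy_genome("g", kegg = intersect(base_ids, tr$module_genes),
                           pfam = intersect(base_ids, tr$pfam_markers))
      g_more <- toy_genome("g", kegg = intersect(extra, tr$module_genes),
                           pfam = intersect(extra, tr$pfam_markers))
      expect_gte(module_completeness(g_more, tr),
                 module_completeness(g_base, tr))
      if (call_trait(g_base, tr)$status == "present")
        expect_true(call_trait(g_more, tr)$status == "present")
    }
  }
})

test_that("permuting genome input order only permutes matrix rows", {
  cfg <- sim_config(n_genomes = 5, seed = 33)
  sim <- generate_annotations(cfg)
  m1 <- build_trait_matrix(sim$annotations, cat49)
  m2 <- build_trait_matrix(rev(sim$annotations), cat49)
  expect_equal(m2$status[rownames(m1$status), ], m1$status)
})
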