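test_that("marker-gene reassignment reproduces the anchored pathway cases", {
  # nirBD coupled to nasA -> ANRA, not DNRA
  p <- assign_n_pathways(n_group_genome(c("nirBD", "nasA")))
  expect_equal(p$anra, "present")
  expect_equal(p$dnra, "absent")
  expect_equal(unname(p$reductase_assignments["nirBD"]), "ANRA")

  # nrfAH is diagnostic for DNRA; no denitrification follows from it
  p <- assign_n_pathways(n_group_genome("nrfAH"))
  expect_equal(p$dnra, "present")
  expect_true(all(p$denitrification_steps == "absent"))

  # diazotroph host with nirA + norB but no nirS/nirK: fixation present,
  # assimilation-linked nitrite reduction, NO-reduction only putative
  p <- assign_n_pathways(n_group_genome(c("nif", "nirA", "norBC")))
  expect_equal(p$n2_fixation, "present")
  expect_equal(p$anra, "putative")
  expect_equal(unname(p$denitrification_steps["NO_to_N2O"]), "putative")
  expect_equal(unname(p$denitrification_steps["NO2_to_NO"]), "absent")

  # nirK marker pulls narGHI into denitrification steps 1-2
  p <- assign_n_pathways(n_group_genome(c("narGHI", "nirK")))
  expect_equal(unname(p$denitrification_steps["NO3_to_NO2"]), "present")
  expect_equal(unname(p$denitrification_steps["NO2_to_NO"]), "present")
  expect_equal(unname(p$reductase_assignments["narGHI"]), "denitrification")

  # nosZ alone: terminal step only (modularity)
  p <- assign_n_pathways(n_group_genome("nosZ"))
  expect_equal(unname(p$denitrification_steps["N2O_to_N2"]), "present")
  expect_true(all(p$denitrification_steps[1:3] == "absent"))

  # empty genome: everything absent
  p <- assign_n_pathways(toy_genome("empty"))
  expect_equal(p$n2_fixation, "absent")
  expect_equal(p$anra, "absent")
  expect_equal(p$dnra, "absent")
  expect_true(all(p$denitrification_steps == "absent"))
})

test_that("nitrate reductases are attached to DNRA only without a denitrification marker", {
  with_marker <- assign_n_pathways(n_group_genome(c("napAB", "nrfAH",
                                                    "nirS")))
  expect_equal(unname(with_marker$reductase_assignments["napAB"]),
               "denitrification")
  without <- assign_n_pathways(n_group_genome(c("napAB", "nrfAH")))
  expect_equal(unname(without$reductase_assignments["napAB"]), "DNRA")
  unassigned <- assign_n_pathways(n_group_genome("napAB"))
  expect_equal(unname(unassigned$reductase_assignments["napAB"]),
               "unassigned_putative")
  expect_equal(unname(unassigned$denitrification_steps["NO3_to_NO2"]),
               "putative")
})

test_that("nrfH alone neither implies DNRA nor n2 fixation from a partial nif module", {
  p <- assign_n_pathways(toy_genome("g", kegg = "K15876"))  # nrfH only
  expect_equal(p$dnra, "absent")
  partial_nif <- toy_genome("g", kegg = c("K02588", "K02591", "K02586"))
  expect_equal(assign_n_pathways(partial_nif)$n2_fixation, "absent")
  expect_equal(assign_n_pathways(partial_nif,
                                 nif_strict = FALSE)$n2_fixation, "present")
})

test_that("pathway assignment is independent of gene input order and exclusive", {
  set.seed(11)
  groups <- names(n_gene_groups())
  for (rep in 1:25) {
    sel <- groups[stats::runif(12) < 0.4]
    genes <- unlist(n_gene_groups()[sel], use.names = FALSE)
    p1 <- assign_n_pathways(toy_genome("a", kegg = genes))
    p2 <- assign_n_pathways(toy_genome("a", kegg = sample(genes)))
    p1$genome_id <- p2$genome_id <- NULL
    expect_equal(p1[c("n2_fixation", "anra", "dnra",
                      "denitrification_steps", "reductase_assignments")],
                 p2[c("n2_fixation", "anra", "dnra",
                      "denitrification_steps", "reductase_assignments")])
    # napAB/narGHI carry exactly one pathway label each
    asg <- p1$reductase_assignments
    for (grp in intersect(names(asg), c("napAB", "narGHI")))
      expect_length(asg[grp], 1)
  }
})

test_that("consortium denitrification coverage detects modular completion", {
  mk <- function(id, sel) assign_n_pathways(n_group_genome(sel, id))
  profiles <- list(mk("g1", c("narGHI", "nirK")),   # steps 1-2
                   mk("g2", c("norBC", "nirS")),    # steps 2-3
                   mk("g3", "nosZ"))                # step 4
  cc <- consortium_denitrification_completeness(profiles)
  expect_true(cc$collectively_complete)
  expect_false(cc$complete_in_single_genome)
  expect_equal(cc$step_genomes$N2O_to_N2, "g3")

  solo <- list(mk("g1", c("narGHI", "nirS", "norBC", "nosZ")))
  cc2 <- consortium_denitrification_completeness(solo)
  expect_true(cc2$collectively_complete)
  expect_true(cc2$complete_in_single_genome)

  no4 <- consortium_denitrification_completeness(profiles[1:2])
  expect_false(no4$collectively_complete)
  expect_error(consortium_denitrification_completeness(list()), "no pathway")
})
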