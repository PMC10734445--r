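test_that("Fe-uptake classification follows single receptor markers", {
  host <- classify_fe_uptake(toy_genome("h", kegg = c("K04759", "K02012")))
  expect_equal(host$fe2, "present")
  expect_equal(host$fe3, "present")
  expect_equal(host$heme, "absent")
  expect_equal(host$citrate, "absent")
  expect_equal(host$siderophore_receptor, "absent")
  expect_false(host$ambiguity_flag)

  sid <- classify_fe_uptake(toy_genome("s", kegg = "K02016"))
  expect_equal(sid$siderophore_receptor, "present")
  expect_true(sid$ambiguity_flag)

  none <- classify_fe_uptake(toy_genome("n"))
  expect_true(all(c(none$fe2, none$fe3, none$heme, none$citrate,
                    none$siderophore_receptor) == "absent"))
})

test_that("TonB system is graded complete / partial / absent", {
  expect_equal(classify_fe_uptake(
    toy_genome("g", kegg = c("K03832", "K03561", "K03559")))$tonb_system,
    "complete")
  expect_equal(classify_fe_uptake(
    toy_genome("g", kegg = "K03832"))$tonb_system, "partial")
  expect_equal(classify_fe_uptake(toy_genome("g"))$tonb_system, "absent")
})

test_that("BGC records validate spans and round-trip through JSON", {
  bgc <- bgc_record("g1", "c1", "ctg", 1, 5000, "NIS",
                    genes = list(list(gene_id = "a", start = 10, end = 900,
                                      pf04183_count = 1, tags = character(0))),
                    synthetase_sequence = "MKLVT")
  path <- withr::local_tempfile(fileext = ".json")
  write_bgc_json(list(bgc), path)
  back <- read_bgc_json(path)
  expect_equal(back[[1]], bgc)

  expect_error(bgc_record("g", "c", "ctg", 1, 100, "NIS",
                          genes = list(list(gene_id = "a", start = 10,
                                            end = 900, pf04183_count = 0))),
               "outside the cluster span")
  expect_error(bgc_record("g", "c", "ctg", 1, 100, "weird"), "cluster_class")
})

test_that("NIS calling gates on total PF04183 count", {
  panel <- nis_reference_panel()
  two <- bgc_record("g", "c1", "ctg", 1, 5000, "NIS", genes = list(
    list(gene_id = "a", start = 1, end = 900, pf04183_count = 1),
    list(gene_id = "b", start = 1000, end = 1900, pf04183_count = 1)),
    synthetase_sequence = panel$sequence[panel$type == "petrobactin"])
  call <- call_nis_siderophore(two, panel)
  expect_equal(call$kind, "NIS")
  expect_equal(call$iuc_domain_count, 2L)
  expect_equal(call$reference_type, "petrobactin")
  expect_true(call$photolabile)
  expect_equal(call$reference_identity_pct, 100)

  zero <- bgc_record("g", "c2", "ctg", 1, 5000, "other", genes = list(
    list(gene_id = "a", start = 1, end = 900, pf04183_count = 0)))
  expect_equal(call_nis_siderophore(zero, panel)$kind, "none")
})

test_that("nearest-reference typing recovers a 10%-mutated panel entry", {
  panel <- nis_reference_panel()
  set.seed(5)
  mutated <- trichotraits:::mutate_aa(
    panel$sequence[panel$type == "vibrioferrin"], 0.1)
  bgc <- bgc_record("g", "c", "ctg", 1, 5000, "NIS", genes = list(
    list(gene_id = "a", start = 1, end = 900, pf04183_count = 1)),
    synthetase_sequence = mutated)
  call <- call_nis_siderophore(bgc, panel)
  expect_equal(call$reference_type, "vibrioferrin")
  # brute-force argmax over the panel agrees
  ids <- vapply(panel$sequence, function(s) sequence_identity(mutated, s),
                numeric(1))
  expect_equal(call$nearest_reference, panel$name[which.max(ids)])
  expect_false(call$tie)
})

test_that("NRPS siderophore calls require class and co-located receptor", {
  mk <- function(class, tags) bgc_record("g", "c", "ctg", 1, 5000, class,
    genes = list(list(gene_id = "a", start = 1, end = 900,
                      pf04183_count = 0, tags = tags)))
  expect_equal(call_nrps_siderophore(
    mk("NRPS", "TBDT_siderophore_receptor"))$kind, "NRPS_putative")
  expect_equal(call_nrps_siderophore(mk("NRPS", character(0)))$kind, "none")
  expect_equal(call_nrps_siderophore(
    mk("other", "TBDT_siderophore_receptor"))$kind, "none")
})

test_that("pairwise identity is symmetric, 100 on self, and decays with mutation load", {
  panel <- nis_reference_panel()
  a <- panel$sequence[1]
  expect_equal(sequence_identity(a, a), 100)
  b <- panel$sequence[2]
  expect_equal(sequence_identity(a, b), sequence_identity(b, a))
  expect_error(sequence_identity("MK!", a), "alphabet")

  set.seed(9)
  mean_id <- vapply(c(0.05, 0.2, 0.4), function(rate) {
    mean(vapply(1:5, function(i)
      sequence_identity(trichotraits:::mutate_aa(a, rate), a), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_id) < 0))
})

test_that("siderophore calls depend only on a genome's own BGC records", {
  panel <- nis_reference_panel()
  own <- bgc_record("g1", "c1", "ctg", 1, 5000, "NIS", genes = list(
    list(gene_id = "a", start = 1, end = 900, pf04183_count = 1)))
  other <- bgc_record("g2", "c2", "ctg", 1, 5000, "NRPS", genes = list(
    list(gene_id = "b", start = 1, end = 900, pf04183_count = 0,
         tags = "TBDT_siderophore_receptor")))
  calls <- call_siderophores(list(own, other), panel)
  expect_equal(calls$kind[calls$genome_id == "g1"], "NIS")
  expect_equal(calls$kind[calls$genome_id == "g2"], "NRPS_putative")
})
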