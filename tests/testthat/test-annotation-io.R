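test_that("annotation TSV reading groups rows by genome and keeps gene order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\tgene_id\tcontig\tstart\tend\tstrand\tkegg_ids\tpfam_ids",
    "g1\ta1\tc1\t1\t900\t+\tK00946\t",
    "g2\tb1\tc1\t1\t900\t-\tK00788;K03149\tPF00765",
    "g1\ta2\tc2\t100\t400\t+\t\t"), path)
  ann <- read_annotations(path)
  expect_length(ann, 2)
  expect_named(ann, c("g1", "g2"))
  expect_equal(ann$g1$genes$gene_id, c("a1", "a2"))
  counts <- trichotraits:::id_counts(ann$g2)
  expect_equal(counts[c("K00788", "K03149", "PF00765")],
               c(K00788 = 1L, K03149 = 1L, PF00765 = 1L))
})

test_that("malformed rows and missing columns are rejected informatively", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\tgene_id\tcontig\tstart\tend\tstrand\tkegg_ids\tpfam_ids",
    "g1\ta1\tc1\t1\t900\t+\tK00946\t",
    "g1\ta2\tc1\t500\t200\t+\t\t"), path)
  expect_error(read_annotations(path), "row 2")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tgene_id\tcontig\tstart\tend\tstrand\tkegg_ids",
               "g1\ta1\tc1\t1\t900\t+\tK00946"), path2)
  expect_error(read_annotations(path2), "pfam_ids")

  expect_error(
    toy_genome("g1", kegg = "K00946") |>
      (\(g) genome_annotation("g1", rbind(g$genes, g$genes)))(),
    "duplicate gene_id")
})

test_that("annotations round-trip through TSV and are row-order independent", {
  cfg <- sim_config(n_genomes = 4, seed = 101)
  sim <- generate_annotations(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(sim$annotations, path)
  back <- read_annotations(path)
  expect_equal(back, sim$annotations, ignore_attr = FALSE)

  # permuting the rows changes nothing but genome order of first appearance
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  set.seed(1)
  perm <- df[sample(nrow(df)), ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(perm, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back2 <- read_annotations(path2)
  for (g in names(back)) {
    ord <- back2[[g]]$genes[order(back2[[g]]$genes$gene_id), ]
    rownames(ord) <- NULL
    ref <- back[[g]]$genes[order(back[[g]]$genes$gene_id), ]
    rownames(ref) <- NULL
    expect_equal(ord, ref)
  }
})

test_that("bundled catalog loads with full category coverage and verified gene lists", {
  cat <- default_catalog()
  expect_gte(length(cat), 40)
  cats <- unique(vapply(cat, function(d) d$category, character(1)))
  expect_setequal(cats, c("iron", "phosphorus", "nitrogen", "vitamin",
                          "interaction"))
  expect_setequal(cat$vitB1_biosynthesis$module_genes,
                  c("K00946", "K00788", "K03149", "K00941", "K03147"))
  expect_setequal(cat$cp_lyase$module_genes,
                  c("K06162", "K06163", "K06164", "K06165", "K06166",
                    "K05780", "K05781"))
  expect_equal(cat$vitB1_biosynthesis$completeness_threshold, 0.5)
  # the synthetic generator relies on trait gene sets being disjoint
  ids <- unlist(lapply(cat, trichotraits:::trait_id_universe))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("catalog validation rejects empty, duplicated and inconsistent entries", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("traits: []", empty)
  expect_error(read_trait_catalog(empty), "no trait definitions")

  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("traits:",
               "  - {trait_id: x, category: iron, module_genes: [K00001]}",
               "  - {trait_id: x, category: iron, module_genes: [K00002]}"),
             dup)
  expect_error(read_trait_catalog(dup), "duplicate trait_id")

  expect_error(
    trait_definition("t", "iron", module_genes = "K00001",
                     marker_genes = "K00002"),
    "marker gene")
  expect_error(trait_definition("t", "iron"), "module_genes")
  expect_error(trait_definition("t", "iron", "K00001",
                                completeness_threshold = 0),
               "threshold")
})

test_that("catalogs round-trip through YAML", {
  cat <- default_catalog()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trait_catalog(cat, path)
  back <- read_trait_catalog(path)
  expect_equal(back, cat)
})

test_that("trait matrices round-trip through TSV with statuses and completeness", {
  genomes <- list(toy_genome("g1", kegg = c("K04759", "K02012")),
                  toy_genome("g2"))
  m <- build_trait_matrix(genomes, default_catalog())
  expect_equal(dim(m$status), c(2L, length(default_catalog())))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait_matrix(m, path)
  back <- read_trait_matrix(path)
  expect_equal(back$status, m$status)
  expect_equal(back$completeness, m$completeness, tolerance = 1e-6)
})

test_that("iTOL export encodes the three statuses numerically", {
  genomes <- list(toy_genome("g1", kegg = c("K04759")),
                  toy_genome("g2"))
  m <- build_trait_matrix(genomes, default_catalog())
  path <- withr::local_tempfile(fileext = ".txt")
  write_itol_binary(m, path)
  lines <- readLines(path)
  expect_equal(lines[1], "DATASET_BINARY")
  data_lines <- lines[(which(lines == "DATA") + 1):length(lines)]
  g1 <- strsplit(data_lines[1], "\t")[[1]]
  expect_equal(g1[1], "g1")
  expect_equal(g1[1 + which(colnames(m$status) == "fe2_uptake")], "1")
})

test_that("override files require justification and valid statuses", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\ttrait_id\tforced_status\treason",
               "g1\tfe2_uptake\tabsent\t"), path)
  expect_error(read_overrides(path), "reason")
  writeLines(c("genome_id\ttrait_id\tforced_status\treason",
               "g1\tfe2_uptake\tmaybe\tchecked manually"), path)
  expect_error(read_overrides(path), "forced_status")
})

test_that("high-quality flag honours both redundancy presets", {
  g <- genome_annotation("g", completeness_pct = 95, redundancy_pct = 7)
  expect_true(is_high_quality(g))
  expect_false(is_high_quality(g, preset = "strict"))
  expect_true(is.na(is_high_quality(genome_annotation("h"))))
})
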