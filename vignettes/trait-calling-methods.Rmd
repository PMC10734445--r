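---
title: "Methods: rule-based trait inference for Trichodesmium consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based trait inference for Trichodesmium consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichotraits)
```

# The inference problem

A *Trichodesmium* colony is a host–epibiont consortium: one dominant
nitrogen-fixing cyanobacterium and tens of low-abundance associated
bacteria, assembled from metagenomes as draft genomes (MAGs). The
scientific questions — who can take up which iron form, who makes
siderophores, who closes the denitrification pathway, who depends on whom
for vitamins — reduce to calling functional traits from per-genome gene
annotations. Annotations are noisy (incomplete bins, scanner dropouts,
ambiguous orthology), so the calls must be rule-based, conservative about
markers, explicit about uncertainty, and auditable. This package
implements those rules and everything needed to test them end-to-end.

Inputs are the *outputs* of upstream tools, as plain files: a gene-level
annotation TSV (KEGG orthologs and PFAM domains per gene), BGC records as
JSON (as produced by secondary-metabolite screening), count and peptide
TSVs, genome FASTA. Running the scanners, assemblers and spectral search
engines themselves is out of scope.

# The generic calling rule

Each trait is a gene set with optional markers
(see `default_catalog()`). For genome $g$ and trait $t$ with module genes
$M_t$ and threshold $\tau_t$:

$$c(g, t) = \frac{|\{m \in M_t : \mathrm{copies}_g(m) \ge 1\}|}{|M_t|}$$

* `present` iff $c \ge \tau_t$ **and** every marker gene (KEGG and PFAM)
  is found;
* `putative` iff $c \ge \tau_t$ with a marker missing, or — for traits
  flagged `report_partial` — any module gene found below threshold;
* `absent` otherwise.

Assumptions worth stating: copy counts never inflate completeness (a gene
in three copies counts once); traits are evaluated independently, so an
ortholog shared by two traits contributes to both (cross-trait
disambiguation is the job of the category modules); and `putative` is a
real third status, not a softened `absent` — partial pathways and
marker-less transporter hits are biologically informative and are kept
visible in the matrix and reports.

The default threshold is $\tau = 0.5$ and it is *inclusive*: a 4-gene
module with exactly 2 genes is present. The 50% completeness convention
is stated in the field without strictness; we chose inclusive, documented
it, and made it configurable per trait. Manual curation is replaced by an
override table that forces a cell's status and must give a reason; every
application is flagged in the call and logged in reports.

# Nitrogen pathway assignment

Nitrate and nitrite reductases recur across assimilatory nitrate
reduction (ANRA), dissimilatory nitrate reduction to ammonium (DNRA) and
denitrification, and KEGG's map largely follows *E. coli*; marker genes
re-assign them. The rule order in `assign_n_pathways()`:

1. N₂ fixation requires the **full** nif module
   {K02588, K02591, K02586, K00531} — stricter than the generic 50% rule,
   because only a complete pathway supports attribution of diazotrophy.
   With `nif_strict = FALSE` the accessory K00531 is not required.
2. *nirS*/*nirK* mark denitrification: nitrite→NO becomes present, and
   any napAB/narGHI group is re-assigned to denitrification step 1.
3. *nrfA* (K03385) is diagnostic for DNRA. *nrfH* strengthens evidence
   but alone implies nothing (an open call; we decided against, since
   only *nrfA* is diagnostic). Without a denitrification marker,
   napAB/narGHI attach to DNRA when *nrfA* is present.
4. ANRA is present with an assimilatory nitrate reductase
   (*nasA*/*narB*) plus a nitrite reductase (*nirA*/*nirBD*); putative
   when only part of that couple occurs. *nirBD* belongs to ANRA when
   *nasA* co-occurs, otherwise it stays unassigned putative nitrite
   reduction.
5. norBC gives step 3 — present with a denitrification marker, putative
   without one (NO reduction can serve assimilation-linked
   detoxification, the pattern seen in the diazotroph host).
6. *nosZ* marks the terminal step independently: denitrification is
   modular, and a consortium can complete the pathway collectively
   (`consortium_denitrification_completeness()`).
7. A nitrate reductase with no downstream marker stays unassigned, with
   a putative first step.

Two pinned identifier choices: the narGHI group is
{K00370, K00371, K00374} (the dissimilatory subunits; the printed range
"K00370–K00374" in common gene lists also spans the assimilatory
subunits) and *nasA* is K00372, the standard ortholog. Multi-gene groups
count as present at ≥ 50% of member genes, consistent with the generic
rule; the exhaustive rule-table test drives groups all-or-none, where
gene- and group-level semantics coincide.

# Siderophore classification

Fe-uptake receptors are single-marker calls (feoB K04759, afuA K02012,
hemR K16087, fecA K16091, fevS K02016); the K02016 call always carries an
ambiguity flag because its KEGG annotation does not separate siderophore
from vitamin-B12 substrates. The TonB/ExbB/ExbD system is graded
complete/partial/absent.

NIS-type clusters are gated on the iucA/iucC domain: a cluster is NIS iff
its member genes carry ≥ 1 PF04183 domain in total. Typing uses
nearest-reference assignment: global Needleman–Wunsch identity (BLOSUM62,
gap open 10, gap extend 0.5, identity = matches / alignment length —
pinned for reproducibility) of the cluster synthetase against a bundled
exemplar panel; the argmax reference contributes its type and
photolability/membrane metadata (petrobactin, vibrioferrin and
rhizoferrin carry a citrate moiety and are photolabile; metadata travels
with the panel, it is never sequence-derived). Ties are broken by panel
order and flagged. This replaces phylogenetic clustering of synthetases
(alignment + tree inference) with a deterministic desk-scale classifier —
a documented methodological substitution; with a panel of curated
synthetases it reproduces type labels, and the bundled panel is a
**synthetic** stand-in (seeded random sequences, labelled `_synthetic`)
sufficient for testing the machinery, not for classifying real clusters.
One genome may carry several clusters; calls are reported per cluster,
never collapsed per genome.

NRPS-type clusters are hard to separate from other secondary metabolites,
so the call is deliberately weak: `NRPS_putative` only when a
TonB-dependent siderophore receptor (SMCOG1082 tag) is co-located within
the cluster span; anything else is `none`.

# Vitamins, phosphorus, interactions

Auxotrophy is uptake-without-biosynthesis, per vitamin. Uptake for B1
(thiB + thiPQ) and B7 (bioY + bioNM or efcTA1A2) requires the
binding-subunit marker plus at least one companion transporter gene; for
B12 the btuB receptor alone marks (putative) uptake, with btuF/btuCD as
supporting evidence — an open call resolved in favour of the receptor as
marker. The B12 biosynthesis module's member orthologs are pinned in the
catalog as a nine-ID transcription of the standard
cobinamide→cobalamin set, since module membership is versioned upstream.
In the generic catalog the uptake thresholds (B1 0.5 of 3, B7 0.33 of 6,
B12 0.2 of 5) are chosen so the generic engine and the dedicated
marker+companion rule agree on every subset.

The phnCDE/ptxABC transporter cannot be resolved by orthology, so its
substrate is interpreted from adjacent metabolism: ptxD → phosphite, a
C-P lyase or complete 2-AEP route → phosphonate, both → `both`, neither →
`ambiguous`. The complete 2-AEP route is phnW plus (phnX or phnA) — the
acetaldehyde and acetate routes; the glycine route is excluded from the
default catalog because its ortholog set is not as standardized.
Fragments are reported (`aep_hydrolysis` is a `report_partial` trait) but
never count as phosphonate linkage.

AHL synthases are luxI-family proteins called by PF00765, in the genome
annotation or inside a BGC; functional assessment (binding-residue
checks) is out of scope — calls are presence-level. The remaining
interaction and metal-response traits are config-driven gene sets routed
through the generic engine; their exact membership is a per-study choice
and the bundled sets are editable transcriptions.

# Abundance, identity, proteomics

Relative abundance is per-sample count fractions with mean ± sd per
genome across samples — the form in which host dominance (e.g. "71% ± 6
of reads") is reported. Samples with zero totals are an error, named.

ANI uses MinHash bottom sketches of canonical (strand-collapsed) k-mers;
contig orientation of MAGs is arbitrary, hence canonicalization. With
bottom-sketch Jaccard $j$, the shared-k-mer fraction is
$w = 2j/(1+j)$ and

$$\mathrm{ANI} = 100 \cdot w^{1/k},$$

the exact inversion of the per-site survival model $w = (\mathrm{ANI}/100)^k$
under uniform substitution. The familiar first-order form
$100(1 + \ln(w)/k)$ agrees to first order but carries a ≈ 0.5 pp
downward bias at 90% identity, which would violate the estimator's own
accuracy contract; the exact form is used. Defaults k = 16 (exact 2-bit
arithmetic in doubles requires k ≤ 26), sketch 5000, seeded hashing.
Degenerate cases: $j = 0$ maps to ANI 0; identical sequences give exactly
100. Re-occurrence between two genome collections is greedy best-hit
one-to-one matching by descending ANI, ties broken by input order and
flagged, and a pair re-occurs iff ANI **strictly** exceeds 97.5 (the
bound is printed as "> 97.5%"; the threshold is configurable). The
matcher also accepts a precomputed identity matrix so full-alignment ANI
output from dedicated tools can be dropped in; the sketch estimator is
the bundled desk-scale stand-in.

NSAF: $\mathrm{saf}_i = c_i / L_i$, $\mathrm{nsaf}_i = \mathrm{saf}_i /
\sum_j \mathrm{saf}_j$, summing to 1 per sample. $L_i$ is the protein
sequence length in residues (the standard NSAF reading of
length-normalization; crediting by summed matched-peptide length is a
sensitivity variant better handled upstream of this contract). Spectral
counts are credited specificity-unaware by default — each peptide's count
to every matched protein, the widest-net convention — with a
`mode = "unique"` alternative. The mapping statistics are the fraction of
peptides matching exactly one protein and the fraction whose matches fall
in one genome.

# What the synthetic generator does and does not emulate

`sim_config()` defaults encode the study conditions this package targets:
52 genomes, one host at a 0.71 read fraction with 0.06 between-sample
jitter, three samples. `generate_annotations()` plants a status per
(genome, trait) and emits gene sets that realize it exactly: all module
genes for `present`, an above-threshold set missing one marker for
`putative`, a strictly below-threshold random subset for `absent`.
Dropout is applied per gene — not per trait — so partial pathways arise
naturally, mirroring real incomplete bins; decoy orthologs are drawn from
outside every catalog module. Planting requires the catalog's trait gene
sets to be pairwise disjoint (true of the bundled catalog and asserted in
tests). Epibiont prevalences in `consortium_preset()` are fixed,
field-plausible rates chosen once (receptors common, full biosynthesis
pathways rarer than uptake, denitrification markers sparse, no epibiont
diazotrophy).

What passing the planted-truth tests shows: the engine inverts the
generator's planting exactly — the rules are implemented as written.
What it does not show: robustness to the correlated, biased errors of
real annotation pipelines (systematically missed gene families,
mis-binned contigs, chimeric clusters), gene co-location structure
(planted coordinates are sequential placeholders), or realistic ortholog
sharing between traits. The generators validate machinery, not biology.

# Numerical and testing choices

* Thresholds are inclusive everywhere (≥); strictness appears only where
  the source convention is explicitly strict (re-occurrence > 97.5).
* All randomness is seeded; generator streams derive from one config seed
  with fixed per-generator offsets, so a full simulate→call→report run is
  byte-identical under one seed (manifests contain no timestamps or
  absolute paths).
* Exhaustive oracles: all 4096 nitrogen group combinations and every gene
  subset of catalog modules with ≤ 6 ids are checked against
  independently coded restatements of the rules; vitamin classification
  is checked against its 2×2 truth table per vitamin.
* Problem sizes in the test suite are desk-scale by design: 52-genome
  planted recovery, 40 kb sequence pairs at 90–100% identity with 20
  seeds per point for estimator accuracy, 20-seed mutation/recovery for
  NIS typing, 500-peptide tables.

# Known limitations

* Trait calls are presence-level genomics: no expression, activity or
  regulation. Proteomic overlays say a protein was detected, not that a
  pathway ran.
* The nearest-reference NIS classifier is only as good as its panel; the
  bundled panel is synthetic and exists to exercise the machinery.
* Sketch ANI assumes ungapped divergence by substitution; indel-rich or
  highly repetitive genomes need a full-alignment ANI matrix (supported
  via the precomputed-matrix input).
* The catalog transcribes published gene lists where printed and pins
  standard ortholog sets where not; both are versioned data, and studies
  with different annotation pipelines should review them before use.
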