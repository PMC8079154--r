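---
title: "Screening a kleptoplastic genome for algal gene transfer: methods and design"
author: "kleptoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a kleptoplastic genome for algal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kleptoscreen)
```

## The scientific problem

Sacoglossan sea slugs ingest siphonous green algae and sequester the algal
chloroplasts ("kleptoplasts") inside their intestinal cells, where the
plastids keep photosynthesizing for weeks to months although no algal
nucleus is present. Because most photosynthetic proteins are encoded in
the algal *nucleus* and turn over quickly, the long-standing hypothesis
was that the slug's own genome must have acquired algal genes by
horizontal gene transfer (HGT). Settling that question requires screening
an animal genome assembly for algae-derived sequence from several
independent directions at once, because each single line of evidence has
a characteristic failure mode:

* **homology hits to algae** can come from contaminating microalgal DNA
  on the animal's surface or gut, not from the nuclear genome;
* **assembled scaffolds** can be bacterial contaminants or organelle
  (kleptoplast/mitochondrial) DNA rather than nuclear sequence;
* **gene models** can be missed by the assembler, so raw reads must be
  screened too;
* and conversely, conserved host genes (kinases, photolyases,
  isomerases) resemble their algal orthologs enough to produce
  spurious "algal" hits.

`kleptoscreen` implements this multi-evidence screen as a set of small,
separately testable statistics over standard tabular inputs (BLAST-style
hit tables, GFF3 gene models, depth tables, orthogroup count matrices),
plus the downstream statistics used to nominate *kleptoplasty-related
molluskan* (KRM) genes — host gene families that expanded and are
up-regulated in the kleptoplast-rich tissue — once HGT has been ruled
out. A fully seeded synthetic-data generator provides genomes with
planted ground truth so that every stage's sensitivity and specificity
can be measured without any external database.

## HGT indices

For one query gene with a set of homology hits carrying bit scores $S$,
the screen computes

$$h = \max_{\text{prokaryote}} S - \max_{\text{eukaryote}} S,
\qquad
h_A = \max_{\text{algae}} S - \max_{\text{lophotrochozoa}} S.$$

$h$ is the classical alien index for prokaryote-derived HGT; $h_A$ is
its algal variant with the animal's own superphylum (Lophotrochozoa) as
the "self" group. Both are donor-minus-host, so large positive values
point away from the host lineage; candidacy uses the conventional
100-bit threshold, applied as $\geq$ (a gene at exactly 100 bits is a
candidate).

Two conventions matter and are exposed in `screenConfig()`:

* **Missing group** (`missing_group_bits`, default 0): a gene with no
  hit in a group contributes 0 bits for that group, the usual
  alien-index practice. Consequently a gene with *only* algal hits gets
  a large positive $h_A$, and adding a constant to all bit scores is
  only guaranteed to cancel when both groups have hits — the package
  documents and tests both behaviors.
* **Sign** (`sign`, default `+1`): some presentations negate the
  h-index and threshold at $-100$; `sign = -1` reproduces that reading
  exactly, without changing which genes are flagged.

Indices are computed from the *raw* hit table. The LCA retention filter
(below) is deliberately not applied first: the index is a statement
about best matches, not about taxonomically filtered support.

## LCA taxonomic assignment

Gene origins are assigned with the MEGAN-style lowest-common-ancestor
procedure. Hits are first retained per query with three filters, with
the defaults of the published screens of this kind:

| parameter | default | meaning |
|---|---|---|
| `min_score` | 50 | minimum bit score |
| `max_expected` | 1e-4 | maximum E-value |
| `top_percent` | 20 | keep hits within 20% of the best retained bit score |
| `lca_percent` | 90 | support a node must reach |
| `min_support` | 1 | run-level minimum genes per assigned node |
| `min_support_percent` | 0.1 | same, as a percentage of assigned genes |

The top-percent band applies to the bit score and is measured against
the best hit that survived the first two filters. Retained hits are then
reduced to their **unique** subject taxa — several hits to one taxon
count once, so a deeply sequenced subject genome cannot dominate — and
the assigned node is the *deepest* node of the taxonomy whose subtree
contains at least `lca_percent` of those taxa. Ties among equally deep
qualifying nodes resolve to their LCA, which makes the assignment
independent of hit order (a property the tests check directly).

Two MEGAN parameters have semantics worth spelling out:

* **Min Support (Percent)** is applied at the *run* level: after all
  queries are assigned, any node holding fewer genes than
  `max(min_support, min_support_percent/100 × n_assigned)` has its genes
  pushed to its parent, repeatedly; genes that would pass beyond the
  root become `UNASSIGNED`.
* **Min Complexity** is a sequence-complexity pre-filter. This pipeline
  never touches sequence content, so the filter is accepted as an
  optional per-query boolean input (`low_complexity=`) and logged as
  skipped when absent, rather than silently recomputed differently.

## Credibility screens

The genome-level alignment screen declares a protein-to-genome hit
credible only if it covers **more than 60%** of the query *and* its
normalized alignment score — the raw alignment score (substitution
matrix plus gap penalties) divided by the aligned length in bp —
exceeds **2**. The translated-search screen requires E-value strictly
below **1e-4**. All three comparisons are strict; a hit sitting exactly
on a threshold fails. Tightening either alignment threshold can only
shrink the credible set (tested as a property).

The read-level screen length-normalizes raw read-hit counts to TPM over
the query universe,

$$\mathrm{tpm}_q = \frac{c_q / (L_q/1000)}{\sum_r c_r / (L_r/1000)}
\times 10^6,$$

where the universe is the union of the algal query set and the host
single-copy control set within one library. This denominator is a
design choice: the alternative (total library reads) is equally
defensible and changes only the scale, not the ~100-fold separation the
screen relies on; the union keeps the statistic self-contained and
makes $\sum \mathrm{tpm} = 10^6$ an exact invariant. The two sets are
compared with a two-sided Welch t-test, and algal queries with
TPM > 100 (strict) are **flagged, not classified**: a flagged query is
then checked against the host gene models, and it is explained away
when more than half of its reads also hit at least one host gene —
the signature of a conserved host homolog.

## Scaffold decontamination

Removal is deliberately conservative, because discarding a nuclear
scaffold could discard the very HGT evidence being sought.

* **Bacterial contaminants**: at least 2 genes assigned to the
  prokaryote group and *zero* lophotrochozoan genes. A single
  host-assigned gene always rescues a scaffold, for every configuration.
* **Organelle scaffolds**: best bit score against an organelle
  reference strictly above 1000, *corroborated by depth*. The nuclear
  mean depth is computed in a second pass over the scaffolds that were
  not bit-flagged (otherwise organelle depths, two orders of magnitude
  above nuclear, would inflate the baseline). The default depth-fold
  threshold is 10×: organelle scaffolds in data of this kind sit at
  ~17–166× the nuclear mean, so 10 is far below the observed minimum
  yet far above nuclear coverage noise. A bit-flagged scaffold that
  fails the depth rule is labelled `ambiguous` and retained.
* **Tissue ratio**: kleptoplast DNA is enriched in kleptoplast-rich
  tissue, so a two- to four-fold depth increase (closed interval
  $[2, 4]$) in the rich-tissue library corroborates a kleptoplast
  origin. Library depths are median-normalized first because raw
  library sizes differ. The flag corroborates; it never gates the
  label, since not every organelle scaffold need show the ratio.

`decontaminate()` removes only `bacterial_contaminant` and `organelle`
labels and reports everything with its evidence; retained + removed
always partition the input.

## Orthogroup expansion and enrichment

Expansion on the focal lineage is scored per orthogroup as

$$z = \frac{n_{\text{focal}} - \bar n}{s},$$

with mean and sample SD (n−1) over **all** species columns including
the focal one — the way a per-row heatmap Z-score is ordinarily
computed; `include_focal = FALSE` switches to the leave-one-out
variant. Zero variance gives $z = 0$, never expanded. Expansion is
strict ($z > 2$). Under a Poisson null with ~18 species the $z > 2$
rate is about 3% — the counts are discrete and right-skewed, so the
rate sits slightly above the Gaussian 2.3% — and the recovery tests
hold the observed null rate to that level while requiring every planted
expansion to be found.

Enrichment of up-regulated genes in an orthogroup is a Fisher exact
test on the 2×2 table (in-group up / in-group not-up / out-group up /
out-group not-up). The two-sided p sums all tables with the observed
margins whose point probability does not exceed the observed one (the
convention of the standard statistical packages; the one-sided
"greater" tail is available, and the headline result — enrichment of
up-regulated genes in the cathepsin-D-like and lectin-like orthogroups
at p < 1e-4 — holds under both). The background universe defaults to
the gene set of the membership table and can be widened to all gene
models; at either background the bound-level conclusion is insensitive.
The odds ratio is the sample cross-product $ad/bc$, with `Inf` allowed.
The implementation is an explicit hypergeometric sum and is checked in
the tests against (a) enumeration of all tables with the observed
margins computed from binomial coefficients, and (b)
`stats::fisher.test`.

Gene-family expansion could alternatively be modelled with a
birth–death process over the species tree; that machinery is out of
scope here, and a pre-computed column of such calls can simply be
carried as an input annotation.

## Physiology statistics

Oxygen rates are ordinary least squares of concentration on time
(`stats::lm`), reported per minute; the measurement window is an
explicit argument because instrument series show a few minutes of
acclimation lag after each light change, and no automated trimming is
attempted. The gross photosynthetic rate is $o_G = o_L + o_D$ with
$o_D$ stored as a *positive* consumption magnitude (the negated dark
slope), so the additive formula holds literally; a positive dark slope
is biologically unexpected and is clamped to zero with a warning.
Welch's t-test is written in closed form with the Welch–Satterthwaite
degrees of freedom so that its degenerate cases are defined (both
groups constant and equal: $t=0, p=1$; constant and unequal: infinite
$t$, $p=0$, with a warning); it is verified against `stats::t.test` to
1e-10.

## The synthetic-data generator

The generator emulates exactly the statistical structure each stage
consumes, and nothing more:

* **Genome**: 100 nuclear scaffolds × 20 host genes (2,000 host genes),
  20 planted algal-HGT genes placed *on nuclear scaffolds among host
  genes* (so decontamination must not remove them), 3 bacterial
  contaminant scaffolds of ≥2 bacterial genes each, and 2 organelle
  scaffolds. These defaults are the study conditions of the recovery
  tests; sequences are random nucleotides because no screen stage reads
  sequence content.
* **Hit tables**: each gene's best hit in its true-origin group follows
  `length_aa × 2 bits × 0.7` (about 420 bits for a 300-residue
  protein), and the opposing group sits a planted `margin` (default
  250) bits lower. Bit scores and raw scores are linked through the
  Karlin–Altschul form $\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ with
  the classic protein-search constants $\lambda = 0.267$, $K = 0.041$ —
  the pipeline only ever consumes scores, so no alignment is simulated.
* **Noise**: score jitter is a normal truncated at ±2 SD. The bounded
  tail gives a deterministic guarantee: with `noise_sd ≤ margin/4` the
  realized donor–host gap never drops below `margin/2`, so with the
  default margin of 250 every planted gene stays above the 100-bit
  candidacy threshold and every host gene below −100, and recovery is
  exactly 1.0/0.0 rather than merely probable. For larger noise the
  separation degrades monotonically, which the tests exercise as a
  trend rather than a point value.
* **Read counts**: negative-binomial, not Poisson, because the
  empirical control sets of this screen show SD of the same order as
  the mean (strong overdispersion); the control set's rate is ~100×
  the algal set's (dispersions 1.4 and 0.06, set sizes 905 and 614).
  An optional planted "shared-homolog" query receives control-like
  counts and must surface in the TPM > 100 flag list.
* **Depths**: nuclear scaffolds draw Normal(31, 4) in both libraries;
  organelle scaffolds get 20–100× the nuclear mean with a rich/poor
  tissue ratio drawn from [2, 4]; contaminant scaffolds sit in a
  distinct shallow band.
* **Orthogroups**: Poisson(3) baseline counts over 18 species; the
  planted group mirrors the published cathepsin-D pattern (203 focal
  genes, ≤5 elsewhere, 45 of them up-regulated against a ~0.2%
  background up rate).

What the generator does **not** emulate — real sequence homology,
database composition and bias, repeat structure, chimeric assembly,
uneven coverage — bounds what a passing test means: recovery results
demonstrate that the *statistics and rules* are implemented correctly
and behave as specified under their stated assumptions, not that the
screen would achieve the same sensitivity on a real assembly against
real databases.

## Numerical conventions

All threshold comparisons are as documented and unit-tested: coverage,
normalized score and E-value are strict; the HGT-index threshold is
closed (≥); the tissue-ratio interval is closed on both ends; the
organelle bit score is strict (>1000); the TPM flag is strict (>100);
the expansion Z is strict (>2). Fisher p-values use the
point-probability two-sided rule with the customary `1 + 1e-7` slack
against floating-point ties. Hit-table dialects are always named
explicitly and never sniffed, because outfmt-6 variants differ silently
in column order. Gene coordinates are kept 1-based inclusive end to
end (the GFF3 and Bioconductor convention), and interval arithmetic is
delegated to `GenomicRanges`, which removes the usual off-by-one
hazards that motivate internal half-open representations.

Problem sizes in the test suite and acceptance script — 10 replicate
genomes of ~2,040 genes, 200 random LCA instances against the
exhaustive all-node oracle, 200 Fisher tables up to N = 200, 100 TPM
tables — were chosen so the whole suite characterizes each statistic
thoroughly while remaining a desk-scale computation.

## A small end-to-end example

```{r example, eval = FALSE}
cfg  <- screenConfig()
tree <- simulateTaxonomy(40, seed = 1)
gen  <- simulateGenome(n_scaffolds = 20, genes_per_scaffold = 10,
                       n_hgt = 5, sequences = FALSE, seed = 1)
hits <- simulateHitTable(gen, tree, seed = 1)

scan <- hgtIndexScan(hits, tree, cfg)
scan$candidates[, c("gene_id", "hA_index")]

lca  <- lcaScan(hits, tree, cfg)
content  <- classifyScaffoldGeneContent(lca, gen$genes, tree)
depths   <- simulateDepths(gen, seed = 1)
asm      <- ScaffoldSet(scaffoldInfo(gen$scaffolds), depths = depths)
verdicts <- classifyScaffolds(asm, content,
                              simulateOrganelleHits(gen, seed = 1), cfg)
decontaminate(asm, verdicts)$report
```

## Known limitations

* Group membership in a `TaxonomyTree` is an explicit taxon set, not a
  clade pointer; supplying only apex nodes silently narrows the groups.
  `readTaxonomy()` fixtures and `simulateTaxonomy()` always enumerate
  whole subtrees.
* The LCA run-level support push-up follows MEGAN's semantics but not
  its implementation details for weighted reads; with the default
  `min_support = 1` and small gene sets it is a no-op.
* `compareReadSets()` tests TPM values with a t-test, as the screen it
  reproduces does; for strongly overdispersed counts a rank test would
  be more robust, and the near-zero p-values here should be read as
  "orders of magnitude apart", not as calibrated tail probabilities.
* The oxygen-rate fit assumes an approximately linear window; the
  caller is responsible for excluding acclimation transients.
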