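---
title: "Methods: CAZyme mining, filtering and xylanolytic screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAZyme mining, filtering and xylanolytic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastcaz)
```

This vignette documents the models and procedures implemented by
`yeastcaz`, the choices made where conventions genuinely diverge, and what
the synthetic test bed does and does not demonstrate.

## The annotation model

A proteome is annotated by searching every protein against a library of
CAZyme family profile HMMs (dbCAN style) and post-processing the
`--domtblout` table. The package does not run HMMER; it consumes its
output. Three rules turn raw domain hits into accepted annotations:

1. **E-value rule.** Keep a hit iff its full-sequence E-value is at most
   `1e-15`. The threshold is inclusive: HMMER's `-E` flag is an inclusive
   reporting threshold, so a hit at exactly `1e-15` is kept.
2. **Coverage rule.** Keep a hit iff it spans at least 35% of the HMM
   model: `(hmm_to − hmm_from + 1) / hmm_length ≥ 0.35`, with 1-based
   inclusive coordinates exactly as domtblout prints them.
3. **Overlap rule.** If two surviving domains on one protein overlap more
   than 20%, only the domain with the better E-value is retained. Three
   conventions needed fixing here:
   - *Denominator.* "20% overlap" is read as shared protein residues
     divided by the **shorter** of the two alignment spans — the
     convention of the dbCAN parser lineage. Overlap of exactly 0.20 is
     tolerated; strictly more conflicts.
   - *Which E-value.* The global threshold uses the full-sequence E-value
     (that is what `-E` filters on); overlap resolution uses the
     per-domain independent i-Evalue, because ranking two domains of the
     same protein needs per-domain statistics.
   - *More than two domains.* The pairwise rule generalises greedily:
     visit hits by ascending i-Evalue (ties: higher bit score, then
     leftmost start, then family name) and accept a hit iff it overlaps
     every already-accepted hit by at most 0.20. With exactly two
     conflicting domains this reduces to the stated pairwise rule. The
     test suite replays this contract with an independent brute-force
     implementation on 1,000 random proteins (and at every boundary:
     coverage 0.35 vs 0.3499, E-value 1e-15 vs 1.1e-15, overlap 0.20 vs
     0.21).

Both hmmsearch (protein = target) and hmmscan (protein = query)
orientations of domtblout are supported through the `orientation`
argument; hmmsearch is the default, which is an assumption rather than a
documented fact about how such tables are usually produced — callers who
used hmmscan must say so.

Secretion calls come from SignalP 5 eukaryote short output. The label
column (`SP(Sec/SPI)` vs `OTHER`) is authoritative; probabilities are
parsed but never re-thresholded, since no custom cutoff is part of the
procedure. A protein without a call is not secreted (join-total default).

## Profiles and substrate categories

The counting unit everywhere is the **distinct (protein, family) pair** —
one CAZyme-encoding gene. A repeated domain of one family within a protein
counts once; a protein with domains of two families counts toward both.
The headline per-species statistic is the total excluding GTs, because
glycosyl transferases are biosynthetic and say nothing about
depolymerisation capacity. Class totals (GH/GT/PL/CE/AA/CBM, by letter
prefix of the family name) partition the family counts, which the tests
assert as an invariant.

Substrate-category counts map families onto nine polysaccharide
categories. A family may map to several categories, so categories are not
disjoint; a gene counts once per category. The shipped map encodes the
published poly-specific assignments for GH5 (cellulose, mannan, xylan,
xyloglucan) and GH3 (β-glucan, cellulose, xylan, xyloglucan) and extends
them with canonical family-level assignments for the remaining categories.
That extension is a package choice, clearly replaceable by the user's own
TSV; it does not claim to reproduce any unpublished supplementary table.
CBMs are non-catalytic and deliberately map to nothing.

Tree heat annotations interpolate linearly from the lightest palette
colour at the minimum GT-excluded total to the darkest at the maximum.
Degenerate inputs are handled explicitly: a single species or all-equal
totals sit mid-palette (with a warning for the all-equal case), and leaves
without profiles get a neutral grey plus a mismatch report.

## Xylanolytic reports

Reports subset profiles to the xylan-relevant families (CE1, CE4, CE5,
CE15, GH3, GH5, GH10, GH11, GH30, GH43, GH51, GH62, GH67, GH115) with
subfamily-aware matching: a parent name like `GH5` matches every `GH5_x`;
a subfamily name matches exactly. Cells render in copy notation
(`GH5_22(4)`, bare name for one copy) and parse back losslessly; per-family
prevalence is the number of carrier species over the dataset size; families
carried by exactly one species are flagged unique.

The packaged transcription of a published 12-species xylanolytic table
serves as a fixture. Two of its printed rows disagree with the sum of
their own printed cells by one copy. The package flags these rows in a
validation report instead of silently correcting either the cells or the
totals — both printed readings are preserved, and equality is asserted
only for the ten internally consistent rows.

## Proteome de-duplication

Near-identical isoforms are removed before annotation by greedy
longest-first clustering at 98% identity: sequences are visited by
decreasing length (ties by identifier), and each joins the first accepted
representative it matches at or above threshold, else founds a cluster.
Identity is the maximum number of exact residue matches over all global
alignments with free gaps (match +1, mismatch 0, gap 0) divided by the
shorter length; under this scoring the optimum equals the longest common
subsequence, computed with a vectorised row recurrence. `X` matches
nothing (conservative). A residue-composition upper bound on the match
count prunes pairs that cannot reach the threshold, which makes the
quadratic scan practical since random (non-isoform) pairs almost never
pass the bound. This is deliberately *not* a re-implementation of CD-HIT's
word-indexing heuristics: de-duplication only removes near-identical
isoforms, and boundary behaviour between the two algorithms at exactly the
threshold is not analysis-critical. The test oracle recomputes every
member–representative identity with an independent full-matrix dynamic
program.

## Phylogenetic association

Trees are consumed as Newick (ape); tree inference is out of scope.
Patristic distance is the sum of branch lengths on the unique leaf-to-leaf
path; it is root-invariant, so unrooted input is fine. Missing branch
lengths become 0 with a warning. Candidates are ranked ascending by the
minimum (default) or mean patristic distance to the labeled xylanolytic
set, with alphabetical tie-breaks. No distance cutoff is applied — the
screen that motivates this operation selected "closely related" species
informally, so the package returns the full ranking and leaves the cutoff
to the analyst.

Pairwise percent identity uses Needleman–Wunsch with match +1, mismatch 0,
linear gap −1, and reports 100 × matches / alignment columns (gaps
included). Because co-optimal alignments can differ in matches and length,
the implementation resolves ties deterministically: among optimal-score
alignments it maximises matches, then minimises columns. This is one of
several identity conventions in use, which is precisely why no published
percent-identity figure is treated as a reproduction target.

## Assay arithmetic

The DNS end-point assay is modelled as a linear standard curve
`A = slope·c + intercept` (OLS fit, slope in absorbance per mM), inverted
to concentration with blank subtraction and a floor at zero (negative
blank-corrected absorbances warn). Volumetric activity converts mM
reducing sugar to U mL⁻¹ by multiplying with the total assay volume in
litres, dividing by the assay time in minutes, and dividing by the sample
volume in litres; with the default geometry (175 µL substrate + 25 µL
sample, 30 min, 30 °C) 1 mM corresponds to 0.2667 U mL⁻¹. One unit is
1 µmol reducing sugar per minute. Growth classification is inclusive at
OD₆₀₀ ≥ 0.2.

Protein masses use average (isotope-abundance-weighted) residue masses
with one water (18.0153 Da) per chain, the convention for predicted
molecular weights in the 20–25 kDa range; ambiguity codes have no defined
mass and error. The packaged 217-residue GH11 xylanase sequence computes
to 23.186 kDa, matching its reported 23.19 kDa within mass-table rounding
(±0.05 kDa). Whether that figure refers to the precursor or a mature
chain is not stated in the source; the full printed sequence is used.

## The synthetic test bed

`generate_dataset()` writes a complete input bundle (per-species FASTA,
combined domtblout, SignalP short file, metadata, substrate map, Newick
tree, ground-truth counts) from a seeded configuration. Its defaults are
the conditions the test suite and acceptance script use throughout:

- 12 species in 4 contiguous clades, 30 proteins per species;
- a family pool of 13 degradative families plus 2 GTs, each planted at a
  mean rate of 0.5 genes per species per family (Poisson), chosen so that
  a 3×-boosted clade stays within the per-species protein budget;
- `rich_boost = 3` on degradative families in the first clade (the
  planted signal; 1-based clade indexing, R convention);
- `noise_fraction = 0.2`: a fifth of planted hits are built to fail
  exactly one filter rule — E-values drawn in `(1e-15, 1e-5]`, coverage
  below 0.35, or an overlapping duplicate with a ≥10× worse i-Evalue on a
  planted gene's protein — while true hits draw E-values log-uniformly in
  `[1e-60, 1e-16]` and coverages in `[0.5, 0.95]`, so both sides of every
  threshold occur;
- `secreted_fraction = 0.5` of CAZyme proteins get an `SP(Sec/SPI)` call.

Identical configuration and seed produce byte-identical files (fixed
numeric formatting everywhere). One gene occupies one protein, so the
ground-truth table is exactly the per-species family counts the pipeline
must recover — with or without noise, since every noise hit is constructed
to be rejected.

What the generator does **not** emulate: real domain motifs (sequences are
uniform random over the 20 canonical residues — the filters operate purely
on coordinates and E-values, so this is sufficient for them, but it means
passing tests say nothing about HMM search sensitivity); correlated domain
architectures; genome incompleteness; realistic sequence evolution on the
tree (branch lengths are arbitrary). Tests on this bed validate the
*post-search* pipeline, not the search itself.

Problem sizes in the test suite and acceptance script — 1,000 random
proteins for the resolution oracle, 20 generator seeds for planted-clade
recovery, 100 replicate wells for noisy assay recovery — are the package's
chosen balance between statistical resolution and a test run that stays
pleasant to iterate on; all complete in well under a minute each.

## Known limitations

- De-duplication is quadratic in the number of non-prunable pairs; for
  full real proteomes (10⁴ proteins) a word-indexed tool remains the right
  choice, with this package consuming its representatives.
- The default substrate map is family-level and intentionally small;
  subfamily-resolved substrate assignments would sharpen the heatmap for
  poly-specific families like GH5 and GH43.
- Reported full-dataset figures from large-scale screens (hundreds of
  proteomes against full HMM libraries) require those external inputs and
  are out of scope here; the package validates structure and arithmetic,
  not genome-scale reproductions.
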