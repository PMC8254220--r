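# yeastcaz

CAZyme genome mining and xylanolytic screening for budding yeasts.

Carbohydrate-active enzymes (CAZymes) — glycoside hydrolases (GH), glycosyl
transferases (GT), polysaccharide lyases (PL), carbohydrate esterases (CE),
auxiliary activities (AA) and carbohydrate-binding modules (CBM) — determine
whether a microbe can depolymerise plant polysaccharides such as xylan,
mannan or cellulose. Screening hundreds of yeast proteomes for CAZymes is a
fast way to shortlist species for consolidated bioprocessing, but the raw
annotation outputs (HMMER domain tables against dbCAN-style family HMMs,
SignalP secretion calls) need careful filtering and aggregation before they
say anything about biology. This package implements that pipeline as
reusable, tested R functions, for computational biologists mining fungal
genomes for polysaccharide-degrading candidates.

## What it computes

**Domain filtering.** A protein domain hit from a dbCAN-style HMM search is
accepted iff

- full-sequence E-value ≤ 10⁻¹⁵ (inclusive; HMMER's `-E` convention),
- HMM model coverage (hmm_to − hmm_from + 1)/hmm_length ≥ 0.35,

and, among surviving hits on one protein, whenever two domains overlap more
than 20 % of the shorter alignment span, only the domain with the better
per-domain (independent) E-value is retained — resolved greedily,
best-E-value first, which reduces exactly to the pairwise rule when only two
domains conflict.

**Profiles.** The counting unit is the distinct (protein, family) pair — a
CAZyme-encoding gene. Per species the package reports family counts, class
breakdowns, and the headline GT-excluded total (GTs are biosynthetic, not
degradative), plus per-category counts over nine polysaccharide substrates
(β-glucan, cellulose, chitin, lignin, mannan, pectin, starch, xylan,
xyloglucan) through a replaceable family→substrate map, and a light-yellow
to dark-red heat annotation for species trees.

**Xylanolytic reports.** Per-species tables of xylan-relevant families
(CE1/4/5/15, GH3, GH5, GH10, GH11, GH30, GH43, GH51, GH62, GH67, GH115) in
copy notation (`GH5_22(4)`), with dataset-wide prevalence (`k/N`) and
unique-family flags, including a packaged transcription of a published
12-species table used as a consistency fixture.

**Phylogenetic association.** Candidate taxa are ranked by patristic
distance (sum of branch lengths) to taxa already known to be xylanolytic —
the closest relatives of the best xylan degraders are the most promising
uncharacterised species.

**Assay arithmetic.** DNS reducing-sugar standard curves, mM sugar from
absorbance, and volumetric xylanase activity
U mL⁻¹ = mM × V_total(L) / t(min) / V_sample(L) under the 175 + 25 µL,
30 min, 30 °C assay geometry (1 U = 1 µmol reducing sugar min⁻¹); growth
classification at OD₆₀₀ ≥ 0.2; protein length and average molecular mass.

**Supporting primitives.** FASTA and Newick I/O (via Biostrings and ape),
HMMER3 `--domtblout` parsing in both hmmsearch and hmmscan orientations,
SignalP 5 short-format parsing, greedy longest-first 98 %-identity proteome
de-duplication, and Needleman–Wunsch percent identity.

A seeded synthetic-data generator (`generate_dataset()`) emulates the whole
input bundle — proteomes, domtblout, SignalP tables, metadata, substrate
map, species tree — with a planted CAZyme-rich clade and known ground
truth, so every stage is testable without downloading real genome data.

## Worked example

The `analysis/` scripts run the whole workflow on the synthetic dataset:

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_annotate_cazymes.R
Rscript analysis/03_cazyme_profiles.R
Rscript analysis/04_xylanolytic_report.R
Rscript analysis/05_assay_activity.R
Rscript analysis/06_phylo_association.R
```

Step 2 reports the filter at work and checks it against the planted truth:

```
<proteome_annotation> 121 accepted domain(s) on 121 protein(s); 31 rejected

Rejection reasons in the audit table:
coverage   evalue  overlap
      14        9        8

Pipeline counts equal planted ground truth for all 84 species x family cells.
```

Step 3 recovers the planted CAZyme-rich clade (clade A was simulated with a
3× degradative-gene rate):

```
Top species by GT-excluded CAZyme total:
  rank species_id  clade total_excl_gt
1    1      sp001 cladeA            18
2    2      sp002 cladeA            16
3    3      sp003 cladeA            16
4    4      sp010 cladeD            11
5    5      sp005 cladeB             8

Mean GT-excluded total per clade:
   clade total_excl_gt
1 cladeA     16.666667
2 cladeB      6.000000
3 cladeC      5.333333
4 cladeD      8.000000
```

The ranks say species sp001–sp003 carry roughly twice the degradative
CAZyme load of the background clades — exactly the planted signal. Step 5
prints the protein arithmetic for the packaged GH11 xylanase sequence:

```
GH11 xylanase: 217 residues, predicted average mass 23.19 kDa
```

Outputs land as TSVs under `results/`.

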