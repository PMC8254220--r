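Package: yeastcaz
Title: CAZyme Genome Mining and Xylanolytic Screening for Budding Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines proteomes for carbohydrate-active enzymes (CAZymes) from
    standard annotation outputs and screens the results for xylanolytic
    potential. Parses HMMER3 domtblout tables of dbCAN-style CAZyme domain
    searches and applies a three-rule filter (full-sequence E-value at most
    1e-15, at least 35% HMM model coverage, greedy resolution of domain pairs
    overlapping more than 20% of the shorter alignment span in favour of the
    better per-domain E-value); parses SignalP 5 short output for secretion
    calls; de-duplicates proteomes by greedy 98%-identity clustering;
    aggregates per-species CAZyme family profiles with
    glycosyltransferase-excluded totals, substrate-category heatmap counts and
    phylogenetic-tree heat annotations; builds xylanolytic family reports with
    copy-number notation, dataset-wide prevalence and unique-family flags;
    ranks candidate taxa by patristic proximity to known xylanolytic taxa on
    Newick trees; and converts dinitrosalicylic-acid (DNS) reducing-sugar
    assay absorbances to volumetric xylanase activities. A seeded synthetic
    data generator emulates multi-species proteomes with planted CAZyme-rich
    clades so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    igraph,
    jsonlite,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
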