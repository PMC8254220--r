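run_pipeline_counts <- function(manifest) {
  hits <- parse_domtblout(manifest$paths$domtblout)
  calls <- parse_signalp_short(manifest$paths$signalp)
  recs <- do.call(rbind, lapply(manifest$paths$proteomes, read_fasta))
  ann <- annotate_proteome(recs, hits, calls)
  prof <- build_profiles(ann, manifest$metadata)
  counts <- prof$counts[, c("species_id", "family", "n")]
  names(counts)[3] <- "count"
  counts[order(counts$species_id, counts$family), ]
}

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(synthetic_config(n_species = 2, n_clades = 5), "n_clades")
  expect_error(synthetic_config(noise_fraction = 1.2), "noise_fraction")
  expect_error(synthetic_config(secreted_fraction = -0.1), "secreted_fraction")
  expect_error(synthetic_config(rich_boost = 0.5), "rich_boost")
  expect_error(synthetic_config(family_pool = character(0)), "family_pool")
  expect_error(synthetic_config(rich_clade_index = 9), "rich_clade_index")
})

test_that("identical config and seed give byte-identical files", {
  cfg <- synthetic_config(n_species = 6, n_clades = 2,
                          proteins_per_species = 10, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the proteomes contain exactly n_species x proteins_per_species records", {
  cfg <- synthetic_config(n_species = 5, n_clades = 2,
                          proteins_per_species = 7, seed = 3)
  m <- generate_dataset(cfg, withr::local_tempdir())
  recs <- do.call(rbind, lapply(m$paths$proteomes, read_fasta))
  expect_equal(nrow(recs), 5L * 7L)
  expect_equal(length(unique(recs$id)), 35L)
})

test_that("with zero noise every planted hit survives and counts equal ground truth", {
  cfg <- synthetic_config(noise_fraction = 0, seed = 7)
  m <- generate_dataset(cfg, withr::local_tempdir())
  got <- run_pipeline_counts(m)
  gt <- m$ground_truth[order(m$ground_truth$species_id, m$ground_truth$family), ]
  rownames(got) <- rownames(gt) <- NULL
  expect_equal(got, gt)
})

test_that("with noise planted to fail each rule, pipeline counts still equal ground truth", {
  cfg <- synthetic_config(noise_fraction = 0.3, seed = 11)
  m <- generate_dataset(cfg, withr::local_tempdir())
  hits <- parse_domtblout(m$paths$domtblout)
  # noise exists: more hits than planted genes
  expect_gt(nrow(hits), sum(m$ground_truth$count))
  got <- run_pipeline_counts(m)
  gt <- m$ground_truth[order(m$ground_truth$species_id, m$ground_truth$family), ]
  rownames(got) <- rownames(gt) <- NULL
  expect_equal(got, gt)
})

test_that("the boosted clade has the highest mean degradative ground-truth count", {
  cfg <- synthetic_config(n_species = 12, n_clades = 4, rich_clade_index = 1,
                          rich_boost = 3, seed = 5)
  m <- generate_dataset(cfg, withr::local_tempdir())
  gt <- m$ground_truth
  gt$clade <- m$metadata$clade[match(gt$species_id, m$metadata$species_id)]
  gt <- gt[cazy_class(gt$family) != "GT", ]
  per_species <- aggregate(count ~ species_id + clade, gt, sum)
  clade_means <- aggregate(count ~ clade, per_species, mean)
  expect_equal(clade_means$clade[which.max(clade_means$count)], "cladeA")
})

test_that("planted filter edge cases fall on the documented side of each rule", {
  edge <- plant_filter_edge_cases()
  flt <- filter_hits(edge[, setdiff(names(edge), "expected")])
  # E-value and coverage fates
  kept_ids <- flt$passed$protein_id
  expect_true(all(c("edge_cov_keep", "edge_ev_tie", "edge_ev_below") %in% kept_ids))
  expect_equal(
    flt$rejected$reason[flt$rejected$protein_id == "edge_cov_drop"], "coverage")
  expect_equal(
    flt$rejected$reason[flt$rejected$protein_id == "edge_ev_drop"], "evalue")
  # exact coverage boundaries
  expect_equal(hmm_coverage(edge[edge$protein_id == "edge_cov_keep", ]), 0.35)
  expect_equal(hmm_coverage(edge[edge$protein_id == "edge_cov_drop", ]), 0.3499)
  # overlap at exactly 0.20: both kept
  ovl20 <- flt$passed[flt$passed$protein_id == "edge_ovl20", ]
  expect_equal(nrow(resolve_overlaps(ovl20)$accepted), 2L)
  # overlap at 0.21: the worse per-domain E-value is dropped
  ovl21 <- flt$passed[flt$passed$protein_id == "edge_ovl21", ]
  res <- resolve_overlaps(ovl21)
  expect_equal(res$accepted$family_id, "GH5_7")
  expect_equal(res$rejected$family_id, "GH3")
  # fates agree with the planted expectations end to end
  ann <- annotate_proteome(NULL, edge[, setdiff(names(edge), "expected")])
  kept <- paste(ann$annotations$protein_id, ann$annotations$family)
  planted_keep <- paste(edge$protein_id, edge$family_id)[edge$expected == "keep"]
  expect_setequal(kept, planted_keep)
  reasons <- merge(edge[edge$expected != "keep", c("protein_id", "family_id",
                                                   "expected")],
                   ann$audit[, c("protein_id", "family_id", "reason")])
  expect_equal(nrow(reasons), sum(edge$expected != "keep"))
  expect_equal(reasons$reason, reasons$expected)
})

test_that("edge cases can be embedded into the generated domtblout", {
  cfg <- synthetic_config(n_species = 4, n_clades = 2,
                          proteins_per_species = 6, seed = 2)
  m <- generate_dataset(cfg, withr::local_tempdir(), include_edge_cases = TRUE)
  hits <- parse_domtblout(m$paths$domtblout)
  expect_true(all(m$edge_cases$protein_id %in% hits$protein_id))
})

test_that("zero-noise assay plates invert exactly and zero activity gives the intercept", {
  plate <- generate_assay_plate(c(0, 0.3, 2.2), curve_slope = 0.41,
                                curve_intercept = 0.08)
  curve <- structure(list(slope = 0.41, intercept = 0.08, r_squared = 1),
                     class = "standard_curve")
  back <- plate_activities(plate$absorbance, curve)$activity_U_per_mL
  expect_equal(back, c(0, 0.3, 2.2), tolerance = 1e-9)
  expect_equal(plate$absorbance[1], 0.08)
})
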