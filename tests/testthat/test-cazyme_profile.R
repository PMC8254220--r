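toy_annotations <- function() {
  data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p4", "p5", "p5"),
    species_id = c("A", "A", "A", "B", "B", "B", "B"),
    family = c("GH10", "GH10", "GT2", "GH5_22", "GH5_22", "GH10", "CBM13"),
    stringsAsFactors = FALSE
  )
}

toy_meta <- function() {
  data.frame(species_id = c("A", "B", "C"),
             clade = c("clade1", "clade1", "clade2"),
             stringsAsFactors = FALSE)
}

test_that("profiles count distinct (protein, family) pairs per species", {
  prof <- build_profiles(toy_annotations(), toy_meta())
  cA <- prof$counts[prof$counts$species_id == "A", ]
  expect_equal(setNames(cA$n, cA$family), c(GH10 = 2L, GT2 = 1L))
  cB <- prof$counts[prof$counts$species_id == "B", ]
  # p4 has two accepted GH5_22 domains but counts once; p5 contributes to
  # both GH10 and CBM13
  expect_equal(setNames(cB$n, cB$family), c(CBM13 = 1L, GH10 = 1L, GH5_22 = 1L))
  # species C has no annotations but stays in the profile set
  expect_true("C" %in% prof$species$species_id)
})

test_that("class totals partition family counts and GTs are excluded from the headline total", {
  totals <- profile_totals(build_profiles(toy_annotations(), toy_meta()))
  expect_equal(totals$total, rowSums(totals[, c("GH", "GT", "PL", "CE", "AA", "CBM")]))
  expect_equal(totals$total_excl_gt + totals$GT, totals$total)
  expect_equal(totals$total_excl_gt[totals$species_id == "A"], 2L)
  expect_equal(totals$total_excl_gt[totals$species_id == "B"], 3L)
  expect_equal(totals$total_excl_gt[totals$species_id == "C"], 0L)
})

test_that("species missing from metadata get clade 'unknown' with a warning", {
  meta <- toy_meta()[1, , drop = FALSE]
  expect_warning(prof <- build_profiles(toy_annotations(), meta), "unknown")
  expect_equal(prof$species$clade[prof$species$species_id == "B"], "unknown")
})

test_that("substrate counts follow the GH5/GH3 poly-specific assignments", {
  ann <- data.frame(
    protein_id = sprintf("p%d", 1:5),
    species_id = "A",
    family = c("GH5_9", "GH5_9", "GH5_22", "GH3", "GH3"),
    stringsAsFactors = FALSE
  )
  prof <- build_profiles(ann, data.frame(species_id = "A", clade = "c"))
  sc <- substrate_counts(prof)
  # GH5 x3 -> cellulose, mannan, xylan, xyloglucan; GH3 x2 -> beta-glucan,
  # cellulose, xylan, xyloglucan
  expect_equal(sc$xylan, 5L)
  expect_equal(sc$cellulose, 5L)
  expect_equal(sc$xyloglucan, 5L)
  expect_equal(sc$mannan, 3L)
  expect_equal(sc$`beta-glucan`, 2L)
  expect_equal(sc$starch, 0L)
})

test_that("unmapped families are counted in no category and reported", {
  ann <- data.frame(protein_id = sprintf("p%d", 1:7), species_id = "A",
                    family = "GT2", stringsAsFactors = FALSE)
  prof <- build_profiles(ann, data.frame(species_id = "A", clade = "c"))
  sc <- substrate_counts(prof)
  expect_true(all(as.matrix(sc[, SUBSTRATE_CATEGORIES]) == 0L))
  expect_equal(attr(sc, "unmapped"), "GT2")
})

test_that("adding one xylan-family gene raises the xylan count by exactly one", {
  ann <- data.frame(protein_id = c("p1", "p2"), species_id = "A",
                    family = c("GH10", "CE1"), stringsAsFactors = FALSE)
  meta <- data.frame(species_id = "A", clade = "c")
  before <- substrate_counts(build_profiles(ann, meta))$xylan
  ann2 <- rbind(ann, data.frame(protein_id = "p3", species_id = "A",
                                family = "GH11"))
  after <- substrate_counts(build_profiles(ann2, meta))$xylan
  expect_equal(after, before + 1L)
})

test_that("rank_species orders by GT-excluded total with alphabetical ties", {
  ann <- data.frame(
    protein_id = sprintf("p%d", 1:8),
    species_id = c(rep("X", 5), rep("Y", 3)),
    family = c(rep("GH10", 2), rep("GT2", 3), rep("GH10", 3)),
    stringsAsFactors = FALSE
  )
  meta <- data.frame(species_id = c("X", "Y", "Z"), clade = "c")
  ranked <- rank_species(build_profiles(ann, meta))
  # X has 5 CAZymes of which 3 GT -> 2; Y has 3 with 0 GT -> Y first
  expect_equal(ranked$species_id, c("Y", "X", "Z"))
  expect_equal(ranked$total_excl_gt, c(3L, 2L, 0L))
  # exact ties break alphabetically
  ann_tie <- data.frame(protein_id = c("p1", "p2"),
                        species_id = c("B", "A"), family = "GH10")
  ranked_tie <- rank_species(build_profiles(
    ann_tie, data.frame(species_id = c("A", "B"), clade = "c")))
  expect_equal(ranked_tie$species_id, c("A", "B"))
})

test_that("select_rich_species takes top_k then applies category minimums", {
  ann <- data.frame(
    protein_id = sprintf("p%d", 1:6),
    species_id = c("X", "X", "X", "Y", "Y", "Z"),
    family = c("GH10", "GH10", "GH18", "GH18", "GH18", "GH10"),
    stringsAsFactors = FALSE
  )
  prof <- build_profiles(ann, data.frame(species_id = c("X", "Y", "Z"),
                                         clade = "c"))
  expect_equal(select_rich_species(prof, 2)$species_id, c("X", "Y"))
  sel <- select_rich_species(prof, 2, required_categories = c(xylan = 1))
  expect_equal(sel$species_id, "X")
  # top_k larger than n selects everyone
  expect_equal(nrow(select_rich_species(prof, 99)), 3L)
  expect_warning(select_rich_species(prof, 1, c(pectin = 1)), "no species")
})

test_that("tree heat annotation ramps linearly from lightest to darkest", {
  ann <- data.frame(
    protein_id = sprintf("p%d", 1:6),
    species_id = c("A", "B", "B", "C", "C", "C"),
    family = "GH10", stringsAsFactors = FALSE
  )
  prof <- build_profiles(ann, data.frame(species_id = c("A", "B", "C"),
                                         clade = "c"))
  heat <- export_tree_heat_annotation(c("A", "B", "C"), prof,
                                      palette = c("#000000", "#FFFFFF"))
  expect_equal(heat$value, c(1L, 2L, 3L))
  expect_equal(heat$color, c("#000000", "#7F7F7F", "#FFFFFF"))
  # unknown leaf gets the neutral colour and a mismatch report
  expect_warning(h2 <- export_tree_heat_annotation(c("A", "Q"), prof), "Q")
  expect_equal(attr(h2, "mismatches"), "Q")
  expect_equal(h2$color[2], "#BEBEBE")
  # single species sits mid-palette
  prof1 <- build_profiles(ann[1, ], data.frame(species_id = "A", clade = "c"))
  h1 <- export_tree_heat_annotation("A", prof1,
                                    palette = c("#000000", "#FFFFFF"))
  expect_equal(h1$color, "#7F7F7F")
  # all-equal totals warn and sit mid-palette
  profeq <- build_profiles(ann[c(1, 2, 4), ],
                           data.frame(species_id = c("A", "B", "C"), clade = "c"))
  expect_warning(heq <- export_tree_heat_annotation(c("A", "B", "C"), profeq,
                                                    palette = c("#000000", "#FFFFFF")),
                 "mid-palette")
  expect_equal(unique(heq$color), "#7F7F7F")
})
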