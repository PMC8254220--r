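#' Configuration for the synthetic dataset generator
#'
#' Describes a multi-species proteome dataset with a planted CAZyme-rich
#' clade. Species are split into contiguous clades; every species gets
#' `proteins_per_species` random protein sequences, a subset of which carry
#' planted CAZyme domain hits. Degradative-family (non-GT) hit counts in the
#' rich clade are boosted `rich_boost`-fold, which is the structure the
#' downstream profiling stage is expected to recover. A `noise_fraction` of
#' all planted hits is constructed to fail one of the three filter rules
#' (bad full-sequence E-value, low HMM coverage, or an overlapping duplicate
#' with a worse per-domain E-value), so pipeline counts equal the emitted
#' ground truth only after filtering.
#'
#' @param n_species number of species (>= `n_clades`).
#' @param n_clades number of contiguous clades (>= 1).
#' @param proteins_per_species proteins per species.
#' @param family_pool CAZy family names to draw planted hits from.
#' @param rich_clade_index 1-based clade index to boost, or `NULL` for none.
#' @param rich_boost multiplier (>= 1) on degradative-family hit rates in the
#'   rich clade.
#' @param noise_fraction fraction in `[0, 1)` of planted hits built to fail a
#'   filter rule.
#' @param secreted_fraction fraction of CAZyme proteins given an
#'   `SP(Sec/SPI)` signal-peptide call.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output files.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 12L, n_clades = 4L,
                             proteins_per_species = 30L,
                             family_pool = c("GH10", "GH11", "GH5_7", "GH5_22",
                                             "GH3", "GH43_24", "GH30_7", "CE1",
                                             "CE4", "GH18", "AA9", "PL1",
                                             "CBM13", "GT2", "GT4"),
                             rich_clade_index = 1L, rich_boost = 3,
                             noise_fraction = 0.2, secreted_fraction = 0.5,
                             seed = 1L) {
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg)
  }
  check(is.numeric(n_species) && n_species >= 1, "n_species", "must be >= 1")
  check(is.numeric(n_clades) && n_clades >= 1, "n_clades", "must be >= 1")
  check(n_species >= n_clades, "n_clades", "must not exceed n_species")
  check(proteins_per_species >= 1, "proteins_per_species", "must be >= 1")
  check(length(family_pool) >= 1, "family_pool", "must be non-empty")
  cazy_class(family_pool)  # errors on malformed names
  check(is.null(rich_clade_index) ||
          (rich_clade_index >= 1 && rich_clade_index <= n_clades),
        "rich_clade_index", "must be in 1..n_clades or NULL")
  check(rich_boost >= 1, "rich_boost", "must be >= 1")
  check(noise_fraction >= 0 && noise_fraction < 1, "noise_fraction",
        "must be in [0, 1)")
  check(secreted_fraction >= 0 && secreted_fraction <= 1, "secreted_fraction",
        "must be in [0, 1]")
  check(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")
  structure(list(
    n_species = as.integer(n_species), n_clades = as.integer(n_clades),
    proteins_per_species = as.integer(proteins_per_species),
    family_pool = family_pool,
    rich_clade_index = if (is.null(rich_clade_index)) NULL else as.integer(rich_clade_index),
    rich_boost = rich_boost, noise_fraction = noise_fraction,
    secreted_fraction = secreted_fraction, seed = as.integer(seed)
  ), class = "synthetic_config")
}

random_protein <- function(len) {
  paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
}

# Mean planted CAZyme genes per species and family before any rich-clade
# boost. Chosen so a 3x-boosted clade stays well under the default
# proteins_per_species budget.
BASE_FAMILY_RATE <- 0.5

#' Generate a synthetic CAZyme-mining dataset
#'
#' Writes, under `out_dir`: one FASTA per species (`proteomes/`), a combined
#' hmmsearch-orientation domtblout of all planted hits, a SignalP 5 short
#' file, a species-to-clade metadata TSV, a family-to-substrate map TSV, a
#' Newick tree whose topology groups the clades, and a ground-truth TSV of
#' intended post-filter CAZyme gene counts per species and family.
#'
#' Planted true hits always pass all three filter rules; noise hits (see
#' [synthetic_config()]) are constructed to fail exactly one of them, so
#' running the annotation pipeline must reproduce the ground truth table.
#' E-values of true hits are drawn log-uniformly in `[1e-60, 1e-16]` and
#' E-value-noise hits in `(1e-15, 1e-5]`, exercising both sides of the
#' threshold.
#'
#' @param config a [synthetic_config()].
#' @param out_dir writable output directory (created if missing).
#' @param include_edge_cases also append the [plant_filter_edge_cases()] rows
#'   to the domtblout (their protein ids are not part of any proteome).
#' @return list of class `dataset_manifest`: `paths` (named list of all
#'   files), `ground_truth` (data frame `species_id`, `family`, `count`),
#'   `metadata`, `config`, and `edge_cases` when requested.
#' @export
generate_dataset <- function(config, out_dir, include_edge_cases = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(file.path(out_dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir)
  }
  set.seed(config$seed)

  n <- config$n_species
  species <- sprintf("sp%03d", seq_len(n))
  clade_sizes <- diff(round(seq(0, n, length.out = config$n_clades + 1L)))
  clade_of <- rep(seq_len(config$n_clades), times = clade_sizes)
  clades <- sprintf("clade%s", LETTERS[clade_of])
  metadata <- data.frame(species_id = species, clade = clades,
                         stringsAsFactors = FALSE)

  fams <- config$family_pool
  degradative <- cazy_class(fams) != "GT"

  all_hits <- list()
  truth <- list()
  signalp_rows <- list()
  proteome_paths <- character(n)

  for (s in seq_len(n)) {
    sid <- species[s]
    plen <- sample(120:400, config$proteins_per_species, replace = TRUE)
    pid <- sprintf("%s_p%03d", sid, seq_len(config$proteins_per_species))
    seqs <- vapply(plen, random_protein, character(1))

    boost <- if (!is.null(config$rich_clade_index) &&
                 clade_of[s] == config$rich_clade_index) config$rich_boost else 1
    lambda <- BASE_FAMILY_RATE * ifelse(degradative, boost, 1)
    n_fam <- rpois(length(fams), lambda)
    genes <- rep(fams, n_fam)
    if (length(genes) > config$proteins_per_species) {
      genes <- sample(genes)[seq_len(config$proteins_per_species)]
    }
    n_true <- length(genes)
    gene_protein <- pid[seq_len(n_true)]

    true_hits <- NULL
    if (n_true > 0L) {
      hmm_len <- sample(100:400, n_true, replace = TRUE)
      cov <- runif(n_true, 0.5, 0.95)
      span <- pmax(1L, round(cov * hmm_len))
      hmm_from <- vapply(hmm_len - span + 1L,
                         function(k) sample.int(k, 1L), integer(1))
      ali_len <- pmin(span, plen[seq_len(n_true)] - 10L)
      ali_from <- vapply(plen[seq_len(n_true)] - ali_len + 1L,
                         function(k) sample.int(k, 1L), integer(1))
      ev_full <- 10^runif(n_true, -60, -16)
      true_hits <- data.frame(
        protein_id = gene_protein, family_id = genes,
        hmm_length = hmm_len, hmm_from = hmm_from,
        hmm_to = hmm_from + span - 1L,
        ali_from = ali_from, ali_to = ali_from + ali_len - 1L,
        evalue_full = ev_full,
        evalue_dom = ev_full * 10^runif(n_true, -0.5, 0.5),
        bitscore = round(runif(n_true, 50, 300), 1),
        stringsAsFactors = FALSE
      )
    }

    noise_hits <- NULL
    n_noise <- if (config$noise_fraction > 0 && n_true > 0L) {
      round(config$noise_fraction / (1 - config$noise_fraction) * n_true)
    } else 0L
    if (n_noise > 0L) {
      modes <- sample(c("evalue", "coverage", "overlap"), n_noise,
                      replace = TRUE)
      noise_hits <- do.call(rbind, lapply(seq_len(n_noise), function(k) {
        if (modes[k] == "overlap") {
          host <- true_hits[sample.int(n_true, 1L), ]
          host_len <- host$ali_to - host$ali_from + 1L
          shift <- floor(host_len * runif(1, 0, 0.5))
          other <- sample(fams[fams != host$family_id], 1L)
          hl <- sample(100:400, 1L)
          sp2 <- max(1L, round(runif(1, 0.5, 0.95) * hl))
          data.frame(
            protein_id = host$protein_id, family_id = other,
            hmm_length = hl,
            hmm_from = sample.int(hl - sp2 + 1L, 1L),
            hmm_to = NA_integer_,  # filled below from span
            ali_from = host$ali_from + shift, ali_to = host$ali_to + shift,
            evalue_full = 10^runif(1, -60, -16),
            evalue_dom = host$evalue_dom * 10^runif(1, 1, 5),
            bitscore = round(runif(1, 10, 49), 1),
            stringsAsFactors = FALSE
          ) -> h
          h$hmm_to <- h$hmm_from + sp2 - 1L
          h
        } else {
          tgt <- sample(pid, 1L)
          hl <- sample(100:400, 1L)
          if (modes[k] == "coverage") {
            sp2 <- max(1L, floor(runif(1, 0.05, 0.34) * hl))
            if (sp2 / hl >= 0.35) sp2 <- ceiling(0.35 * hl) - 1L
            ev <- 10^runif(1, -60, -16)
          } else {
            sp2 <- max(1L, round(runif(1, 0.5, 0.95) * hl))
            ev <- 10^runif(1, -14.9, -5)
          }
          al <- min(sp2, plen[match(tgt, pid)] - 10L)
          af <- sample.int(plen[match(tgt, pid)] - al + 1L, 1L)
          hf <- sample.int(hl - sp2 + 1L, 1L)
          data.frame(
            protein_id = tgt, family_id = sample(fams, 1L),
            hmm_length = hl, hmm_from = hf, hmm_to = hf + sp2 - 1L,
            ali_from = af, ali_to = af + al - 1L,
            evalue_full = ev, evalue_dom = ev, bitscore = round(runif(1, 10, 150), 1),
            stringsAsFactors = FALSE
          )
        }
      }))
    }

    # signal peptide calls: a fraction of CAZyme proteins are secreted
    cazy_proteins <- unique(gene_protein)
    n_sec <- round(config$secreted_fraction * length(cazy_proteins))
    secreted <- if (n_sec > 0L) sample(cazy_proteins, n_sec) else character(0)
    sp_prob <- round(runif(length(pid), 0.9, 0.99), 4)
    cs <- sample(15:25, length(pid), replace = TRUE)
    signalp_rows[[s]] <- vapply(seq_along(pid), function(i) {
      if (pid[i] %in% secreted) {
        sprintf("%s\tSP(Sec/SPI)\t%.4f\t%.4f\tCS pos: %d-%d. Pr: 0.8000",
                pid[i], sp_prob[i], 1 - sp_prob[i], cs[i], cs[i] + 1L)
      } else {
        sprintf("%s\tOTHER\t%.4f\t%.4f\t", pid[i], round(1 - sp_prob[i], 4),
                sp_prob[i])
      }
    }, character(1))

    fasta_path <- file.path(out_dir, "proteomes", paste0(sid, ".fasta"))
    write_fasta(data.frame(id = pid, sequence = seqs,
                           description = sprintf("%s synthetic protein", sid),
                           stringsAsFactors = FALSE), fasta_path)
    proteome_paths[s] <- fasta_path

    all_hits[[s]] <- rbind(true_hits, noise_hits)
    if (n_true > 0L) {
      tt <- aggregate(list(count = gene_protein),
                      by = list(family = genes), FUN = length)
      tt$species_id <- sid
      truth[[s]] <- tt[, c("species_id", "family", "count")]
    }
  }

  hits <- do.call(rbind, all_hits)
  if (include_edge_cases) {
    edge <- plant_filter_edge_cases()
    hits <- rbind(hits, edge[, DOMHIT_COLS])
  }
  hits <- hits[order(hits$protein_id, hits$family_id, hits$evalue_dom), ]

  dom_path <- file.path(out_dir, "cazyme_hits.domtblout")
  write_domtblout(hits, dom_path)

  sp_path <- file.path(out_dir, "signalp_short.tsv")
  writeLines(c(
    "# SignalP-5.0\tOrganism: Eukarya\tTimestamp: fixed",
    "# ID\tPrediction\tSP(Sec/SPI)\tOTHER\tCS Position",
    unlist(signalp_rows)
  ), sp_path)

  meta_path <- file.path(out_dir, "species_metadata.tsv")
  write.table(metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  map_path <- file.path(out_dir, "substrate_map.tsv")
  file.copy(system.file("extdata", "substrate_map_default.tsv",
                        package = "yeastcaz"), map_path, overwrite = TRUE)

  tree_path <- file.path(out_dir, "species_tree.nwk")
  writeLines(synthetic_clade_tree(species, clade_of), tree_path)

  ground_truth <- if (length(truth) > 0L) {
    gt <- do.call(rbind, truth)
    gt <- gt[order(gt$species_id, gt$family), ]
    rownames(gt) <- NULL
    gt
  } else {
    data.frame(species_id = character(), family = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  gt_path <- file.path(out_dir, "ground_truth_counts.tsv")
  write.table(ground_truth, gt_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  out <- list(
    paths = list(proteomes = proteome_paths, domtblout = dom_path,
                 signalp = sp_path, metadata = meta_path,
                 substrate_map = map_path, tree = tree_path,
                 ground_truth = gt_path),
    ground_truth = ground_truth, metadata = metadata, config = config
  )
  if (include_edge_cases) out$edge_cases <- plant_filter_edge_cases()
  structure(out, class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf(
    "<dataset_manifest> %d species, %d clades, %d planted CAZyme genes (seed %d)\n",
    x$config$n_species, x$config$n_clades, sum(x$ground_truth$count),
    x$config$seed
  ))
  invisible(x)
}

# Ladder newick per clade, clades joined in a ladder; branch lengths from
# the active RNG stream, fixed 4-decimal formatting for byte determinism.
synthetic_clade_tree <- function(species, clade_of) {
  bl <- function() sprintf("%.4f", runif(1, 0.01, 0.2))
  # subtree strings carry no trailing branch length; lengths are added when
  # two subtrees are combined, so every edge gets exactly one length
  combine <- function(x, y) sprintf("(%s:%s,%s:%s)", x, bl(), y, bl())
  ladder <- function(labels) Reduce(combine, labels)
  subtrees <- vapply(unique(clade_of), function(cl) {
    ladder(species[clade_of == cl])
  }, character(1))
  paste0(Reduce(combine, subtrees), ";")
}

#' Write domain hits as an HMMER3 domtblout file
#'
#' Emits hmmsearch orientation (protein = target) with the 23-column layout
#' [parse_domtblout()] reads back; numeric formatting is fixed so identical
#' inputs give byte-identical files.
#'
#' @param hits domain-hit data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_domtblout <- function(hits, path) {
  validate_domain_hits(hits)
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  lines <- sprintf(
    "%s - %d %s - %d %.2g %.1f 0.1 1 1 %.2g %.2g %.1f 0.1 %d %d %d %d %d %d 0.90 -",
    hits$protein_id, hits$ali_to + 10L, hits$family_id, hits$hmm_length,
    hits$evalue_full, hits$bitscore, hits$evalue_dom / 10, hits$evalue_dom,
    hits$bitscore, hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
    hits$ali_from, hits$ali_to
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Plant filter-boundary edge cases
#'
#' Domain hits sitting exactly on, and just past, each filter boundary:
#' HMM coverage 0.35 (kept) and 0.3499 (dropped); full-sequence E-value
#' exactly 1e-15 (kept, inclusive threshold) and just past it (dropped);
#' a same-protein pair overlapping exactly 20% of the shorter span (both
#' kept) and one overlapping 21% (worse per-domain E-value dropped).
#'
#' @param thresholds a [filter_thresholds()] (used only to document which
#'   side each hit falls on; boundaries are fixed at the defaults).
#' @return domain-hit data frame with extra column `expected` in
#'   `{"keep", "evalue", "coverage", "overlap"}` — the fate of the hit under
#'   the default thresholds.
#' @export
plant_filter_edge_cases <- function(thresholds = filter_thresholds()) {
  hit <- function(protein, family, hmm_len, hmm_from, hmm_to, ali_from,
                  ali_to, ev_full, ev_dom, bits, expected) {
    data.frame(protein_id = protein, family_id = family, hmm_length = hmm_len,
               hmm_from = hmm_from, hmm_to = hmm_to, ali_from = ali_from,
               ali_to = ali_to, evalue_full = ev_full, evalue_dom = ev_dom,
               bitscore = bits, expected = expected, stringsAsFactors = FALSE)
  }
  rbind(
    # coverage boundary: 35/100 = 0.35 kept; 3499/10000 = 0.3499 dropped
    hit("edge_cov_keep", "GH10", 100L, 1L, 35L, 10L, 44L, 1e-30, 1e-30, 80, "keep"),
    hit("edge_cov_drop", "GH10", 10000L, 1L, 3499L, 10L, 300L, 1e-30, 1e-30, 80, "coverage"),
    # E-value boundary: exactly 1e-15 kept (inclusive); above dropped
    hit("edge_ev_tie", "GH11", 200L, 1L, 150L, 5L, 154L, 1e-15, 1e-15, 60, "keep"),
    hit("edge_ev_below", "GH11", 200L, 1L, 150L, 5L, 154L, 9e-16, 9e-16, 60, "keep"),
    hit("edge_ev_drop", "GH11", 200L, 1L, 150L, 5L, 154L, 1.1e-15, 1.1e-15, 60, "evalue"),
    # overlap exactly 0.20: both kept (20 shared / 100 shorter span)
    hit("edge_ovl20", "GH5_7", 300L, 1L, 200L, 1L, 100L, 1e-40, 1e-40, 90, "keep"),
    hit("edge_ovl20", "GH3", 300L, 1L, 200L, 81L, 180L, 1e-20, 1e-20, 70, "keep"),
    # overlap 0.21: worse per-domain E-value dropped (21 shared / 100)
    hit("edge_ovl21", "GH5_7", 300L, 1L, 200L, 1L, 100L, 1e-40, 1e-40, 90, "keep"),
    hit("edge_ovl21", "GH3", 300L, 1L, 200L, 80L, 179L, 1e-20, 1e-20, 70, "overlap")
  )
}

#' Simulate a DNS assay plate from known activities
#'
#' Inverts the assay arithmetic: each true activity (U/mL) is converted to
#' the reducing-sugar concentration it would release under the assay
#' geometry, then to an absorbance through the standard curve, optionally
#' with Gaussian absorbance noise. Back-calculation through
#' [plate_activities()] recovers the inputs exactly at zero noise.
#'
#' @param true_activities non-negative activities in U/mL.
#' @param curve_slope,curve_intercept standard-curve parameters (slope > 0).
#' @param noise_sd absorbance noise standard deviation (default 0).
#' @param n_replicates wells per activity.
#' @param config an [assay_config()].
#' @param seed RNG seed for the noise.
#' @return data frame `well`, `sample_id`, `true_activity`, `absorbance`.
#' @export
generate_assay_plate <- function(true_activities, curve_slope,
                                 curve_intercept, noise_sd = 0,
                                 n_replicates = 1L, config = assay_config(),
                                 seed = 1L) {
  if (any(true_activities < 0)) stop("negative activity")
  stopifnot(curve_slope > 0, noise_sd >= 0, n_replicates >= 1L)
  set.seed(seed)
  act <- rep(true_activities, each = n_replicates)
  conc <- act * config$sample_volume_uL * config$incubation_time_min /
    config$total_volume_uL
  absorbance <- curve_slope * conc + curve_intercept +
    rnorm(length(act), 0, noise_sd)
  data.frame(
    well = sprintf("W%03d", seq_along(act)),
    sample_id = rep(sprintf("S%03d", seq_along(true_activities)),
                    each = n_replicates),
    true_activity = act, absorbance = absorbance,
    stringsAsFactors = FALSE
  )
}
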