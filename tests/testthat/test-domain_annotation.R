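DOMLINE <- paste("p1 - 412 GH10 - 331 1.2e-45 152.3 0.1 1 1 3.1e-47 1.4e-45",
                 "150.9 0.1 5 320 30 360 25 368 0.95 -")

test_that("parse_domtblout reads the published column layout in both orientations", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment", DOMLINE), f)
  h <- parse_domtblout(f, orientation = "hmmsearch")
  expect_equal(h$protein_id, "p1")
  expect_equal(h$family_id, "GH10")
  expect_equal(h$hmm_length, 331L)
  expect_equal(h$hmm_from, 5L)
  expect_equal(h$hmm_to, 320L)
  expect_equal(h$ali_from, 30L)
  expect_equal(h$ali_to, 360L)
  expect_equal(h$evalue_full, 1.2e-45)
  expect_equal(h$evalue_dom, 1.4e-45)
  expect_equal(h$bitscore, 150.9)
  # hmmscan orientation swaps protein and family (and takes tlen = col 3)
  h2 <- parse_domtblout(f, orientation = "hmmscan")
  expect_equal(h2$protein_id, "GH10")
  expect_equal(h2$family_id, "p1")
  expect_equal(h2$hmm_length, 412L)
})

test_that("parse_domtblout handles headers, .hmm suffixes, and malformed lines", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# only", "# headers"), f)
  expect_equal(nrow(parse_domtblout(f)), 0L)
  writeLines(sub("GH10", "GH10.hmm", DOMLINE), f)
  expect_equal(parse_domtblout(f)$family_id, "GH10")
  writeLines("p1 - 412 GH10", f)
  expect_error(parse_domtblout(f), "line 1")
  writeLines(sub("1.2e-45", "notanumber", DOMLINE, fixed = TRUE), f)
  expect_error(parse_domtblout(f), "non-numeric")
})

test_that("hmm_coverage is the spanned fraction of the model", {
  h <- data.frame(hmm_from = c(5L, 1L, 10L), hmm_to = c(320L, 100L, 40L),
                  hmm_length = c(331L, 100L, 100L))
  expect_equal(hmm_coverage(h), c(316 / 331, 1, 0.31))
})

test_that("filter_hits keeps passing hits and records the first failed rule", {
  mk <- function(ev, cov) data.frame(
    protein_id = "p", family_id = "GH10", hmm_length = 100L, hmm_from = 1L,
    hmm_to = as.integer(round(cov * 100)), ali_from = 1L, ali_to = 50L,
    evalue_full = ev, evalue_dom = ev, bitscore = 100
  )
  hits <- rbind(mk(1e-20, 0.5), mk(1e-10, 0.9), mk(1e-20, 0.34))
  out <- filter_hits(hits)
  expect_equal(nrow(out$passed), 1L)
  expect_equal(out$passed$evalue_full, 1e-20)
  expect_equal(out$rejected$reason, c("evalue", "coverage"))
  # boundary: E-value exactly at the threshold is kept (inclusive)
  expect_equal(nrow(filter_hits(mk(1e-15, 0.5))$passed), 1L)
  expect_equal(nrow(filter_hits(mk(1e-20, 0.35))$passed), 1L)
})

test_that("resolve_overlaps drops the worse per-domain E-value past 20% overlap", {
  mk <- function(fam, from, to, ev) data.frame(
    protein_id = "p", family_id = fam, hmm_length = 200L, hmm_from = 1L,
    hmm_to = 150L, ali_from = from, ali_to = to, evalue_full = ev,
    evalue_dom = ev, bitscore = 100, stringsAsFactors = FALSE
  )
  # A(1-50, 1e-30), B(40-90, 1e-20), C(45-100, 1e-10):
  # A-B share 11/50 = 0.22 so B falls; A-C share 6/50 = 0.12 so C stands
  hits <- rbind(mk("A", 1, 50, 1e-30), mk("B", 40, 90, 1e-20),
                mk("C", 45, 100, 1e-10))
  res <- resolve_overlaps(hits)
  expect_setequal(res$accepted$family_id, c("A", "C"))
  expect_equal(res$rejected$family_id, "B")
  expect_equal(res$rejected$reason, "overlap")
  # non-overlapping hits are all kept
  res2 <- resolve_overlaps(rbind(mk("A", 1, 50, 1e-30), mk("B", 60, 90, 1e-20)))
  expect_equal(nrow(res2$accepted), 2L)
  # identical spans: only the better e-value survives
  res3 <- resolve_overlaps(rbind(mk("A", 1, 50, 1e-40), mk("B", 1, 50, 1e-16)))
  expect_equal(res3$accepted$family_id, "A")
  expect_error(resolve_overlaps(rbind(mk("A", 1, 50, 1e-30),
                                      within(mk("B", 1, 50, 1e-20),
                                             protein_id <- "q"))),
               "single protein")
})

test_that("greedy resolution matches the brute-force pairwise replay and is idempotent", {
  set.seed(11)
  for (rep in 1:50) {
    hits <- random_protein_hits(sample(2:10, 1))
    res <- resolve_overlaps(hits)
    oracle_rows <- oracle_resolve_indices(hits)
    got_rows <- sort(match(
      paste(res$accepted$family_id, res$accepted$ali_from,
            res$accepted$evalue_dom),
      paste(hits$family_id, hits$ali_from, hits$evalue_dom)))
    expect_equal(got_rows, oracle_rows)
    # all accepted pairs satisfy the overlap constraint
    acc <- res$accepted
    if (nrow(acc) > 1L) {
      for (i in seq_len(nrow(acc) - 1L)) {
        for (j in (i + 1L):nrow(acc)) {
          shared <- max(0, min(acc$ali_to[i], acc$ali_to[j]) -
                          max(acc$ali_from[i], acc$ali_from[j]) + 1)
          shorter <- min(acc$ali_to[i] - acc$ali_from[i] + 1,
                         acc$ali_to[j] - acc$ali_from[j] + 1)
          expect_lte(shared / shorter, 0.20)
        }
      }
    }
    # idempotence
    res2 <- resolve_overlaps(res$accepted)
    expect_equal(nrow(res2$accepted), nrow(res$accepted))
    expect_equal(sort(res2$accepted$ali_from), sort(res$accepted$ali_from))
  }
})

test_that("relaxing thresholds never decreases the number of passing hits", {
  set.seed(3)
  hits <- do.call(rbind, lapply(1:20, function(i) {
    h <- random_protein_hits(1, protein = paste0("p", i))
    h$evalue_full <- 10^runif(1, -30, -5)
    h$hmm_to <- as.integer(sample(30:200, 1))
    h
  }))
  base <- nrow(filter_hits(hits, filter_thresholds())$passed)
  looser_e <- nrow(filter_hits(hits, filter_thresholds(evalue_max = 1e-10))$passed)
  looser_c <- nrow(filter_hits(hits, filter_thresholds(coverage_min = 0.10))$passed)
  expect_gte(looser_e, base)
  expect_gte(looser_c, base)
})

test_that("annotate_proteome composes filters, joins secretion, and audits rejects", {
  recs <- data.frame(id = c("p1", "p2", "p3"), species_id = "sp1",
                     sequence = "MKL", description = "")
  mk <- function(p, fam, ev, cov) data.frame(
    protein_id = p, family_id = fam, hmm_length = 100L, hmm_from = 1L,
    hmm_to = as.integer(round(cov * 100)), ali_from = 1L, ali_to = 50L,
    evalue_full = ev, evalue_dom = ev, bitscore = 100,
    stringsAsFactors = FALSE
  )
  hits <- rbind(mk("p1", "GH10", 1e-40, 0.9),  # accepted, secreted
                mk("p2", "GH11", 1e-5, 0.9),   # rejected: evalue
                mk("p3", "CE1", 1e-40, 0.2))   # rejected: coverage
  calls <- data.frame(protein_id = "p1", prediction = "SP(Sec/SPI)",
                      sp_probability = 0.97, other_probability = 0.03,
                      cs_from = 18L, cs_to = 19L)
  ann <- annotate_proteome(recs, hits, calls)
  expect_equal(ann$annotations$protein_id, "p1")
  expect_equal(ann$annotations$family, "GH10")
  expect_true(ann$annotations$secreted)
  expect_setequal(ann$audit$protein_id, c("p2", "p3"))
  expect_setequal(ann$audit$reason, c("evalue", "coverage"))
  # unknown hit ids are skipped with a warning (or an error on request)
  stray <- rbind(hits[1, ], within(hits[1, ], protein_id <- "ghost"))
  expect_warning(annotate_proteome(recs, stray, calls), "ghost")
  expect_error(annotate_proteome(recs, stray, calls, unknown_ids = "error"),
               "ghost")
})

test_that("annotation TSV round-trips all fields exactly", {
  set.seed(5)
  hits <- random_protein_hits(6)
  ann <- annotate_proteome(NULL, hits)$annotations
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  back$species_id <- as.character(back$species_id)
  expect_equal(back, ann)
})
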