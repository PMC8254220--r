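# Independent oracle implementations used to cross-check the package's own
# algorithms. These deliberately use different code paths (full-matrix DP,
# explicit double loops, recursive enumeration) from the implementations.

# Longest-common-subsequence match count via a plain full DP matrix,
# X matching nothing.
oracle_match_count <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (av[i] == bv[j] && av[i] != "X") {
        L[i + 1L, j + 1L] <- L[i, j] + 1L
      } else {
        L[i + 1L, j + 1L] <- max(L[i, j + 1L], L[i + 1L, j])
      }
    }
  }
  L[n + 1L, m + 1L]
}

oracle_identity <- function(a, b) {
  oracle_match_count(a, b) / min(nchar(a), nchar(b))
}

# Brute-force replay of the overlap-resolution contract: visit hits in the
# documented priority order and accept a hit iff an explicit pairwise check
# against every accepted hit passes. Returns row indices of accepted hits.
oracle_resolve_indices <- function(hits, overlap_max = 0.20) {
  pri <- order(hits$evalue_dom, -hits$bitscore, hits$ali_from, hits$family_id)
  accepted <- integer(0)
  for (i in pri) {
    ok <- TRUE
    for (j in accepted) {
      lo <- max(hits$ali_from[i], hits$ali_from[j])
      hi <- min(hits$ali_to[i], hits$ali_to[j])
      shared <- max(0L, hi - lo + 1L)
      shorter <- min(hits$ali_to[i] - hits$ali_from[i] + 1L,
                     hits$ali_to[j] - hits$ali_from[j] + 1L)
      if (shared / shorter > overlap_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  sort(accepted)
}

# Recursive enumeration of all global alignments (match +1, mismatch 0,
# gap -1), returning the best (score, matches, -columns) lexicographically.
# Only usable for very short sequences.
oracle_alignment_best <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- c(score = -Inf, matches = -Inf, negcols = -Inf)
  rec <- function(i, j, score, matches, cols) {
    if (i > length(av) && j > length(bv)) {
      cand <- c(score, matches, -cols)
      if (cand[1] > best[1] ||
          (cand[1] == best[1] && cand[2] > best[2]) ||
          (cand[1] == best[1] && cand[2] == best[2] && cand[3] > best[3])) {
        best <<- cand
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      m <- as.integer(av[i] == bv[j])
      rec(i + 1L, j + 1L, score + m, matches + m, cols + 1L)
    }
    if (i <= length(av)) rec(i + 1L, j, score - 1L, matches, cols + 1L)
    if (j <= length(bv)) rec(i, j + 1L, score - 1L, matches, cols + 1L)
  }
  rec(1L, 1L, 0L, 0L, 0L)
  list(score = best[[1]], matches = best[[2]], cols = -best[[3]],
       identity = 100 * best[[2]] / -best[[3]])
}

# Random filtered-looking domain hits on one protein, for resolution
# property tests.
random_protein_hits <- function(n_hits, protein = "p1") {
  starts <- sample(1:300, n_hits, replace = TRUE)
  lens <- sample(20:120, n_hits, replace = TRUE)
  ev <- 10^runif(n_hits, -60, -16)
  data.frame(
    protein_id = protein,
    family_id = sample(c("GH10", "GH11", "GH5_7", "GH3", "CE1"), n_hits,
                       replace = TRUE),
    hmm_length = 200L, hmm_from = 1L, hmm_to = 150L,
    ali_from = starts, ali_to = starts + lens - 1L,
    evalue_full = ev, evalue_dom = ev * 10^runif(n_hits, -0.5, 0.5),
    bitscore = round(runif(n_hits, 20, 300), 1),
    stringsAsFactors = FALSE
  )
}

random_aa_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"), len,
               replace = TRUE), collapse = "")
}
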