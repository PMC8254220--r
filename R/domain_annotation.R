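#' Default domain-filter thresholds
#'
#' The three-rule filter used throughout: keep a hit iff its full-sequence
#' E-value is at most `evalue_max` and the hit spans at least `coverage_min`
#' of the HMM model; then, among surviving hits on the same protein, drop the
#' hit with the worse per-domain E-value whenever two hits overlap more than
#' `overlap_max` of the shorter alignment span.
#'
#' @param evalue_max maximum full-sequence E-value (inclusive). Default 1e-15.
#' @param coverage_min minimum HMM model coverage (inclusive). Default 0.35.
#' @param overlap_max maximum tolerated pairwise overlap fraction. Default 0.20.
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(evalue_max = 1e-15, coverage_min = 0.35,
                              overlap_max = 0.20) {
  stopifnot(evalue_max > 0, coverage_min > 0, coverage_min <= 1,
            overlap_max > 0, overlap_max <= 1)
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 overlap_max = overlap_max), class = "filter_thresholds")
}

DOMHIT_COLS <- c("protein_id", "family_id", "hmm_length", "hmm_from", "hmm_to",
                 "ali_from", "ali_to", "evalue_full", "evalue_dom", "bitscore")

validate_domain_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(DOMHIT_COLS %in% names(hits)))
  if (nrow(hits) == 0L) return(hits)
  with(hits, {
    if (any(hmm_from < 1 | hmm_from > hmm_to | hmm_to > hmm_length))
      stop("invalid HMM coordinates: need 1 <= hmm_from <= hmm_to <= hmm_length")
    if (any(ali_from < 1 | ali_from > ali_to))
      stop("invalid alignment coordinates: need 1 <= ali_from <= ali_to")
    if (any(evalue_full < 0 | evalue_dom < 0)) stop("negative E-value")
  })
  hits
}

empty_domain_hits <- function() {
  data.frame(
    protein_id = character(), family_id = character(),
    hmm_length = integer(), hmm_from = integer(), hmm_to = integer(),
    ali_from = integer(), ali_to = integer(),
    evalue_full = numeric(), evalue_dom = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Parse an HMMER3 per-domain table (domtblout)
#'
#' Reads the 23+-column whitespace-delimited table written by `hmmsearch` or
#' `hmmscan` with `--domtblout`. The `orientation` argument states which
#' program produced the file: for `hmmsearch` the protein is the target
#' (column 1) and the CAZyme HMM the query (column 4); for `hmmscan` the two
#' swap, as do the length columns. A trailing `.hmm` suffix on the family
#' name is stripped.
#'
#' @param path path to a domtblout file.
#' @param orientation `"hmmsearch"` (default) or `"hmmscan"`.
#' @return data frame of domain hits with columns `protein_id`, `family_id`,
#'   `hmm_length`, `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, `evalue_full`,
#'   `evalue_dom` (the independent per-domain i-Evalue), `bitscore`
#'   (per-domain score).
#' @export
parse_domtblout <- function(path, orientation = c("hmmsearch", "hmmscan")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("domtblout file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty_domain_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23L)) {
    i <- which(nf < 23L)[1]
    stop("domtblout line ", lineno[i], " has ", nf[i],
         " columns; at least 23 expected")
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  num <- function(k, what) {
    x <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(x)) {
      i <- which(is.na(x))[1]
      stop("non-numeric ", what, " ('", col(k)[i], "') on domtblout line ",
           lineno[i])
    }
    x
  }
  if (orientation == "hmmsearch") {
    protein <- col(1); family <- col(4); hmm_len <- num(6, "qlen")
  } else {
    protein <- col(4); family <- col(1); hmm_len <- num(3, "tlen")
  }
  validate_domain_hits(data.frame(
    protein_id = protein,
    family_id = sub("\\.hmm$", "", family),
    hmm_length = as.integer(hmm_len),
    hmm_from = as.integer(num(16, "hmm from")),
    hmm_to = as.integer(num(17, "hmm to")),
    ali_from = as.integer(num(18, "ali from")),
    ali_to = as.integer(num(19, "ali to")),
    evalue_full = num(7, "full-sequence E-value"),
    evalue_dom = num(13, "i-Evalue"),
    bitscore = num(14, "domain score"),
    stringsAsFactors = FALSE
  ))
}

#' Fraction of the HMM model covered by a hit
#'
#' @param hits domain-hit data frame (vectorised).
#' @return numeric vector `(hmm_to - hmm_from + 1) / hmm_length`.
#' @export
hmm_coverage <- function(hits) {
  (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
}

#' Apply the E-value and HMM-coverage filters
#'
#' Keeps a hit iff `evalue_full <= evalue_max` (both boundaries inclusive:
#' HMMER's `-E` is an inclusive reporting threshold, so a hit at exactly the
#' threshold is kept) and `hmm_coverage >= coverage_min`. The rejection
#' reason records the first failed rule, E-value checked first.
#'
#' @param hits domain-hit data frame.
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `passed` (hit data frame) and `rejected` (hit data frame
#'   with extra column `reason` in `{"evalue", "coverage"}`).
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  validate_domain_hits(hits)
  cov <- hmm_coverage(hits)
  bad_e <- hits$evalue_full > thresholds$evalue_max
  bad_c <- !bad_e & cov < thresholds$coverage_min
  rejected <- hits[bad_e | bad_c, , drop = FALSE]
  rejected$reason <- as.character(ifelse(bad_e[bad_e | bad_c], "evalue", "coverage"))
  list(passed = hits[!(bad_e | bad_c), , drop = FALSE], rejected = rejected)
}

# Overlap between two hits on the same protein: shared residues divided by
# the shorter of the two alignment spans (the dbCAN-parser convention).
ali_overlap <- function(from1, to1, from2, to2) {
  shared <- pmax(0, pmin(to1, to2) - pmax(from1, from2) + 1)
  shared / pmin(to1 - from1 + 1, to2 - from2 + 1)
}

# Greedy acceptance order for overlap resolution: better per-domain i-Evalue
# first; ties by higher bitscore, then leftmost start, then family name.
overlap_order <- function(hits) {
  order(hits$evalue_dom, -hits$bitscore, hits$ali_from, hits$family_id)
}

#' Resolve overlapping domains on one protein
#'
#' Greedy resolution of the rule that when two domains overlap more than
#' `overlap_max` of the shorter alignment span, only the domain with the
#' better per-domain E-value is retained. Hits are visited in the order of
#' [overlap_order()] and accepted iff their overlap with every
#' already-accepted hit is at most `overlap_max`. With exactly two
#' conflicting domains this reduces to the pairwise rule.
#'
#' @param hits hits for a single protein that already passed [filter_hits()].
#' @param overlap_max maximum tolerated overlap fraction (default 0.20).
#' @return list with `accepted` (ordered by `ali_from`) and `rejected`
#'   (with column `reason = "overlap"`).
#' @export
resolve_overlaps <- function(hits, overlap_max = 0.20) {
  validate_domain_hits(hits)
  if (nrow(hits) > 0L && length(unique(hits$protein_id)) > 1L) {
    stop("resolve_overlaps() expects hits for a single protein; got ",
         length(unique(hits$protein_id)))
  }
  ord <- overlap_order(hits)
  acc <- integer(0)
  rej <- integer(0)
  for (i in ord) {
    ok <- all(ali_overlap(hits$ali_from[i], hits$ali_to[i],
                          hits$ali_from[acc], hits$ali_to[acc]) <= overlap_max)
    if (ok) acc <- c(acc, i) else rej <- c(rej, i)
  }
  accepted <- hits[acc[order(hits$ali_from[acc], hits$ali_to[acc])], , drop = FALSE]
  rejected <- hits[rej, , drop = FALSE]
  if (nrow(rejected) > 0L) rejected$reason <- "overlap" else rejected$reason <- character(0)
  list(accepted = accepted, rejected = rejected)
}

#' Annotate a proteome with filtered CAZyme domains
#'
#' Full composition of the hit filter: E-value and coverage rules, per-protein
#' overlap resolution, then a left join of secretion calls (missing call =
#' not secreted). Proteins whose hits are all rejected carry no annotation
#' but remain visible in the audit table with their rejection reasons.
#'
#' @param records protein records (columns `id`, `species_id`); may be `NULL`
#'   to skip the id check.
#' @param hits domain-hit data frame for these proteins.
#' @param secretion_calls optional data frame from [parse_signalp_short()].
#' @param thresholds a [filter_thresholds()] object.
#' @param unknown_ids `"warn"` (default) to warn and skip hits whose protein
#'   id is not among `records$id`, or `"error"`.
#' @return list of class `proteome_annotation`: `annotations` (data frame
#'   `protein_id`, `species_id`, `family`, `ali_from`, `ali_to`,
#'   `hmm_coverage`, `evalue_full`, `evalue_dom`, `secreted`) and `audit`
#'   (all rejected hits with `reason`).
#' @export
annotate_proteome <- function(records, hits, secretion_calls = NULL,
                              thresholds = filter_thresholds(),
                              unknown_ids = c("warn", "error")) {
  unknown_ids <- match.arg(unknown_ids)
  validate_domain_hits(hits)
  if (!is.null(records)) {
    unknown <- setdiff(unique(hits$protein_id), records$id)
    if (length(unknown) > 0L) {
      msg <- paste0(length(unknown), " hit protein id(s) not in the proteome: ",
                    paste(head(unknown, 5), collapse = ", "))
      if (unknown_ids == "error") stop(msg)
      warning(msg, "; skipping")
      hits <- hits[hits$protein_id %in% records$id, , drop = FALSE]
    }
  }
  flt <- filter_hits(hits, thresholds)
  audit <- flt$rejected
  accepted <- empty_domain_hits()
  if (nrow(flt$passed) > 0L) {
    per_protein <- split(flt$passed, flt$passed$protein_id)
    for (ph in per_protein) {
      res <- resolve_overlaps(ph, thresholds$overlap_max)
      accepted <- rbind(accepted, res$accepted)
      if (nrow(res$rejected) > 0L) {
        audit <- rbind(audit, res$rejected)
      }
    }
  }
  secreted_ids <- character(0)
  if (!is.null(secretion_calls) && nrow(secretion_calls) > 0L) {
    secreted_ids <- secretion_calls$protein_id[is_secreted(secretion_calls)]
  }
  species <- if (!is.null(records)) {
    setNames(records$species_id, records$id)
  } else {
    NULL
  }
  ann <- data.frame(
    protein_id = accepted$protein_id,
    species_id = if (is.null(species)) NA_character_ else unname(species[accepted$protein_id]),
    family = accepted$family_id,
    ali_from = accepted$ali_from, ali_to = accepted$ali_to,
    hmm_coverage = if (nrow(accepted) > 0L) hmm_coverage(accepted) else numeric(0),
    evalue_full = accepted$evalue_full, evalue_dom = accepted$evalue_dom,
    secreted = accepted$protein_id %in% secreted_ids,
    stringsAsFactors = FALSE
  )
  structure(list(annotations = ann, audit = audit),
            class = "proteome_annotation")
}

#' @export
print.proteome_annotation <- function(x, ...) {
  cat(sprintf(
    "<proteome_annotation> %d accepted domain(s) on %d protein(s); %d rejected\n",
    nrow(x$annotations), length(unique(x$annotations$protein_id)), nrow(x$audit)
  ))
  invisible(x)
}

#' Write and re-read resolved annotations
#'
#' TSV round-trip of the accepted-annotation table; all numeric fields are
#' written at full precision so re-reading reproduces them exactly.
#'
#' @param annotations the `annotations` data frame of a `proteome_annotation`.
#' @param path TSV path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   the data frame.
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations
  for (col in c("evalue_full", "evalue_dom", "hmm_coverage")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$secreted <- as.logical(df$secreted)
  df
}
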