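#' Read a protein FASTA file
#'
#' Reads single-line or wrapped FASTA into a data frame of protein records.
#' The header is split at the first whitespace into an identifier and a free
#' text description.
#'
#' @param path path to a FASTA file.
#' @param species_id species attribution recorded on every record; defaults to
#'   the file name without extension.
#' @return data frame with columns `id`, `species_id`, `sequence`,
#'   `description`. An empty file returns zero rows with a warning.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a xylanase", "MKL", "SNA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  species_id <- species_id %||% tools::file_path_sans_ext(basename(path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty_protein_records())
  }
  # BString: keep raw characters so invalid residues are caught (and
  # reported with their position) rather than silently dropped
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(empty_protein_records())
  }
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty identifier in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(aas))
  for (i in seq_along(seqs)) {
    bad <- regmatches(seqs[i], gregexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs[i]))[[1]]
    if (length(bad) > 0L) {
      pos <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs[i])
      stop("non-amino-acid character '", bad[1], "' at position ", pos,
           " in record ", ids[i])
    }
    if (nchar(seqs[i]) == 0L) stop("zero-length sequence in record ", ids[i])
  }
  data.frame(
    id = unname(ids), species_id = species_id, sequence = unname(seqs),
    description = unname(desc), row.names = NULL, stringsAsFactors = FALSE
  )
}

empty_protein_records <- function() {
  data.frame(
    id = character(), species_id = character(),
    sequence = character(), description = character(),
    stringsAsFactors = FALSE
  )
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns. `read_fasta()` of the written file
#' round-trips all fields.
#'
#' @param records data frame as returned by [read_fasta()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  aas <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(aas) <- ifelse(desc == "" | is.na(desc), records$id,
                       paste(records$id, desc))
  Biostrings::writeXStringSet(aas, filepath = path, width = 60L)
  invisible(path)
}

# Residue composition upper bound on the number of alignment matches between
# two sequences: no alignment can match a letter more often than it occurs in
# both. X never matches.
composition_match_bound <- function(a, b) {
  ta <- table(strsplit(a, "")[[1]])
  tb <- table(strsplit(b, "")[[1]])
  common <- setdiff(intersect(names(ta), names(tb)), "X")
  if (length(common) == 0L) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

# Maximum number of exact matches over all global alignments with free gaps
# (match +1, mismatch 0, gap 0). Under this scoring the optimum equals the
# longest common subsequence, computed row-wise with a cummax recurrence.
# X matches nothing.
max_alignment_matches <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    match_row <- as.integer(bv == av[i] & av[i] != "X")
    cand <- pmax(prev[seq_len(m)] + match_row, prev[-1L])
    curr <- c(0L, cummax(cand))
    prev <- curr
  }
  prev[m + 1L]
}

#' Pairwise sequence identity for clustering
#'
#' Identity between two protein sequences defined as the maximum number of
#' exact residue matches over all global alignments scored match +1,
#' mismatch 0, gaps free, divided by the length of the shorter sequence.
#' `X` matches nothing.
#'
#' @param a,b amino-acid strings.
#' @return identity fraction in `[0, 1]`.
#' @export
cluster_identity <- function(a, b) {
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  if (a == b && !grepl("X", a, fixed = TRUE)) return(1)
  max_alignment_matches(a, b) / min(nchar(a), nchar(b))
}

#' De-duplicate a proteome by greedy identity clustering
#'
#' Greedy longest-first clustering in the style of CD-HIT's representative
#' selection: sequences are visited by decreasing length (ties broken by
#' identifier); each sequence joins the first previously accepted
#' representative to which its [cluster_identity()] is at least `threshold`,
#' otherwise it founds a new cluster. A cheap residue-composition bound on the
#' match count prunes hopeless comparisons before the alignment is computed.
#'
#' @param records protein record data frame (columns `id`, `sequence`).
#' @param threshold identity threshold in `(0, 1]`; default 0.98, the
#'   conventional near-duplicate cutoff for proteome de-duplication.
#' @return object of class `cluster_result`: list with `representatives`
#'   (character vector of ids, in acceptance order), `membership` (data frame
#'   `member_id`, `representative_id`, `identity`) and `identity_threshold`.
#' @examples
#' recs <- data.frame(id = c("a", "b"), sequence = c("MKLSNA", "MKLSNA"))
#' dedup_proteome(recs)$representatives
#' @export
dedup_proteome <- function(records, threshold = 0.98) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            threshold > 0, threshold <= 1)
  ord <- order(-nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  lens <- nchar(seqs)

  rep_idx <- integer(0)
  member_rep <- character(nrow(records))
  member_ident <- numeric(nrow(records))
  for (i in seq_along(ids)) {
    assigned <- FALSE
    for (r in rep_idx) {
      short_len <- min(lens[i], lens[r])
      if (composition_match_bound(seqs[i], seqs[r]) / short_len < threshold) next
      ident <- cluster_identity(seqs[i], seqs[r])
      if (ident >= threshold) {
        member_rep[i] <- ids[r]
        member_ident[i] <- ident
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      member_rep[i] <- ids[i]
      member_ident[i] <- 1
    }
  }
  structure(list(
    representatives = ids[rep_idx],
    membership = data.frame(
      member_id = ids, representative_id = member_rep,
      identity = member_ident, stringsAsFactors = FALSE
    ),
    identity_threshold = threshold
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d sequences -> %d representatives (identity >= %g)\n",
    nrow(x$membership), length(x$representatives), x$identity_threshold
  ))
  invisible(x)
}

#' Write a cluster membership table
#'
#' @param clusters a `cluster_result`.
#' @param path output TSV path (columns member_id, representative_id, identity).
#' @return invisibly, `path`.
#' @export
write_cluster_table <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_result"))
  write.table(clusters$membership, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
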