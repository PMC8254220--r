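#' Default xylanolytic family set
#'
#' The CAZyme families conventionally implicated in xylan depolymerisation:
#' GH10/GH11 endo-xylanases, GH30 glucuronoxylanases, GH43/GH51/GH62
#' arabinofuranosidases, GH67/GH115 glucuronidases, GH3 exo-glycosidases,
#' the poly-specific GH5, and the CE1/CE4/CE5/CE15 esterases. Parent names
#' match all subfamilies (see [family_in_set()]).
#' @export
XYLAN_FAMILY_SET <- c(
  "CE1", "CE4", "CE5", "CE15", "GH3", "GH5", "GH10", "GH11",
  "GH30", "GH43", "GH51", "GH62", "GH67", "GH115"
)

#' Parse a family copy-number list
#'
#' Parses cell text in copy notation, e.g. `"CE1(2), CE4(3), CE15"`:
#' comma/whitespace-separated tokens of the form `NAME` or `NAME(k)`, where
#' an absent parenthesised count means one copy.
#'
#' @param text a single string (empty or NA yields zero entries).
#' @return data frame `family`, `copies` in input order.
#' @examples
#' parse_family_copy_list("GH5_5(2), GH5_9(2), GH5_49")
#' @export
parse_family_copy_list <- function(text) {
  empty <- data.frame(family = character(), copies = integer(),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L) stop("parse_family_copy_list() takes a single string")
  if (is.na(text) || trimws(text) == "") return(empty)
  tokens <- trimws(strsplit(text, ",")[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(empty)
  m <- regexec("^([A-Za-z]+[0-9]+(?:_[0-9]+)?)\\s*(?:\\(([0-9]+)\\))?$", tokens)
  parts <- regmatches(tokens, m)
  bad <- lengths(parts) == 0L
  if (any(bad)) stop("malformed family token: '", tokens[bad][1], "'")
  data.frame(
    family = vapply(parts, `[[`, character(1), 2),
    copies = as.integer(ifelse(vapply(parts, `[[`, character(1), 3) == "",
                               "1", vapply(parts, `[[`, character(1), 3))),
    stringsAsFactors = FALSE
  )
}

#' Render family copy entries back to text
#'
#' Inverse of [parse_family_copy_list()] up to whitespace normalisation:
#' single copies render bare, multiples with a parenthesised count.
#'
#' @param entries data frame `family`, `copies`.
#' @return a single string.
#' @export
render_family_copy_list <- function(entries) {
  if (nrow(entries) == 0L) return("")
  paste(ifelse(entries$copies == 1L, entries$family,
               sprintf("%s(%d)", entries$family, entries$copies)),
        collapse = ", ")
}

#' Total copies in a set of family copy entries
#'
#' @param entries data frame `family`, `copies` (or text, which is parsed).
#' @return integer sum of copies.
#' @export
species_total <- function(entries) {
  if (is.character(entries)) entries <- parse_family_copy_list(entries)
  as.integer(sum(entries$copies))
}

#' Dataset-wide prevalence of a CAZyme family
#'
#' How many of the profiled species carry at least one gene of `family`
#' (subfamily-aware: `GH5` counts species with any GH5 subfamily).
#'
#' @param profiles a `cazyme_profiles` object.
#' @param family one family or parent-family name.
#' @return list with `k` (species carrying it), `N` (species profiled) and
#'   `label` rendered `"k/N"`.
#' @export
family_prevalence <- function(profiles, family) {
  stopifnot(inherits(profiles, "cazyme_profiles"), length(family) == 1L)
  counts <- profiles$counts
  carriers <- unique(counts$species_id[family_in_set(counts$family, family) &
                                         counts$n >= 1L])
  k <- length(carriers)
  N <- nrow(profiles$species)
  stopifnot(N >= 1L)
  list(k = k, N = N, label = sprintf("%d/%d", k, N))
}

#' Families unique to a single species
#'
#' Flags every (species, family) pair whose family occurs in exactly one
#' species dataset-wide — the analog of bold entries in a xylanolytic
#' family table.
#'
#' @param profiles a `cazyme_profiles` object.
#' @return data frame `species_id`, `family`.
#' @export
unique_family_flags <- function(profiles) {
  stopifnot(inherits(profiles, "cazyme_profiles"))
  if (nrow(profiles$species) < 2L) {
    warning("unique-family flags over fewer than 2 species are not meaningful")
  }
  counts <- profiles$counts[profiles$counts$n >= 1L, , drop = FALSE]
  carriers <- table(unique(counts[, c("species_id", "family")])$family)
  uniq <- names(carriers)[carriers == 1L]
  out <- counts[counts$family %in% uniq, c("species_id", "family")]
  out <- out[order(out$species_id, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a xylanolytic CAZyme report
#'
#' One row per species, restricted to the xylanolytic family set, with
#' copy-number notation per family, dataset-wide prevalence, unique-family
#' flags and a per-species total. Species without any set-member family are
#' retained with total 0.
#'
#' @param profiles a `cazyme_profiles` object.
#' @param xylan_family_set families to report (default [XYLAN_FAMILY_SET]);
#'   parent names match all subfamilies.
#' @return list of class `xylanolytic_report` with elements `rows` (data
#'   frame `species_id`, `clade`, `entries` in copy notation, `unique`
#'   comma-separated unique families, `total`) and `prevalence` (data frame
#'   `family`, `k`, `N`, `label` for each parent family of the set).
#' @export
build_xylanolytic_table <- function(profiles,
                                    xylan_family_set = XYLAN_FAMILY_SET) {
  stopifnot(inherits(profiles, "cazyme_profiles"))
  counts <- profiles$counts
  in_set <- family_in_set(counts$family, xylan_family_set)
  sub <- counts[in_set, , drop = FALSE]
  uniq <- unique_family_flags(profiles)
  sp <- profiles$species
  rows <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
    sid <- sp$species_id[i]
    entries <- sub[sub$species_id == sid, , drop = FALSE]
    entries <- entries[order(entries$class, entries$family), , drop = FALSE]
    uf <- intersect(entries$family, uniq$family[uniq$species_id == sid])
    data.frame(
      species_id = sid, clade = sp$clade[i],
      entries = render_family_copy_list(
        data.frame(family = entries$family, copies = entries$n)),
      unique = paste(uf, collapse = ","),
      total = as.integer(sum(entries$n)),
      stringsAsFactors = FALSE
    )
  }))
  prevalence <- do.call(rbind, lapply(xylan_family_set, function(f) {
    p <- family_prevalence(profiles, f)
    data.frame(family = f, k = p$k, N = p$N, label = p$label,
               stringsAsFactors = FALSE)
  }))
  structure(list(rows = rows, prevalence = prevalence),
            class = "xylanolytic_report")
}

#' @export
print.xylanolytic_report <- function(x, ...) {
  cat(sprintf("<xylanolytic_report> %d species, grand total %d genes\n",
              nrow(x$rows), sum(x$rows$total)))
  invisible(x)
}

#' Read a printed xylanolytic family table transcription
#'
#' Reads a TSV transcription of a published per-species xylanolytic CAZyme
#' table: columns `clade`, `species`, one column per family group in copy
#' notation, `printed_total` and `unique_printed`. The default file is the
#' transcription shipped with the package.
#'
#' @param path TSV path.
#' @return data frame with the cell columns plus `printed_total`,
#'   `unique_printed`.
#' @export
read_printed_xylanolytic_table <- function(path = system.file(
  "extdata", "xylanolytic_table_printed.tsv", package = "yeastcaz")) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
             check.names = FALSE)
}

#' Validate a printed table transcription against its own arithmetic
#'
#' Recomputes each row's total from the copy-notation cells and compares it
#' with the printed total, flagging rows where the two disagree (transcription
#' or arithmetic slips in the source are reported, never silently corrected).
#'
#' @param printed data frame from [read_printed_xylanolytic_table()].
#' @return data frame `species`, `computed_total`, `printed_total`,
#'   `consistent`.
#' @export
validate_printed_totals <- function(printed) {
  cell_cols <- setdiff(names(printed),
                       c("clade", "species", "printed_total", "unique_printed"))
  computed <- vapply(seq_len(nrow(printed)), function(i) {
    sum(vapply(cell_cols,
               function(cc) species_total(printed[[cc]][i]), integer(1)))
  }, numeric(1))
  data.frame(
    species = printed$species,
    computed_total = as.integer(computed),
    printed_total = printed$printed_total,
    consistent = computed == printed$printed_total,
    stringsAsFactors = FALSE
  )
}
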