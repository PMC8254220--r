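#' Substrate categories recognised by the heatmap
#'
#' The nine polysaccharide-degradation categories a CAZyme family can be
#' assigned to. "beta-glucan" is the ASCII spelling used throughout.
#' @export
SUBSTRATE_CATEGORIES <- c(
  "beta-glucan", "cellulose", "chitin", "lignin", "mannan",
  "pectin", "starch", "xylan", "xyloglucan"
)

#' Does a family belong to a family set?
#'
#' Subfamily-aware matching: a set entry naming a parent family (`GH5`)
#' matches the family itself and all its subfamilies (`GH5_7`); an entry
#' naming a subfamily (`GH43_14`) matches only exactly.
#'
#' @param family character vector of family names.
#' @param set character vector of family or subfamily names.
#' @return logical vector.
#' @export
family_in_set <- function(family, set) {
  family %in% set | sub("_.*$", "", family) %in% set
}

#' Build per-species CAZyme profiles
#'
#' Aggregates accepted domain annotations into per-species family counts.
#' The counting unit is the distinct (protein, family) pair — it counts
#' CAZyme-encoding genes, so a protein carrying two accepted GH5_22 domains
#' contributes 1 to GH5_22, while a protein with GH10 + CBM13 contributes to
#' both families.
#'
#' @param annotations `annotations` data frame of [annotate_proteome()] (or a
#'   `proteome_annotation` object), columns `protein_id`, `species_id`,
#'   `family`.
#' @param metadata data frame `species_id`, `clade`. Species present in the
#'   annotations but missing here get clade `"unknown"` with a warning;
#'   species listed here but absent from the annotations appear with all-zero
#'   profiles.
#' @return object of class `cazyme_profiles`: list with `counts` (long data
#'   frame `species_id`, `clade`, `family`, `class`, `n`) and `species`
#'   (data frame `species_id`, `clade`).
#' @export
build_profiles <- function(annotations, metadata) {
  if (inherits(annotations, "proteome_annotation")) {
    annotations <- annotations$annotations
  }
  stopifnot(all(c("protein_id", "species_id", "family") %in% names(annotations)),
            all(c("species_id", "clade") %in% names(metadata)))
  missing_meta <- setdiff(unique(annotations$species_id), metadata$species_id)
  if (length(missing_meta) > 0L) {
    warning("species missing from metadata, clade set to 'unknown': ",
            paste(missing_meta, collapse = ", "))
    metadata <- rbind(metadata[, c("species_id", "clade")],
                      data.frame(species_id = missing_meta, clade = "unknown"))
  }
  species <- metadata[!duplicated(metadata$species_id),
                      c("species_id", "clade"), drop = FALSE]
  rownames(species) <- NULL

  uniq <- unique(annotations[, c("species_id", "protein_id", "family")])
  if (nrow(uniq) > 0L) {
    counts <- aggregate(list(n = uniq$protein_id),
                        by = list(species_id = uniq$species_id,
                                  family = uniq$family),
                        FUN = length)
  } else {
    counts <- data.frame(species_id = character(), family = character(),
                         n = integer(), stringsAsFactors = FALSE)
  }
  counts$clade <- species$clade[match(counts$species_id, species$species_id)]
  counts$class <- if (nrow(counts) > 0L) cazy_class(counts$family) else character(0)
  counts <- counts[order(counts$species_id, counts$family),
                   c("species_id", "clade", "family", "class", "n")]
  rownames(counts) <- NULL
  structure(list(counts = counts, species = species),
            class = "cazyme_profiles")
}

#' @export
print.cazyme_profiles <- function(x, ...) {
  cat(sprintf("<cazyme_profiles> %d species, %d families, %d gene counts\n",
              nrow(x$species), length(unique(x$counts$family)), sum(x$counts$n)))
  invisible(x)
}

#' Per-species totals and class breakdown
#'
#' @param profiles a `cazyme_profiles` object.
#' @return data frame with one row per species: `species_id`, `clade`, one
#'   column per CAZy class (GH, GT, PL, CE, AA, CBM), `total` (all classes)
#'   and `total_excl_gt` (glycosyltransferases excluded — the headline count
#'   used for ranking, since GTs are biosynthetic rather than degradative).
#' @export
profile_totals <- function(profiles) {
  stopifnot(inherits(profiles, "cazyme_profiles"))
  sp <- profiles$species
  out <- data.frame(species_id = sp$species_id, clade = sp$clade,
                    stringsAsFactors = FALSE)
  for (cls in CAZY_CLASSES) {
    sub <- profiles$counts[profiles$counts$class == cls, , drop = FALSE]
    tot <- tapply(sub$n, sub$species_id, sum)
    out[[cls]] <- as.integer(ifelse(is.na(tot[sp$species_id]), 0L,
                                    tot[sp$species_id]))
  }
  out$total <- as.integer(rowSums(out[, CAZY_CLASSES]))
  out$total_excl_gt <- out$total - out$GT
  rownames(out) <- NULL
  out
}

#' Read a family-to-substrate mapping table
#'
#' Long TSV with columns `family` and `category`; one row per assignment, a
#' family may map to several categories.
#'
#' @param path TSV path; default the mapping shipped with the package, which
#'   encodes the GH5 (cellulose, mannan, xylan, xyloglucan) and GH3
#'   (beta-glucan, cellulose, xylan, xyloglucan) assignments plus canonical
#'   assignments for the remaining categories. CBMs are deliberately absent
#'   (non-catalytic).
#' @return data frame `family`, `category`, validated against
#'   [SUBSTRATE_CATEGORIES].
#' @export
read_substrate_map <- function(path = system.file("extdata",
                                                  "substrate_map_default.tsv",
                                                  package = "yeastcaz")) {
  map <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("family", "category") %in% names(map)))
  bad <- setdiff(unique(map$category), SUBSTRATE_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown substrate categories in map: ", paste(bad, collapse = ", "))
  }
  unique(map[, c("family", "category")])
}

#' Per-species substrate-category counts
#'
#' For every species, the number of CAZyme genes whose family maps to each
#' polysaccharide category. A gene is counted once per category its family
#' maps to, so categories are not disjoint. Families absent from the map are
#' counted nowhere and reported in the `unmapped` attribute.
#'
#' @param profiles a `cazyme_profiles` object.
#' @param map substrate map data frame (see [read_substrate_map()]).
#' @return data frame with `species_id`, `clade` and one integer column per
#'   category in [SUBSTRATE_CATEGORIES]; attribute `unmapped` lists families
#'   not covered by the map.
#' @export
substrate_counts <- function(profiles, map = read_substrate_map()) {
  stopifnot(inherits(profiles, "cazyme_profiles"))
  sp <- profiles$species
  out <- data.frame(species_id = sp$species_id, clade = sp$clade,
                    stringsAsFactors = FALSE)
  counts <- profiles$counts
  mapped_any <- logical(nrow(counts))
  for (cat in SUBSTRATE_CATEGORIES) {
    fams <- map$family[map$category == cat]
    in_cat <- family_in_set(counts$family, fams)
    mapped_any <- mapped_any | in_cat
    sub <- counts[in_cat, , drop = FALSE]
    tot <- tapply(sub$n, sub$species_id, sum)
    out[[cat]] <- as.integer(ifelse(is.na(tot[sp$species_id]), 0L,
                                    tot[sp$species_id]))
  }
  rownames(out) <- NULL
  attr(out, "unmapped") <- sort(unique(counts$family[!mapped_any]))
  out
}

#' Rank species by GT-excluded CAZyme total
#'
#' @param profiles a `cazyme_profiles` object.
#' @return the [profile_totals()] data frame ordered by `total_excl_gt`
#'   descending, ties broken by `species_id` ascending; column `rank` added.
#' @export
rank_species <- function(profiles) {
  totals <- profile_totals(profiles)
  stopifnot(nrow(totals) >= 1L)
  totals <- totals[order(-totals$total_excl_gt, totals$species_id), , drop = FALSE]
  totals$rank <- seq_len(nrow(totals))
  rownames(totals) <- NULL
  totals
}

#' Select CAZyme-rich species
#'
#' Takes the `top_k` species by GT-excluded total, then optionally filters by
#' minimum substrate-category counts (e.g. `c(xylan = 1)` to require at least
#' one xylan-mapped CAZyme gene).
#'
#' @param profiles a `cazyme_profiles` object.
#' @param top_k number of top-ranked species to take (>= 1); values larger
#'   than the number of species select all.
#' @param required_categories optional named numeric vector of minimum
#'   category counts.
#' @param map substrate map used when `required_categories` is given.
#' @return subset of the ranking data frame; empty with a warning when the
#'   filter removes everything.
#' @export
select_rich_species <- function(profiles, top_k,
                                required_categories = NULL,
                                map = read_substrate_map()) {
  stopifnot(top_k >= 1L)
  ranked <- rank_species(profiles)
  sel <- ranked[seq_len(min(top_k, nrow(ranked))), , drop = FALSE]
  if (!is.null(required_categories)) {
    stopifnot(!is.null(names(required_categories)),
              all(names(required_categories) %in% SUBSTRATE_CATEGORIES))
    sc <- substrate_counts(profiles, map)
    keep <- rep(TRUE, nrow(sel))
    for (cat in names(required_categories)) {
      cat_n <- sc[[cat]][match(sel$species_id, sc$species_id)]
      keep <- keep & cat_n >= required_categories[[cat]]
    }
    sel <- sel[keep, , drop = FALSE]
    if (nrow(sel) == 0L) warning("no species satisfy the category minimums")
  }
  rownames(sel) <- NULL
  sel
}

#' Export a tree heat annotation of CAZyme totals
#'
#' Maps each tree leaf's GT-excluded CAZyme total onto a colour ramp (light
#' yellow for the minimum through dark red for the maximum, linear in the
#' total), producing a generic leaf-annotation table usable with common tree
#' annotation tools.
#'
#' @param leaf_ids character vector of tree leaf labels (species ids).
#' @param profiles a `cazyme_profiles` object.
#' @param palette two or more colours from lightest to darkest; default light
#'   yellow to dark red.
#' @param neutral_color colour given to leaves without a profile.
#' @return data frame `leaf`, `value` (total, NA when missing), `color`
#'   (hex); attribute `mismatches` lists leaves absent from the profiles.
#'   When all totals are equal every leaf gets the mid-palette colour, with a
#'   warning.
#' @export
export_tree_heat_annotation <- function(leaf_ids, profiles,
                                        palette = c("#FFFFB2", "#BD0026"),
                                        neutral_color = "#BEBEBE") {
  stopifnot(inherits(profiles, "cazyme_profiles"), length(palette) >= 2L)
  totals <- profile_totals(profiles)
  value <- totals$total_excl_gt[match(leaf_ids, totals$species_id)]
  mismatches <- leaf_ids[is.na(value)]
  if (length(mismatches) > 0L) {
    warning("leaf id(s) without a profile: ", paste(mismatches, collapse = ", "))
  }
  present <- !is.na(value)
  frac <- rep(NA_real_, length(value))
  if (any(present)) {
    rng <- range(value[present])
    if (rng[1] == rng[2]) {
      if (sum(present) > 1L) warning("all totals equal; using mid-palette colour")
      frac[present] <- 0.5
    } else {
      frac[present] <- (value[present] - rng[1]) / (rng[2] - rng[1])
    }
  }
  ramp <- colorRamp(palette)
  color <- rep(neutral_color, length(value))
  if (any(present)) {
    m <- ramp(frac[present])
    color[present] <- rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
  data.frame(leaf = leaf_ids, value = value, color = color,
             stringsAsFactors = FALSE) |>
    structure(mismatches = mismatches)
}
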