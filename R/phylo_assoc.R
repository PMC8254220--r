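#' Read a Newick tree
#'
#' Thin wrapper around ape's Newick parser with the validation this package
#' relies on: unique leaf labels; missing branch lengths are set to 0 with a
#' warning. Bootstrap labels on internal nodes are tolerated and ignored.
#' Unrooted trees are accepted (patristic distances are root-invariant).
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string instead of a file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    tree <- ape::read.tree(path)
  } else {
    tree <- ape::read.tree(text = text)
  }
  if (is.null(tree)) stop("failed to parse Newick input")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between leaves `a` and `b`.
#'
#' @param tree a `phylo` tree.
#' @param a,b leaf labels.
#' @return non-negative numeric distance.
#' @export
patristic_distance <- function(tree, a, b) {
  for (x in c(a, b)) {
    if (!(x %in% tree$tip.label)) stop("unknown leaf: ", x)
  }
  if (a == b) return(0)
  d <- ape::cophenetic.phylo(tree)
  d[a, b]
}

#' All pairwise patristic distances
#'
#' @param tree a `phylo` tree.
#' @return symmetric matrix of leaf-to-leaf path-length distances.
#' @export
patristic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Rank candidate taxa by patristic proximity to labeled taxa
#'
#' The phylogenetic-association screen: each candidate is scored by the
#' minimum (or mean) patristic distance to the set of taxa already known to
#' be xylanolytic, and candidates are ranked ascending — closest first. No
#' hard distance cutoff is applied; the full ranking is returned.
#'
#' @param tree a `phylo` tree.
#' @param labeled leaf labels of known xylanolytic taxa (non-empty).
#' @param candidates leaf labels to score; must be disjoint from `labeled`.
#' @param statistic `"min"` (default) or `"mean"` of distances to `labeled`.
#' @return data frame `taxon`, `statistic`, `rank`, sorted ascending by the
#'   statistic with ties broken by taxon name; ranks are 1..n.
#' @export
rank_candidates <- function(tree, labeled, candidates,
                            statistic = c("min", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(length(labeled) >= 1L)
  if (length(intersect(labeled, candidates)) > 0L) {
    stop("labeled and candidate sets must be disjoint")
  }
  missing <- setdiff(c(labeled, candidates), tree$tip.label)
  if (length(missing) > 0L) {
    stop("unknown leaf: ", paste(missing, collapse = ", "))
  }
  out <- data.frame(taxon = character(), statistic = numeric(),
                    rank = integer(), stringsAsFactors = FALSE)
  if (length(candidates) == 0L) return(out)
  d <- patristic_matrix(tree)[candidates, labeled, drop = FALSE]
  stat <- apply(d, 1, if (statistic == "min") min else mean)
  ord <- order(stat, candidates)
  data.frame(taxon = candidates[ord], statistic = unname(stat[ord]),
             rank = seq_along(candidates), stringsAsFactors = FALSE)
}

#' Global-alignment percent identity
#'
#' Needleman-Wunsch global alignment scored match +1, mismatch 0, linear gap
#' -1; identity is 100 x matches / alignment length, gap columns included in
#' the denominator. When several alignments reach the optimal score, the one
#' with the most matches and, among those, the fewest columns is reported,
#' so the result is well-defined.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @return percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACDEF", "ACEF")  # 80
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  n <- length(a); m <- length(b)
  # S: optimal score; M: max matches among optimal paths; C: min columns
  # among optimal paths with M matches. Lexicographic (S, M, -C) DP.
  S <- matrix(0L, n + 1L, m + 1L)
  M <- matrix(0L, n + 1L, m + 1L)
  C <- matrix(0L, n + 1L, m + 1L)
  S[1, ] <- -(0:m); C[1, ] <- 0:m
  S[, 1] <- -(0:n); C[, 1] <- 0:n
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      mt <- as.integer(a[i] == b[j])
      cand_s <- c(S[i, j] + mt, S[i, j + 1L] - 1L, S[i + 1L, j] - 1L)
      cand_m <- c(M[i, j] + mt, M[i, j + 1L], M[i + 1L, j])
      cand_c <- c(C[i, j], C[i, j + 1L], C[i + 1L, j]) + 1L
      best <- max(cand_s)
      k <- which(cand_s == best)
      mm <- max(cand_m[k])
      k <- k[cand_m[k] == mm]
      S[i + 1L, j + 1L] <- best
      M[i + 1L, j + 1L] <- mm
      C[i + 1L, j + 1L] <- min(cand_c[k])
    }
  }
  100 * M[n + 1L, m + 1L] / C[n + 1L, m + 1L]
}
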