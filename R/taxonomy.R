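#' Rooted taxonomy with fixed ranks
#'
#' A `taxonomy_tree` holds nodes at the six ranks
#' domain > phylum > class > order > family > genus, as used for
#' lowest-common-ancestor (LCA) assignment and rank roll-ups. It is a thin
#' wrapper around a node table with columns `taxon_id`, `name`, `rank`,
#' `parent_id` (`NA` for the single root).
#'
#' @param nodes data.frame with columns `taxon_id`, `name`, `rank`,
#'   `parent_id`.
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  required <- c("taxon_id", "name", "rank", "parent_id")
  assert_that(all(required %in% names(nodes)),
              "taxonomy nodes need columns %s", paste(required, collapse = ", "))
  obj <- structure(list(nodes = nodes), class = "taxonomy_tree")
  validate_taxonomy(obj)
  obj
}

validate_taxonomy <- function(tree) {
  nodes <- tree$nodes
  assert_that(!anyDuplicated(nodes$taxon_id), "duplicated taxon_ids")
  is_root <- is.na(nodes$parent_id)
  assert_that(sum(is_root) == 1L, "taxonomy must have exactly one root")
  assert_that(all(nodes$rank %in% TAX_RANKS), "unknown rank in taxonomy")
  nonroot <- nodes[!is_root, , drop = FALSE]
  missing <- setdiff(nonroot$parent_id, nodes$taxon_id)
  if (length(missing))
    stopf("taxonomy parent '%s' does not exist", missing[1])
  pr <- match(nodes$rank[match(nonroot$parent_id, nodes$taxon_id)], TAX_RANKS)
  cr <- match(nonroot$rank, TAX_RANKS)
  assert_that(all(cr > pr), "child rank must be strictly below parent rank")
  invisible(tree)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  tab <- table(factor(x$nodes$rank, levels = TAX_RANKS))
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

rank_depth <- function(rank) match(rank, TAX_RANKS)

tax_genera <- function(tree) {
  sort(tree$nodes$taxon_id[tree$nodes$rank == "genus"])
}

tax_name <- function(tree, taxon_id) {
  tree$nodes$name[match(taxon_id, tree$nodes$taxon_id)]
}

# Path from root to `taxon_id`, as a character vector of taxon_ids.
tax_path <- function(tree, taxon_id) {
  nodes <- tree$nodes
  idx <- match(taxon_id, nodes$taxon_id)
  if (is.na(idx)) stopf("taxon '%s' not found in taxonomy", taxon_id)
  path <- character(0)
  while (!is.na(idx)) {
    path <- c(nodes$taxon_id[idx], path)
    idx <- match(nodes$parent_id[idx], nodes$taxon_id)
  }
  path
}

# Ancestor of `taxon_id` at `rank` (or NA if the node is above that rank).
tax_ancestor_at <- function(tree, taxon_id, rank) {
  path <- tax_path(tree, taxon_id)
  d <- rank_depth(rank)
  if (length(path) < d) NA_character_ else path[d]
}

# LCA of a set of taxon ids: deepest node ancestral-or-self to all of them.
lca_of <- function(tree, taxon_ids) {
  taxon_ids <- unique(taxon_ids)
  paths <- lapply(taxon_ids, function(t) tax_path(tree, t))
  depth <- min(lengths(paths))
  lca <- NA_character_
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[`, character(1), d)
    if (length(unique(level)) == 1L) lca <- level[1] else break
  }
  lca
}

#' Generate a rooted taxonomy with a fixed number of genus leaves
#'
#' Builds a deterministic six-rank taxonomy (domain, phylum, class, order,
#' family, genus). The number of nodes per rank grows by the per-rank
#' branching factors, capped so that the tree carries exactly `n_genera`
#' genus leaves; children are distributed contiguously over parents, which
#' keeps related genera adjacent (so homolog families placed on neighbouring
#' genera share deep ancestors).
#'
#' @param n_genera number of genus leaves (>= 1).
#' @param branching integer vector of length 5: branching factor below
#'   domain, phylum, class, order, family respectively (each >= 1).
#' @param seed integer seed (accepted for interface uniformity; the
#'   construction is fully deterministic).
#' @return A [taxonomy_tree()].
#' @examples
#' tr <- generate_taxonomy(8, branching = c(2, 2, 2, 1, 1), seed = 1)
#' @export
generate_taxonomy <- function(n_genera, branching = c(2, 2, 2, 2, 2),
                              seed = 0L) {
  assert_count(n_genera, "n_genera", min = 1L)
  assert_that(length(branching) == 5L && all(branching >= 1),
              "`branching` must be 5 factors >= 1")
  assert_seed(seed)

  counts <- integer(6)
  counts[1] <- 1L
  for (r in 2:6) counts[r] <- min(counts[r - 1] * branching[r - 1], n_genera)
  counts[6] <- as.integer(n_genera)

  abbr <- c("d", "p", "c", "o", "f", "g")
  rows <- vector("list", 6)
  for (r in seq_len(6)) {
    ids <- sprintf("%s%02d", abbr[r], seq_len(counts[r]))
    parents <- if (r == 1) NA_character_ else {
      # balanced contiguous assignment of children to parents
      pidx <- ((seq_len(counts[r]) - 1L) * counts[r - 1]) %/% counts[r] + 1L
      sprintf("%s%02d", abbr[r - 1], pidx)
    }
    rows[[r]] <- data.frame(
      taxon_id = ids,
      name = paste0(toupper(substr(TAX_RANKS[r], 1, 1)),
                    substr(TAX_RANKS[r], 2, nchar(TAX_RANKS[r])),
                    "_", seq_len(counts[r])),
      rank = TAX_RANKS[r],
      parent_id = parents,
      stringsAsFactors = FALSE
    )
  }
  taxonomy_tree(do.call(rbind, rows))
}
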