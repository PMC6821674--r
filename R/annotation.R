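# Alignment-based consensus annotation: Smith-Waterman hits against the
# annotated reference store, LCA taxonomy, and modal-name consensus
# function.

# Gapped Karlin-Altschul constants for BLOSUM62 with gap open 11 / extend 1.
SW_LAMBDA <- 0.267
SW_K <- 0.041

bit_score <- function(raw) (SW_LAMBDA * raw - log(SW_K)) / log(2)

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Smith-Waterman local alignment of two protein sequences
#'
#' Standard local alignment with BLOSUM62, gap open 11, gap extend 1. The
#' bit score is `(lambda * S - ln K) / ln 2` with gapped constants
#' `lambda = 0.267`, `K = 0.041`.
#'
#' @param query,subject non-empty amino-acid strings.
#' @return List with `score` (raw) and `bitscore`.
#' @export
local_align <- function(query, subject) {
  assert_that(is.character(query) && length(query) == 1L && nchar(query) > 0L,
              "`query` must be a non-empty string")
  assert_that(is.character(subject) && length(subject) == 1L &&
                nchar(subject) > 0L, "`subject` must be a non-empty string")
  s <- align_scores(query, subject)
  list(score = s, bitscore = bit_score(s))
}

# Raw SW scores of one query against many subjects (vectorised in C).
align_scores <- function(query, subjects) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  as.numeric(pa)
}

#' Build the 5-mer prefilter index of a reference store
#'
#' @param refdb a [generate_reference_proteomes()] table.
#' @param k word size (default 5).
#' @return Object of class `kmer_prefilter`.
#' @export
build_kmer_prefilter <- function(refdb, k = 5L) {
  lists <- lapply(refdb$sequence, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(stringi::stri_sub(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  tab <- data.table::data.table(
    kmer = unlist(lists, use.names = FALSE),
    idx = rep(seq_along(lists), lengths(lists)))
  data.table::setkey(tab, kmer)
  structure(list(table = tab, k = as.integer(k)),
            class = "kmer_prefilter")
}

#' Best alignment hits of a query against the reference store
#'
#' Candidates are prefiltered by shared 5-mer count (at least
#' `prefilter_min_shared` shared words required -- a hit clearing an 80-bit
#' score shares dozens -- and the top `prefilter_n` kept), aligned by
#' Smith-Waterman, filtered to bit score > `min_bitscore`, sorted by raw
#' score descending (ties by subject id) and truncated to `max_hits`. With
#' `prefilter = FALSE` every reference sequence is aligned -- the
#' exhaustive oracle mode.
#'
#' @param query an amino-acid string (for a protein group: the anchor
#'   member's sequence).
#' @param refdb a [generate_reference_proteomes()] table.
#' @param max_hits maximum hits returned (default 20).
#' @param min_bitscore strict lower bound on the bit score (default 80).
#' @param prefilter use the shared-5-mer prefilter.
#' @param prefilter_n number of candidates retained by the prefilter.
#' @param prefilter_min_shared minimum shared 5-mer count for a candidate.
#' @param prefilter_index optional precomputed [build_kmer_prefilter()].
#' @return data.frame of class `alignment_hits` with columns `subject_id`,
#'   `score`, `bitscore`, `taxon_id`, `function_name`.
#' @export
top_hits <- function(query, refdb, max_hits = 20L, min_bitscore = 80,
                     prefilter = TRUE, prefilter_n = 200L,
                     prefilter_min_shared = 2L, prefilter_index = NULL) {
  assert_that(nrow(refdb) > 0L, "reference store is empty")
  empty <- data.frame(subject_id = character(0), score = numeric(0),
                      bitscore = numeric(0), taxon_id = character(0),
                      function_name = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("alignment_hits", "data.frame")
  if (nchar(query) == 0L) return(empty)

  if (prefilter) {
    if (is.null(prefilter_index)) prefilter_index <- build_kmer_prefilter(refdb)
    k <- prefilter_index$k
    n <- nchar(query)
    if (n < k) return(empty)
    qk <- unique(stringi::stri_sub(query, seq_len(n - k + 1L),
                                   seq_len(n - k + 1L) + k - 1L))
    tab <- prefilter_index$table[data.table::data.table(kmer = qk),
                                 on = "kmer", nomatch = NULL]
    if (nrow(tab) == 0L) return(empty)
    cnt <- tab[, .N, by = idx]
    cnt <- cnt[N >= prefilter_min_shared]
    if (nrow(cnt) == 0L) return(empty)
    cnt <- cnt[order(-N, refdb$protein_id[idx])]
    cand <- head(cnt$idx, prefilter_n)
  } else {
    cand <- seq_len(nrow(refdb))
  }
  scores <- align_scores(query, refdb$sequence[cand])
  bits <- bit_score(scores)
  keep <- bits > min_bitscore
  if (!any(keep)) return(empty)
  hits <- data.frame(subject_id = refdb$protein_id[cand][keep],
                     score = scores[keep], bitscore = bits[keep],
                     taxon_id = refdb$taxon_id[cand][keep],
                     function_name = refdb$function_name[cand][keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$score, hits$subject_id), , drop = FALSE]
  hits <- head(hits, max_hits)
  rownames(hits) <- NULL
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Lowest-common-ancestor taxonomic annotation of a hit list
#'
#' Returns the deepest taxonomy node that is ancestor-or-self of every
#' hit's genus; an empty hit list yields no annotation.
#'
#' @param hits an `alignment_hits` table (column `taxon_id`).
#' @param tree a [taxonomy_tree()].
#' @return List of class `taxonomic_annotation`: `taxon_id`, `rank`,
#'   `n_hits_used` (each NA/0 when no hits).
#' @export
lca_annotate <- function(hits, tree) {
  if (nrow(hits) == 0L)
    return(structure(list(taxon_id = NA_character_, rank = NA_character_,
                          n_hits_used = 0L),
                     class = "taxonomic_annotation"))
  taxa <- unique(hits$taxon_id)
  missing <- setdiff(taxa, tree$nodes$taxon_id)
  if (length(missing))
    stopf("hit taxon '%s' does not resolve in the taxonomy", missing[1])
  lca <- lca_of(tree, taxa)
  structure(list(taxon_id = lca,
                 rank = tree$nodes$rank[match(lca, tree$nodes$taxon_id)],
                 n_hits_used = nrow(hits)),
            class = "taxonomic_annotation")
}

#' Normalise protein function names for consensus building
#'
#' Lowercases, squeezes whitespace, and iteratively strips trailing
#' designators (subunit/chain/isoform plus argument, greek letters, short
#' numeric suffixes) so that isoforms and subunits of one protein collapse
#' onto the same function, e.g. both "ATP synthase subunit alpha" and
#' "ATP synthase subunit beta" become "atp synthase".
#'
#' @param x character vector of names.
#' @param designators regular expressions (applied repeatedly, anchored at
#'   the end of the name) defining what counts as a designator.
#' @return Character vector of normalised names.
#' @export
normalize_function_name <- function(x,
    designators = c("\\s+(subunit|chain|isoform)\\s+\\S+$",
                    "\\s+(alpha|beta|gamma|delta|epsilon)$",
                    "\\s+[a-z]?[0-9]+[a-z]?$",
                    "\\s+(subunit|chain|isoform)$")) {
  out <- tolower(trimws(gsub("\\s+", " ", x)))
  repeat {
    prev <- out
    for (p in designators) out <- sub(p, "", out)
    if (identical(out, prev)) break
  }
  out
}

#' Consensus functional annotation of a hit list
#'
#' Normalises the hit names and returns the modal normalised name when its
#' frequency among hits exceeds `tolerance`; otherwise the group is flagged
#' for manual validation. No hits: no name, no manual flag.
#'
#' @param hits an `alignment_hits` table (column `function_name`).
#' @param tolerance strict lower bound on the modal-name frequency.
#' @return List of class `functional_annotation`: `name`, `agreement`,
#'   `needs_manual`.
#' @export
consensus_function <- function(hits, tolerance = 0.8) {
  assert_fraction(tolerance, "tolerance", lo = 0, hi = 1,
                  lo_open = TRUE, hi_open = TRUE)
  if (nrow(hits) == 0L)
    return(structure(list(name = NA_character_, agreement = NA_real_,
                          needs_manual = FALSE),
                     class = "functional_annotation"))
  norm <- normalize_function_name(hits$function_name)
  tab <- sort(table(norm), decreasing = TRUE)
  modal <- names(tab)[order(-tab, names(tab))][1]
  agreement <- as.numeric(tab[modal]) / nrow(hits)
  if (agreement > tolerance)
    structure(list(name = modal, agreement = agreement,
                   needs_manual = FALSE), class = "functional_annotation")
  else
    structure(list(name = NA_character_, agreement = agreement,
                   needs_manual = TRUE), class = "functional_annotation")
}

#' Annotate every accepted protein group of a search result
#'
#' Aligns each accepted group's anchor sequence against the reference
#' store, assigns the LCA taxon and the consensus function, and computes
#' per-rank annotation fractions (a group is annotated at rank r iff its
#' LCA rank is r or deeper, so fractions are non-increasing from domain to
#' genus).
#'
#' @param result a `search_result`.
#' @param refdb a [generate_reference_proteomes()] table.
#' @param tree a [taxonomy_tree()].
#' @param max_hits,min_bitscore,tolerance annotation thresholds (defaults:
#'   20 hits, bit score > 80, agreement > 0.8).
#' @param prefilter,prefilter_n see [top_hits()].
#' @return Object of class `annotated_metaproteome`: the `search_result`
#'   plus `annotations` (one row per accepted group) and `rank_fractions`.
#' @export
annotate_all <- function(result, refdb, tree, max_hits = 20L,
                         min_bitscore = 80, tolerance = 0.8,
                         prefilter = TRUE, prefilter_n = 200L) {
  groups <- result$groups
  n <- nrow(groups)
  idx <- if (prefilter && n > 0L) build_kmer_prefilter(refdb) else NULL
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- top_hits(groups$anchor_sequence[i], refdb, max_hits,
                     min_bitscore, prefilter, prefilter_n,
                     prefilter_index = idx)
    ta <- lca_annotate(hits, tree)
    fa <- consensus_function(hits, tolerance)
    ann[[i]] <- data.frame(
      group_id = groups$group_id[i], anchor = groups$anchor[i],
      n_hits = nrow(hits), lca_taxon = ta$taxon_id, lca_rank = ta$rank,
      function_name = fa$name, agreement = fa$agreement,
      needs_manual = fa$needs_manual,
      n_distinct_peptides = groups$n_distinct_peptides[i],
      stringsAsFactors = FALSE)
  }
  annotations <- if (n > 0L) do.call(rbind, ann) else data.frame(
    group_id = character(0), anchor = character(0), n_hits = integer(0),
    lca_taxon = character(0), lca_rank = character(0),
    function_name = character(0), agreement = numeric(0),
    needs_manual = logical(0), n_distinct_peptides = integer(0),
    stringsAsFactors = FALSE)
  depth <- rank_depth(annotations$lca_rank)
  rank_fractions <- vapply(seq_along(TAX_RANKS), function(d) {
    if (n == 0L) 0 else mean(!is.na(depth) & depth >= d)
  }, numeric(1))
  names(rank_fractions) <- TAX_RANKS
  structure(list(result = result, annotations = annotations,
                 rank_fractions = rank_fractions,
                 label = result$label, db_name = result$db_name),
            class = "annotated_metaproteome")
}

#' @export
print.annotated_metaproteome <- function(x, ...) {
  cat(sprintf("<annotated_metaproteome> %s vs %s: %d groups, %.0f%% genus-annotated\n",
              x$label %||% "?", x$db_name, nrow(x$annotations),
              100 * x$rank_fractions[["genus"]]))
  invisible(x)
}
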