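# Shared fixtures. Worlds are built in code (no stored data) and cached per
# test session; every generator call is seeded, so fixtures are stable.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small six-rank tree with 4 genera: g01,g02 under one class branch,
# g03,g04 under the other
tiny_tree <- function() {
  cache_get("tiny_tree", function() generate_taxonomy(4, c(2, 2, 1, 1, 1), 1))
}

# mid-sized tree for LCA property tests
wide_tree <- function() {
  cache_get("wide_tree", function() generate_taxonomy(16, c(2, 2, 2, 2, 1), 1))
}

# a small annotated reference store: 6 genera x 40 proteins, families on
tiny_proteomes <- function() {
  cache_get("tiny_proteomes", function() {
    tr <- generate_taxonomy(6, c(2, 3, 1, 1, 1), 1)
    pr <- generate_reference_proteomes(tr, 40, n_families = 20,
                                       within_family_identity = 0.9,
                                       seed = 42)
    list(tree = tr, proteomes = pr)
  })
}

# the cached desk-scale world + round-1 databases + workflow (built once;
# reused by structural and acceptance tests)
desk_world <- function() {
  cache_get("desk_world", function() simulate_world(desk_config(seed = 7)))
}

desk_dbs <- function() {
  cache_get("desk_dbs", function() build_round1_dbs(desk_world()))
}

desk_workflow <- function() {
  cache_get("desk_workflow", function() {
    dbs <- desk_dbs()
    run_workflow(desk_world()$peptidomes, dbs[c("NAM", "AM", "TAX")])
  })
}

desk_annotated <- function() {
  cache_get("desk_annotated", function() {
    w <- desk_world()
    lapply(desk_workflow()$results, function(res)
      annotate_all(res, w$proteomes, w$tree))
  })
}

# minimal hand-built annotated metaproteome for analytics tests
fake_am <- function(lca_taxon, lca_rank, function_name, n_peptides,
                    needs_manual = rep(FALSE, length(lca_taxon)),
                    label = "gel_free", db_name = "TAX") {
  n <- length(lca_taxon)
  ann <- data.frame(
    group_id = sprintf("G%05d", seq_len(n)),
    anchor = sprintf("p%03d", seq_len(n)), n_hits = rep(1L, n),
    lca_taxon = lca_taxon, lca_rank = lca_rank,
    function_name = function_name,
    agreement = ifelse(needs_manual, 0.5, 1),
    needs_manual = needs_manual, n_distinct_peptides = n_peptides,
    stringsAsFactors = FALSE)
  depth <- match(ann$lca_rank, c("domain", "phylum", "class", "order",
                                 "family", "genus"))
  fr <- vapply(1:6, function(d) if (n == 0) 0 else
    mean(!is.na(depth) & depth >= d), numeric(1))
  names(fr) <- c("domain", "phylum", "class", "order", "family", "genus")
  structure(list(result = NULL, annotations = ann, rank_fractions = fr,
                 label = label, db_name = db_name),
            class = "annotated_metaproteome")
}

# hand-construct a protein_groups table (multi-peptide groups so that
# single-peptide validation stays out of the way)
make_groups <- function(scores, is_decoy, n_peptides = 2L) {
  n <- length(scores)
  out <- data.frame(
    group_id = sprintf("G%05d", seq_len(n)),
    anchor = sprintf("%sE%03d", ifelse(is_decoy, "DECOY_", ""), seq_len(n)),
    anchor_sequence = rep("MKAAAAAAAK", n),
    score = scores, n_distinct_peptides = rep(as.integer(n_peptides), n),
    n_spectra = as.integer(scores), is_decoy = is_decoy,
    stringsAsFactors = FALSE)
  out$members <- as.list(out$anchor)
  out$peptides <- lapply(seq_len(n), function(i)
    sprintf("PEPTIDEAAK%03d_%d", i, seq_len(n_peptides)))
  out$peptide_counts <- lapply(seq_len(n), function(i) {
    base <- rep(scores[i] %/% n_peptides, n_peptides)
    base[1] <- base[1] + scores[i] %% n_peptides
    as.integer(base)
  })
  out$peptide_shared <- lapply(seq_len(n), function(i) rep(FALSE, n_peptides))
  class(out) <- c("protein_groups", "data.frame")
  out
}

rank_order <- c("domain", "phylum", "class", "order", "family", "genus")
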