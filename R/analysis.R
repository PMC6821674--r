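# Comparative analytics across metaproteomes: distribution tables,
# annotation-rate profiles, Venn partitions, mean +/- SEM summaries,
# taxon x function matrices and complete-linkage heatmap clustering.

distribution_table <- function(labels, weights, other_threshold, axis,
                               weighting) {
  total <- sum(weights)
  if (total == 0 || length(labels) == 0L) {
    out <- data.frame(label = character(0), proportion = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    agg <- tapply(weights, labels, sum)
    prop <- 100 * as.numeric(agg) / total
    lab <- names(agg)
    pooled <- prop < other_threshold
    out <- data.frame(label = lab[!pooled], proportion = prop[!pooled],
                      stringsAsFactors = FALSE)
    if (any(pooled))
      out <- rbind(out, data.frame(label = "Other",
                                   proportion = sum(prop[pooled]),
                                   stringsAsFactors = FALSE))
    out <- out[order(-out$proportion, out$label), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, axis = axis, weighting = weighting,
            other_threshold = other_threshold,
            class = c("distribution_table", "data.frame"))
}

#' Taxonomic distribution of an annotated metaproteome at one rank
#'
#' Groups annotated at `rank` or deeper are rolled up to their ancestor at
#' that rank; weights are the per-group distinct peptide counts
#' (`weighting = "peptide_count"`, the quantitative value used throughout)
#' or 1 per group (`"protein_count"`). Proportions are percentages of the
#' total annotated-at-rank weight; labels below `other_threshold` percent
#' are pooled into `"Other"`.
#'
#' @param am an `annotated_metaproteome`.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @param weighting `"peptide_count"` or `"protein_count"`.
#' @param other_threshold pooling threshold in percent.
#' @param tree the [taxonomy_tree()] used for annotation.
#' @param use_names label rows by taxon name (default) or taxon id.
#' @return A `distribution_table` (columns `label`, `proportion`; sums to
#'   100 when non-empty).
#' @export
taxon_distribution <- function(am, rank, weighting = c("peptide_count",
                                                       "protein_count"),
                               other_threshold = 1.0, tree,
                               use_names = TRUE) {
  assert_that(rank %in% TAX_RANKS, "invalid rank '%s'", rank)
  weighting <- match.arg(weighting)
  ann <- am$annotations
  d <- rank_depth(ann$lca_rank)
  keep <- !is.na(d) & d >= rank_depth(rank)
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) == 0L)
    return(distribution_table(character(0), numeric(0), other_threshold,
                              paste0("taxon-at-", rank), weighting))
  anc <- vapply(ann$lca_taxon, function(t) tax_ancestor_at(tree, t, rank),
                character(1), USE.NAMES = FALSE)
  labels <- if (use_names) tax_name(tree, anc) else anc
  weights <- if (weighting == "peptide_count") ann$n_distinct_peptides
             else rep(1, nrow(ann))
  distribution_table(labels, weights, other_threshold,
                     paste0("taxon-at-", rank), weighting)
}

#' Functional distribution of an annotated metaproteome
#'
#' Same as [taxon_distribution()] but keyed by the normalised consensus
#' function name; groups without an accepted consensus (unnamed or flagged
#' for manual validation) are excluded from the denominator.
#'
#' @inheritParams taxon_distribution
#' @return A `distribution_table`.
#' @export
function_distribution <- function(am, weighting = c("peptide_count",
                                                    "protein_count"),
                                  other_threshold = 1.0) {
  weighting <- match.arg(weighting)
  ann <- am$annotations
  keep <- !is.na(ann$function_name) & !ann$needs_manual
  ann <- ann[keep, , drop = FALSE]
  weights <- if (weighting == "peptide_count") ann$n_distinct_peptides
             else rep(1, nrow(ann))
  distribution_table(ann$function_name, weights, other_threshold,
                     "function", weighting)
}

#' Per-rank annotation-rate profile across metaproteomes
#'
#' Fraction of accepted groups annotated at each rank (LCA at that rank or
#' deeper), per metaproteome. Non-increasing from domain to genus by
#' construction.
#'
#' @param ams named list of `annotated_metaproteome`s.
#' @return Matrix ranks x metaproteomes of fractions in \[0, 1\].
#' @export
annotation_rate_profile <- function(ams) {
  out <- vapply(ams, function(a) a$rank_fractions, numeric(length(TAX_RANKS)))
  rownames(out) <- TAX_RANKS
  out
}

#' Venn partition of four label sets
#'
#' Assigns every label of the union to exactly one of the 15 non-empty
#' subset regions of four sets.
#'
#' @param sets named list of exactly four character vectors (e.g. taxa per
#'   database).
#' @return Named integer vector of length 15; names are `&`-joined set
#'   names. Counts sum to the size of the union.
#' @export
venn_partition <- function(sets) {
  assert_that(is.list(sets) && length(sets) == 4L,
              "venn_partition needs exactly 4 sets")
  if (is.null(names(sets))) names(sets) <- paste0("S", 1:4)
  labels <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) labels %in% s, logical(length(labels)))
  if (length(labels) == 1L) member <- matrix(member, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  region_names <- character(15); counts <- integer(15)
  r <- 0L
  for (mask in 1:15) {
    r <- r + 1L
    in_set <- as.logical(bitwAnd(mask, 2^(0:3)))
    region_names[r] <- paste(names(sets)[in_set], collapse = "&")
    if (length(labels)) {
      counts[r] <- sum(apply(member, 1, function(m) all(m == in_set)))
    } else counts[r] <- 0L
  }
  setNames(counts, region_names)
}

#' Row-wise mean and standard error of a comparison matrix
#'
#' For each row (taxon or function) across the metaproteome columns:
#' arithmetic mean and SEM (sample standard deviation with n-1 divisor over
#' the square root of n). Display columns follow the field's convention:
#' mean rounded to 1 decimal; SEM to 2 decimals when below 1, else 1
#' decimal.
#'
#' @param mat numeric matrix or data.frame with at least 2 columns; row
#'   names identify the rows.
#' @return data.frame with columns `row`, `mean`, `sem`, `display_mean`,
#'   `display_sem`.
#' @export
summarize_mean_sem <- function(mat) {
  m <- as.matrix(mat)
  assert_that(ncol(m) >= 2L, "summarize_mean_sem needs >= 2 columns")
  mu <- rowMeans(m)
  sem <- apply(m, 1, function(x) stats::sd(x) / sqrt(length(x)))
  data.frame(row = rownames(m) %||% as.character(seq_len(nrow(m))),
             mean = mu, sem = sem,
             display_mean = round_half_up(mu, 1),
             display_sem = ifelse(sem < 1, round_half_up(sem, 2),
                                  round_half_up(sem, 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Half-away-from-zero rounding as used for printed tables (base round()
# applies banker's rounding, turning a printed 18.15 into 18.1). The tiny
# epsilon absorbs binary representation error of decimal-derived values.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Order-level taxon x function peptide-count matrix
#'
#' Rows are order-rank taxa, columns normalised functions; cells sum the
#' distinct-peptide counts of groups annotated at both levels. Groups
#' lacking either annotation are excluded.
#'
#' @param am an `annotated_metaproteome`.
#' @param tree the [taxonomy_tree()] used for annotation.
#' @param rank taxonomic rank for the rows (default `"order"`).
#' @return Numeric matrix (possibly 0 x 0).
#' @export
taxon_function_matrix <- function(am, tree, rank = "order") {
  ann <- am$annotations
  d <- rank_depth(ann$lca_rank)
  keep <- !is.na(d) & d >= rank_depth(rank) &
    !is.na(ann$function_name) & !ann$needs_manual
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) == 0L) return(matrix(numeric(0), 0, 0))
  taxa <- tax_name(tree, vapply(ann$lca_taxon, function(t)
    tax_ancestor_at(tree, t, rank), character(1), USE.NAMES = FALSE))
  funs <- ann$function_name
  tab <- tapply(ann$n_distinct_peptides, list(taxa, funs), sum,
                default = 0)
  mat <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
}

#' Complete-linkage clustering of a comparison matrix
#'
#' Rows and columns are clustered independently by complete-linkage
#' agglomeration on Euclidean distances ([stats::hclust()]); the matrix is
#' returned reordered by the dendrograms. Input order breaks ties, so runs
#' are reproducible.
#'
#' @param mat numeric matrix with at least 2 rows and 2 columns.
#' @return List with `row_hclust`, `col_hclust`, `matrix` (reordered).
#' @export
cluster_heatmap <- function(mat) {
  assert_that(is.matrix(mat) && nrow(mat) >= 2L && ncol(mat) >= 2L,
              "cluster_heatmap needs a matrix with >= 2 rows and columns")
  hr <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  hc <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                      method = "complete")
  list(row_hclust = hr, col_hclust = hc,
       matrix = mat[hr$order, hc$order, drop = FALSE])
}

#' Render a clustered taxon x function heatmap (optional)
#'
#' Convenience wrapper around `pheatmap` (suggested dependency) using the
#' same complete-linkage/Euclidean clustering as [cluster_heatmap()].
#' Values are raw peptide counts by default; `scale` passes through to
#' pheatmap since the conventional display scaling is not fixed.
#'
#' @param mat matrix from [taxon_function_matrix()].
#' @param file optional output path (png/pdf inferred from extension).
#' @param scale `"none"`, `"row"` or `"column"`.
#' @return The pheatmap object, invisibly.
#' @export
render_heatmap <- function(mat, file = NULL, scale = "none") {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stopf("render_heatmap needs the suggested package 'pheatmap'")
  ph <- pheatmap::pheatmap(
    mat, clustering_method = "complete",
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean", scale = scale,
    silent = TRUE, filename = if (is.null(file)) NA else file)
  invisible(ph)
}

#' Ground-truth recovery metrics for one annotated metaproteome
#'
#' Reports, against the simulator's hidden truth: the genus-level Spearman
#' correlation between the metaproteome's peptide-weighted genus
#' distribution and the true community abundances; the fraction of
#' expressed proteins (>= `min_peptides` distinct sampled peptides in the
#' peptidome truth) recovered as a member of any accepted group; and the
#' fraction of function-annotated groups whose consensus matches the true
#' function of one of their source proteins.
#'
#' @param am an `annotated_metaproteome`.
#' @param community the true `community_profile`.
#' @param peptidome the searched `observed_peptidome` (hidden truth).
#' @param db the searched `protein_db` (maps entries to source proteins).
#' @param refdb the reference store (true function names).
#' @param tree the [taxonomy_tree()].
#' @param min_peptides distinct-peptide threshold defining "expressed".
#' @return List with `genus_spearman`, `protein_recovery`,
#'   `function_recovery`, `n_expressed` (NA when undefined).
#' @export
ground_truth_report <- function(am, community, peptidome, db, refdb, tree,
                                min_peptides = 2L) {
  ann <- am$annotations

  # genus-level Spearman
  genus_spearman <- NA_real_
  d <- rank_depth(ann$lca_rank)
  keep <- !is.na(d) & d >= rank_depth("genus")
  if (any(keep)) {
    genus <- ann$lca_taxon[keep]
    w <- tapply(ann$n_distinct_peptides[keep], genus, sum)
    truth_ab <- as.numeric(community)
    names(truth_ab) <- names(community)
    obs <- setNames(rep(0, length(truth_ab)), names(truth_ab))
    shared <- intersect(names(w), names(obs))
    obs[shared] <- w[shared]
    if (length(obs) >= 2L)
      genus_spearman <- suppressWarnings(
        cor(obs, truth_ab, method = "spearman"))
  }

  # expressed-protein recovery
  truth <- peptidome$truth
  non_noise <- truth[!vapply(truth, function(t) identical(t, "noise"),
                             logical(1))]
  # count distinct peptides per protein
  pp <- data.table::data.table(
    protein = unlist(non_noise, use.names = FALSE),
    peptide = rep(names(non_noise), lengths(non_noise)))
  per_prot <- pp[, .(n = data.table::uniqueN(peptide)), by = protein]
  expressed <- per_prot$protein[per_prot$n >= min_peptides]
  protein_recovery <- NA_real_
  if (length(expressed)) {
    members <- unique(unlist(am$result$groups$members, use.names = FALSE))
    src <- db$entries$source_protein[match(members, db$entries$entry_id)]
    recovered_proteins <- unique(src[!is.na(src)])
    protein_recovery <- mean(expressed %in% recovered_proteins)
  }

  # function recovery
  function_recovery <- NA_real_
  groups <- am$result$groups
  fn_keep <- !is.na(ann$function_name) & !ann$needs_manual
  if (any(fn_keep)) {
    ok <- vapply(which(fn_keep), function(i) {
      g <- groups[groups$group_id == ann$group_id[i], , drop = FALSE]
      src <- db$entries$source_protein[match(g$members[[1]],
                                             db$entries$entry_id)]
      src <- unique(src[!is.na(src)])
      if (length(src) == 0L) return(NA)
      true_fun <- normalize_function_name(
        refdb$function_name[match(src, refdb$protein_id)])
      ann$function_name[i] %in% true_fun
    }, logical(1))
    if (any(!is.na(ok))) function_recovery <- mean(ok, na.rm = TRUE)
  }

  list(genus_spearman = genus_spearman,
       protein_recovery = protein_recovery,
       function_recovery = function_recovery,
       n_expressed = length(expressed))
}

#' The printed phylum/class comparison table used by the summary examples
#'
#' Loads the packaged eight-metaproteome proportion table (phylum and class
#' rows by gel-based/gel-free x TAX/NAM/AM/Comb columns) shipped as plain
#' text under `inst/extdata`.
#'
#' @param level `"phylum"`, `"class"` or `"all"`.
#' @return Numeric matrix with row names, 8 columns.
#' @export
read_published_distribution <- function(level = c("all", "phylum", "class")) {
  level <- match.arg(level)
  path <- system.file("extdata", "table2_phylum_class.tsv",
                      package = "mproteo", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (level != "all") tab <- tab[tab$level == level, , drop = FALSE]
  m <- as.matrix(tab[, !(names(tab) %in% c("level", "row")), drop = FALSE])
  rownames(m) <- tab$row
  m
}
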