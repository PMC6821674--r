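# Construction of the four protein search databases (NAM, AM, TAX, Comb)
# from one simulated metagenome.

DB_NAMES <- c("NAM", "AM", "TAX", "Comb")

#' Protein search database container
#'
#' Targets and (optionally) decoys for one database name and search round.
#' Entries carry free-text provenance and, where known, the true source
#' protein (used only by ground-truth reporting, never by the search).
#'
#' @param db_name one of NAM, AM, TAX, Comb.
#' @param round 1 or 2.
#' @param entries data.frame with columns `entry_id`, `sequence`, `origin`,
#'   and optionally `source_protein`.
#' @param decoys optional data.frame with columns `entry_id`, `sequence`,
#'   `origin`.
#' @return Object of class `protein_db`.
#' @export
protein_db <- function(db_name, round, entries, decoys = NULL) {
  assert_that(db_name %in% DB_NAMES, "db_name must be one of %s",
              paste(DB_NAMES, collapse = "/"))
  assert_that(round %in% c(1L, 2L), "round must be 1 or 2")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"source_protein" %in% names(entries))
    entries$source_protein <- NA_character_
  if (is.null(decoys))
    decoys <- data.frame(entry_id = character(0), sequence = character(0),
                         origin = character(0), stringsAsFactors = FALSE)
  ids <- c(entries$entry_id, decoys$entry_id)
  assert_that(!anyDuplicated(ids),
              "entry ids must be unique across targets and decoys")
  structure(list(db_name = db_name, round = as.integer(round),
                 entries = entries, decoys = decoys),
            class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db> %s round %d: %d targets, %d decoys\n",
              x$db_name, x$round, nrow(x$entries), nrow(x$decoys)))
  invisible(x)
}

db_size <- function(db) nrow(db$entries)

# Six-frame ORF extraction shared by the read and contig gene callers.
# Returns entries for one nucleotide sequence: maximal stop-free stretches
# of length >= min_orf_aa in all 6 frames (no start codon required, so
# edge-truncated gene fragments are kept).
orfs_for_sequence <- function(seq_id, nt, min_orf_aa, source_protein = NA) {
  out <- vector("list", 6)
  k <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else revcomp(nt)
    for (frame in 0:2) {
      aa <- translate_frame(substr(s, frame + 1L, nchar(s)))
      if (nchar(aa) == 0L) next
      runs <- gregexpr("[^*]+", aa, perl = TRUE)[[1]]
      if (runs[1] == -1L) next
      lens <- attr(runs, "match.length")
      for (ri in seq_along(runs)) {
        if (lens[ri] < min_orf_aa) next
        a0 <- runs[ri] - 1L
        k <- k + 1L
        out[[k]] <- data.frame(
          entry_id = sprintf("%s|%s%d|%d", seq_id, strand, frame, a0),
          sequence = substr(aa, runs[ri], runs[ri] + lens[ri] - 1L),
          origin = sprintf("orf source=%s strand=%s frame=%d aa=%d-%d",
                           seq_id, strand, frame, a0, a0 + lens[ri]),
          source_protein = source_protein,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) NULL else do.call(rbind, out[seq_len(k)])
}

#' Predict gene fragments directly from reads (NAM database, round 1)
#'
#' Translates every read in all six frames and keeps maximal stop-free
#' stretches of at least `min_orf_aa` residues as database entries. No
#' start codon is required: reads are genome fragments, so edge-truncated
#' genes must be retained. Non-ACGT characters translate as stops
#' (conservative).
#'
#' @param reads a `read_set`.
#' @param min_orf_aa minimum fragment length in residues (>= 5).
#' @return A round-1 `protein_db` named `NAM` (not yet deduplicated).
#' @export
predict_genes_from_reads <- function(reads, min_orf_aa = 30L) {
  assert_count(min_orf_aa, "min_orf_aa", min = 5L)
  pieces <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads)))
    pieces[[i]] <- orfs_for_sequence(reads$read_id[i], reads$sequence[i],
                                     min_orf_aa, reads$source_protein[i])
  entries <- do.call(rbind, pieces)
  if (is.null(entries))
    entries <- data.frame(entry_id = character(0), sequence = character(0),
                          origin = character(0),
                          source_protein = character(0),
                          stringsAsFactors = FALSE)
  protein_db("NAM", 1L, entries)
}

#' Predict gene fragments from contigs (AM database, round 1)
#'
#' Applies the same six-frame stop-free ORF rule as
#' [predict_genes_from_reads()] to assembled contigs.
#'
#' @param contigs a `contig_set` from [assemble_reads()].
#' @param min_orf_aa minimum fragment length in residues (>= 5).
#' @return A round-1 `protein_db` named `AM` (not yet deduplicated).
#' @export
predict_genes_from_contigs <- function(contigs, min_orf_aa = 30L) {
  assert_count(min_orf_aa, "min_orf_aa", min = 5L)
  pieces <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs)))
    pieces[[i]] <- orfs_for_sequence(contigs$contig_id[i],
                                     contigs$sequence[i], min_orf_aa,
                                     contigs$source_protein[i])
  entries <- do.call(rbind, pieces)
  if (is.null(entries))
    entries <- data.frame(entry_id = character(0), sequence = character(0),
                          origin = character(0),
                          source_protein = character(0),
                          stringsAsFactors = FALSE)
  db <- protein_db("AM", 1L, entries)
  db
}

# All maximal exact suffix(a)-prefix(b) overlaps of length >= min_overlap
# among the current contigs, both orientations. A k-mer prescreen (k =
# min_overlap) proposes anchor positions: an overlap of length L implies
# that b's first k bases occur in a at position na - L + 1; every proposed
# L is then verified by a full string comparison.
all_overlaps <- function(ids, seqs, min_overlap) {
  k <- min_overlap
  n <- length(ids)
  if (n < 2L) return(NULL)
  ors <- c("F", "R")
  oseq <- list(F = seqs, R = revcomp(seqs))
  km <- list(); m <- 0L
  for (o in ors) {
    for (i in seq_len(n)) {
      s <- oseq[[o]][i]
      ns <- nchar(s)
      if (ns < k) next
      starts <- seq_len(ns - k + 1L)
      m <- m + 1L
      km[[m]] <- data.table::data.table(
        kmer = stringi::stri_sub(s, starts, starts + k - 1L),
        idx = i, orient = o, pos = starts)
    }
  }
  if (m == 0L) return(NULL)
  kmers <- data.table::rbindlist(km)
  pref <- data.table::data.table(
    kmer = c(stringi::stri_sub(oseq$F, 1L, k), stringi::stri_sub(oseq$R, 1L, k)),
    jdx = rep(seq_len(n), 2L),
    orient_b = rep(ors, each = n))
  pref <- pref[nchar(kmer) == k]
  cand <- kmers[pref, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  cand <- cand[idx != jdx]
  if (nrow(cand) == 0L) return(NULL)
  cand[, `:=`(na = nchar(seqs)[idx], nb = nchar(seqs)[jdx])]
  cand[, L := na - pos + 1L]
  cand <- cand[L >= k & L <= nb]
  if (nrow(cand) == 0L) return(NULL)
  ok <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- oseq[[cand$orient[r]]][cand$idx[r]]
    b <- oseq[[cand$orient_b[r]]][cand$jdx[r]]
    L <- cand$L[r]
    ok[r] <- substr(a, nchar(a) - L + 1L, nchar(a)) == substr(b, 1L, L)
  }
  cand <- cand[ok]
  if (nrow(cand) == 0L) return(NULL)
  res <- cand[, .(ov = max(L)),
              by = .(idx, jdx, orient_a = orient, orient_b)]
  data.frame(id_a = ids[res$idx], id_b = ids[res$jdx],
             orient_a = res$orient_a, orient_b = res$orient_b,
             ov = res$ov, stringsAsFactors = FALSE)
}

#' Greedy overlap-layout assembly of reads into contigs
#'
#' Iteratively merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least `min_overlap` bases (both strands are
#' considered; ties are broken by overlap length, then lexicographically by
#' the id pair, then by orientation). Reads that never merge remain
#' singleton contigs; with `drop_singletons = TRUE` (the default, mirroring
#' real assemblers' minimum-contig behaviour) they are discarded, which is
#' what makes assembled databases lose unassembled gene fragments.
#'
#' @param reads a `read_set`.
#' @param min_overlap minimum exact overlap in bases (>= 10).
#' @param drop_singletons drop contigs supported by a single read.
#' @return data.frame of class `contig_set` with columns `contig_id`,
#'   `sequence`, `support`, `source_protein` (NA when reads from several
#'   proteins merged).
#' @export
assemble_reads <- function(reads, min_overlap = 30L, drop_singletons = TRUE) {
  assert_count(min_overlap, "min_overlap", min = 10L)
  ids <- reads$read_id
  seqs <- reads$sequence
  src <- if ("source_protein" %in% names(reads)) reads$source_protein
         else rep(NA_character_, length(ids))
  support <- rep(1L, length(ids))

  repeat {
    cands <- all_overlaps(ids, seqs, min_overlap)
    if (is.null(cands) || nrow(cands) == 0L) break
    ord <- order(-cands$ov, cands$id_a, cands$id_b,
                 cands$orient_a, cands$orient_b)
    best <- cands[ord[1], ]
    ia <- match(best$id_a, ids); ib <- match(best$id_b, ids)
    a <- if (best$orient_a == "F") seqs[ia] else revcomp(seqs[ia])
    b <- if (best$orient_b == "F") seqs[ib] else revcomp(seqs[ib])
    merged <- paste0(a, substr(b, best$ov + 1L, nchar(b)))
    new_id <- min(best$id_a, best$id_b)
    new_src <- if (identical(src[ia], src[ib])) src[ia] else NA_character_
    new_support <- support[ia] + support[ib]
    keep <- setdiff(seq_along(ids), c(ia, ib))
    ids <- c(ids[keep], new_id)
    seqs <- c(seqs[keep], merged)
    src <- c(src[keep], new_src)
    support <- c(support[keep], new_support)
  }

  out <- data.frame(contig_id = paste0("ctg_", ids), sequence = seqs,
                    support = support, source_protein = src,
                    stringsAsFactors = FALSE)
  if (drop_singletons) out <- out[out$support > 1L, , drop = FALSE]
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_set", "data.frame")
  out
}

#' Build a genus marker k-mer index from the reference store
#'
#' For every genus, the coding sequences of its first `n_marker_proteins`
#' proteins (by id; the designated single-copy markers) are chopped into
#' `k`-mers, optionally restricted to the region covering the first
#' `n_peptides` tryptic peptides. This is the package's stand-in for a
#' single-copy marker-gene profiler used to detect which genera are present
#' in a read set. The default uses the whole marker coding sequence: with
#' hundreds (not millions) of reads, the marker region must be as large as
#' the designated genes allow or nothing is ever sampled.
#'
#' @param proteomes a [generate_reference_proteomes()] table.
#' @param n_marker_proteins,n_peptides,k index parameters (`n_peptides =
#'   Inf` uses the full marker protein).
#' @return Object of class `marker_index`.
#' @export
build_marker_index <- function(proteomes, n_marker_proteins = 5L,
                               n_peptides = Inf, k = 21L) {
  genera <- sort(unique(proteomes$taxon_id))
  kmer <- character(0); genus <- character(0)
  for (g in genera) {
    rows <- which(proteomes$taxon_id == g)
    rows <- rows[order(proteomes$protein_id[rows])]
    rows <- head(rows, n_marker_proteins)
    for (r in rows) {
      s <- proteomes$sequence[r]
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      cuts <- c(cut_sites(chars), length(chars))
      end_aa <- if (is.finite(n_peptides))
        cuts[min(n_peptides, length(cuts))] else length(chars)
      cds <- reverse_translate(substr(s, 1L, end_aa), add_stop = FALSE)
      n <- nchar(cds)
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      km <- stringi::stri_sub(cds, starts, starts + k - 1L)
      kmer <- c(kmer, km)
      genus <- c(genus, rep(g, length(km)))
    }
  }
  dt <- data.table::data.table(kmer = kmer, genus = genus)
  dt <- unique(dt)
  structure(list(table = dt, k = as.integer(k)), class = "marker_index")
}

#' Detect present genera from reads by marker k-mer counting
#'
#' A genus is reported iff at least `min_hits` reads contain one of its
#' marker k-mers on either strand.
#'
#' @param reads a `read_set`.
#' @param marker_index a [build_marker_index()].
#' @param min_hits minimum supporting reads per genus (>= 1).
#' @return Sorted character vector of detected genus taxon ids.
#' @export
detect_taxa <- function(reads, marker_index, min_hits = 2L) {
  assert_that(inherits(marker_index, "marker_index") &&
                nrow(marker_index$table) > 0L, "empty marker index")
  assert_count(min_hits, "min_hits", min = 1L)
  if (nrow(reads) == 0L) return(character(0))
  k <- marker_index$k
  km_tab <- marker_index$table
  read_id <- integer(0); kms <- character(0)
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    fw <- stringi::stri_sub(s, starts, starts + k - 1L)
    rc <- stringi::stri_sub(revcomp(s), starts, starts + k - 1L)
    both <- unique(c(fw, rc))
    kms <- c(kms, both)
    read_id <- c(read_id, rep(i, length(both)))
  }
  obs <- data.table::data.table(kmer = kms, read = read_id)
  hits <- km_tab[obs, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(character(0))
  per_genus <- hits[, .(n_reads = data.table::uniqueN(read)), by = genus]
  sort(per_genus$genus[per_genus$n_reads >= min_hits])
}

#' Build the taxonomy-derived database (TAX, round 1)
#'
#' Pulls the complete reference proteome of every detected genus -- the
#' whole "downloaded" proteome, not just expressed proteins -- and
#' deduplicates. This is why the taxonomy-derived database is far larger
#' than read-derived ones.
#'
#' @param detected character vector of genus taxon ids.
#' @param proteome_store a [generate_reference_proteomes()] table.
#' @return A round-1 `protein_db` named `TAX`.
#' @export
build_taxonomy_db <- function(detected, proteome_store) {
  unknown <- setdiff(detected, unique(proteome_store$taxon_id))
  if (length(unknown))
    stopf("unknown genus id in detected set: '%s'", unknown[1])
  rows <- proteome_store[proteome_store$taxon_id %in% detected, , drop = FALSE]
  entries <- data.frame(entry_id = rows$protein_id,
                        sequence = rows$sequence,
                        origin = sprintf("refstore taxon=%s", rows$taxon_id),
                        source_protein = rows$protein_id,
                        stringsAsFactors = FALSE)
  deduplicate(protein_db("TAX", 1L, entries))
}

#' Remove exact duplicate target sequences
#'
#' Collapses identical target sequences to a single entry, keeping the
#' lexicographically smallest entry id. Idempotent; decoys are dropped
#' (rebuild them from the deduplicated targets).
#'
#' @param db a `protein_db`.
#' @return A `protein_db` with unique target sequences and no decoys.
#' @export
deduplicate <- function(db) {
  e <- db$entries
  if (nrow(e) > 1L) {
    e <- e[order(e$sequence, e$entry_id), , drop = FALSE]
    e <- e[!duplicated(e$sequence), , drop = FALSE]
    e <- e[order(e$entry_id), , drop = FALSE]
    rownames(e) <- NULL
  }
  protein_db(db$db_name, db$round, e)
}

#' Merge databases and deduplicate (Comb construction)
#'
#' Unions the target entries of the input databases, removes redundant
#' sequences, and rebuilds decoys fresh from the merged targets (decoys are
#' never carried over, so the FDR always reflects the searched space).
#'
#' @param dbs non-empty list of `protein_db` objects.
#' @param name database name for the result (default `"Comb"`).
#' @param round round tag for the result.
#' @param build_decoys_too build fresh decoys for the merged targets.
#' @return A `protein_db`.
#' @export
merge_dbs <- function(dbs, name = "Comb", round = 2L,
                      build_decoys_too = TRUE) {
  assert_that(is.list(dbs) && length(dbs) >= 1L,
              "`dbs` must be a non-empty list of protein_db objects")
  entries <- do.call(rbind, lapply(dbs, function(d)
    d$entries[, c("entry_id", "sequence", "origin", "source_protein")]))
  entries <- entries[!duplicated(entries$entry_id), , drop = FALSE]
  db <- deduplicate(protein_db(name, round, entries))
  if (build_decoys_too) db <- build_decoys(db)
  db
}
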