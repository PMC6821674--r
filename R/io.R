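# Plain-text interchange: FASTA (via Biostrings), FASTQ, taxonomy /
# peptidome / result TSVs. Everything round-trips losslessly on canonical
# form.

#' Write / read protein database FASTA
#'
#' Headers follow the convention `{db}|{round}|{entry_id} origin={...}`
#' (plus `source={...}` when the true source protein is known); decoy
#' entries carry ids prefixed `DECOY_`.
#'
#' @param db a `protein_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_db_fasta <- function(db, path) {
  hdr <- function(e, decoy) {
    src <- if ("source_protein" %in% names(e)) e$source_protein
           else rep(NA_character_, nrow(e))
    sprintf("%s|%d|%s origin=%s%s", db$db_name, db$round, e$entry_id,
            gsub("\\s+", "_", e$origin),
            ifelse(!decoy & !is.na(src), paste0(" source=", src), ""))
  }
  seqs <- c(db$entries$sequence, db$decoys$sequence)
  nm <- c(hdr(db$entries, FALSE),
          if (nrow(db$decoys)) hdr(db$decoys, TRUE) else character(0))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_db_fasta
#' @export
read_db_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  full <- names(x)
  first <- sub("\\s.*$", "", full)
  parts <- strsplit(first, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stopf("malformed database FASTA header at record %d: '%s'",
          bad[1], full[bad[1]])
  db_name <- parts[[1]][1]
  round <- as.integer(parts[[1]][2])
  entry_id <- vapply(parts, `[`, character(1), 3L)
  origin <- sub("^.*\\sorigin=(\\S+).*$", "\\1", full)
  src <- ifelse(grepl(" source=", full, fixed = TRUE),
                sub("^.*\\ssource=(\\S+).*$", "\\1", full), NA_character_)
  is_decoy <- startsWith(entry_id, "DECOY_")
  entries <- data.frame(entry_id = entry_id[!is_decoy],
                        sequence = as.character(x)[!is_decoy],
                        origin = origin[!is_decoy],
                        source_protein = src[!is_decoy],
                        stringsAsFactors = FALSE)
  decoys <- data.frame(entry_id = entry_id[is_decoy],
                       sequence = as.character(x)[is_decoy],
                       origin = origin[is_decoy], stringsAsFactors = FALSE)
  protein_db(db_name, round, entries, decoys)
}

#' Write / read a reference proteome store as annotated FASTA
#'
#' Headers carry `taxon=`, `function=` and `family=` tags, so any user
#' FASTA with those tags can serve as an annotated reference store.
#'
#' @param proteomes a [generate_reference_proteomes()] table.
#' @param path file path.
#' @return `path` invisibly / the table.
#' @export
write_reference_fasta <- function(proteomes, path) {
  x <- Biostrings::AAStringSet(proteomes$sequence)
  names(x) <- sprintf("%s taxon=%s family=%s function=%s",
                      proteomes$protein_id, proteomes$taxon_id,
                      proteomes$family_id,
                      gsub("\\s+", "_", proteomes$function_name))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  full <- names(x)
  need <- c("taxon=", "family=", "function=")
  bad <- which(!vapply(full, function(h) all(vapply(need, grepl, logical(1),
                                                    x = h, fixed = TRUE)),
                       logical(1)))
  if (length(bad))
    stopf("reference FASTA record %d lacks taxon=/family=/function= tags",
          bad[1])
  out <- data.frame(
    protein_id = sub("\\s.*$", "", full),
    sequence = as.character(x),
    taxon_id = sub("^.*taxon=(\\S+).*$", "\\1", full),
    function_name = gsub("_", " ", sub("^.*function=(\\S+).*$", "\\1", full)),
    family_id = sub("^.*family=(\\S+).*$", "\\1", full),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reference_proteomes", "data.frame")
  out
}

#' Write / read reads as FASTQ (Sanger / Phred+33)
#'
#' The header comment records the hidden source
#' (`src= strand= start= end=`) so simulated read sets round-trip. The
#' reader validates record structure and reports the offending line.
#'
#' @param reads a `read_set`.
#' @param path file path.
#' @return `path` invisibly / a `read_set`.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  if (nrow(reads)) {
    lines[seq(1, length(lines), 4)] <- sprintf(
      "@%s src=%s strand=%s start=%d end=%d", reads$read_id,
      reads$source_protein, reads$strand, reads$start, reads$end)
    lines[seq(2, length(lines), 4)] <- reads$sequence
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- reads$quality
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stopf("truncated FASTQ: %d lines is not a multiple of 4", length(lines))
  n <- length(lines) %/% 4L
  hd <- lines[seq(1, length(lines), 4)]
  sq <- lines[seq(2, length(lines), 4)]
  pl <- lines[seq(3, length(lines), 4)]
  qu <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stopf("malformed FASTQ record %d (line %d)", bad[1], (bad[1] - 1L) * 4L + 1L)
  mism <- which(nchar(sq) != nchar(qu))
  if (length(mism))
    stopf("FASTQ record '%s' (line %d): sequence and quality lengths differ",
          sub("^@", "", sub("\\s.*$", "", hd[mism[1]])),
          (mism[1] - 1L) * 4L + 2L)
  notacgt <- which(grepl("[^ACGTN]", sq))
  if (length(notacgt))
    stopf("FASTQ record %d contains non-ACGTN characters", notacgt[1])
  get_tag <- function(tag, def = NA_character_) {
    hit <- grepl(paste0(tag, "="), hd, fixed = TRUE)
    out <- rep(def, n)
    out[hit] <- sub(paste0("^.*", tag, "=(\\S+).*$"), "\\1", hd[hit])
    out
  }
  out <- data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", hd)),
    sequence = sq, quality = qu,
    source_protein = get_tag("src"),
    strand = get_tag("strand"),
    start = suppressWarnings(as.integer(get_tag("start"))),
    end = suppressWarnings(as.integer(get_tag("end"))),
    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write / read a taxonomy as two TSV files
#'
#' The structure file has columns `taxon_id`, `parent_id`, `rank` (root
#' parent written as `-`); the names file has `taxon_id`, `name`.
#'
#' @param tree a [taxonomy_tree()].
#' @param path structure TSV path.
#' @param names_path names TSV path (default: `path` with `.names.tsv`).
#' @return `path` invisibly / a `taxonomy_tree`.
#' @export
write_taxonomy_tsv <- function(tree, path,
                               names_path = sub("\\.tsv$", ".names.tsv", path)) {
  n <- tree$nodes
  struct <- data.frame(taxon_id = n$taxon_id,
                       parent_id = ifelse(is.na(n$parent_id), "-", n$parent_id),
                       rank = n$rank, stringsAsFactors = FALSE)
  write.table(struct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(n[, c("taxon_id", "name")], names_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy_tsv <- function(path,
                              names_path = sub("\\.tsv$", ".names.tsv", path)) {
  struct <- read.delim(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("taxon_id", "parent_id", "rank")
  if (!all(need %in% names(struct)))
    stopf("taxonomy TSV must have columns %s", paste(need, collapse = ", "))
  struct$parent_id[struct$parent_id == "-"] <- NA_character_
  orphan <- setdiff(struct$parent_id[!is.na(struct$parent_id)],
                    struct$taxon_id)
  if (length(orphan))
    stopf("taxonomy TSV references unknown parent taxon '%s'", orphan[1])
  nm <- if (file.exists(names_path)) {
    read.delim(names_path, stringsAsFactors = FALSE,
               colClasses = "character")
  } else data.frame(taxon_id = struct$taxon_id, name = struct$taxon_id,
                    stringsAsFactors = FALSE)
  struct$name <- nm$name[match(struct$taxon_id, nm$taxon_id)]
  taxonomy_tree(struct[, c("taxon_id", "name", "rank", "parent_id")])
}

#' Write / read an observed peptidome as TSV
#'
#' Observations as (peptide, count); ground truth, when kept, as a third
#' column of `;`-joined source protein ids (or `noise`).
#'
#' @param peptidome an `observed_peptidome`.
#' @param path file path.
#' @param with_truth include the hidden truth column.
#' @return `path` invisibly / an `observed_peptidome`.
#' @export
write_peptidome_tsv <- function(peptidome, path, with_truth = TRUE) {
  obs <- peptidome$observations
  df <- data.frame(peptide = obs$peptide, count = obs$count,
                   stringsAsFactors = FALSE)
  if (with_truth && length(peptidome$truth))
    df$truth <- vapply(peptidome$truth[obs$peptide], paste, character(1),
                       collapse = ";")
  attr(df, "label") <- peptidome$label
  writeLines(sprintf("# label=%s n_spectra=%d", peptidome$label,
                     peptidome$n_spectra), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_peptidome_tsv
#' @export
read_peptidome_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  label <- "gel_free"; n_spectra <- NA_integer_
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    label <- sub("^.*label=(\\S+).*$", "\\1", first)
    n_spectra <- as.integer(sub("^.*n_spectra=(\\S+).*$", "\\1", first))
  }
  df <- read.delim(path, skip = skip, stringsAsFactors = FALSE)
  if (!all(c("peptide", "count") %in% names(df)))
    stopf("peptidome TSV needs columns peptide, count")
  bad <- which(grepl("[^ACDEFGHIKLMNPQRSTVWY]", df$peptide))
  if (length(bad))
    stopf("peptidome TSV line %d: invalid peptide '%s'",
          bad[1] + skip + 1L, df$peptide[bad[1]])
  if (any(df$count < 1L))
    stopf("peptidome TSV: counts must be >= 1")
  truth <- if ("truth" %in% names(df)) {
    tr <- strsplit(df$truth, ";", fixed = TRUE)
    names(tr) <- df$peptide
    tr
  } else list()
  if (is.na(n_spectra)) n_spectra <- sum(df$count)
  structure(list(label = label,
                 observations = data.frame(peptide = df$peptide,
                                           count = as.integer(df$count),
                                           stringsAsFactors = FALSE),
                 truth = truth, n_spectra = n_spectra),
            class = "observed_peptidome")
}

#' Write the groups of a search result as TSV
#'
#' One row per accepted protein group: members and peptides are
#' `;`-joined.
#'
#' @param result a `search_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(result, path) {
  g <- result$groups
  df <- data.frame(
    group_id = g$group_id, anchor = g$anchor,
    anchor_sequence = g$anchor_sequence,
    members = vapply(g$members, paste, character(1), collapse = ";"),
    peptides = vapply(g$peptides, paste, character(1), collapse = ";"),
    n_distinct_peptides = g$n_distinct_peptides,
    n_spectra = g$n_spectra, score = g$score,
    decoy_flag = g$is_decoy, accepted_flag = rep(TRUE, nrow(g)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a search-result groups TSV back into a minimal `search_result`
#'
#' Reconstructs enough of the result (group ids, anchors with sequences,
#' members, peptide counts) for downstream annotation; peptide-level count
#' detail is not preserved by the TSV.
#'
#' @param path file written by [write_result_tsv()].
#' @param label,db_name metadata for the reconstructed result.
#' @return A `search_result` (bookkeeping scalars recomputed where
#'   possible, otherwise NA).
#' @export
read_result_tsv <- function(path, label = NA_character_,
                            db_name = NA_character_) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "anchor", "anchor_sequence", "members", "peptides",
            "n_distinct_peptides", "n_spectra", "score")
  if (!all(need %in% names(df)))
    stopf("result TSV must have columns %s", paste(need, collapse = ", "))
  g <- data.frame(group_id = df$group_id, anchor = df$anchor,
                  anchor_sequence = df$anchor_sequence,
                  score = df$score,
                  n_distinct_peptides = df$n_distinct_peptides,
                  n_spectra = df$n_spectra,
                  is_decoy = df$decoy_flag %||% FALSE,
                  stringsAsFactors = FALSE)
  g$members <- strsplit(df$members, ";", fixed = TRUE)
  g$peptides <- strsplit(df$peptides, ";", fixed = TRUE)
  g$peptide_counts <- lapply(seq_len(nrow(df)), function(i)
    rep(NA_integer_, length(g$peptides[[i]])))
  g$peptide_shared <- lapply(seq_len(nrow(df)), function(i)
    rep(NA, length(g$peptides[[i]])))
  class(g) <- c("protein_groups", "data.frame")
  structure(list(label = label, db_name = db_name, round = NA_integer_,
                 groups = g,
                 n_spectra_identified = sum(df$n_spectra),
                 coverage_percent = NA_real_,
                 n_distinct_peptides = length(unique(unlist(g$peptides))),
                 n_proteins_validated = nrow(g),
                 fdr_threshold_score = NA_real_,
                 total_spectra = NA_integer_, fdr = NA_real_),
            class = "search_result")
}

#' Write the annotations of an annotated metaproteome as TSV
#'
#' @param am an `annotated_metaproteome`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(am, path) {
  write.table(am$annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
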