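# Metagenomic read simulation and quality trimming.

#' Simulate metagenomic short reads from coding sequences
#'
#' Each read is drawn from the reverse-translated coding sequence (fixed
#' one-codon-per-residue table plus TAA stop) of a reference protein. The
#' source genus is drawn proportionally to community abundance and the
#' protein uniformly within the genus (reads are DNA, so every gene of a
#' present genome is eligible regardless of expression). The strand is
#' uniform; substitutions are applied at `error_rate` per base. Hidden
#' ground truth (source protein, strand, 0-based half-open coordinates on
#' the forward coding strand) is recorded per read.
#'
#' Base qualities are constant `base_quality` except that a fraction
#' `low_quality_tail_fraction` of reads get a low-quality 3' tail of
#' `tail_length` bases at `tail_quality`, so that [trim_reads()] has
#' something to do.
#'
#' @param community a [simulate_community()] profile.
#' @param proteomes a [generate_reference_proteomes()] table.
#' @param read_length read length in bases (>= 30).
#' @param n_reads number of reads (>= 0).
#' @param error_rate substitution probability per base, in \[0, 0.2).
#' @param seed integer seed.
#' @param low_quality_tail_fraction fraction of reads with a bad 3' tail.
#' @param tail_length,base_quality,tail_quality quality model knobs.
#' @return data.frame of class `read_set` with columns `read_id`,
#'   `sequence`, `quality` (Phred+33 string), `source_protein`, `strand`,
#'   `start`, `end`.
#' @export
simulate_reads <- function(community, proteomes, read_length = 150L,
                           n_reads = 1000L, error_rate = 0.01, seed = 0L,
                           low_quality_tail_fraction = 0.1,
                           tail_length = 15L, base_quality = 38L,
                           tail_quality = 2L) {
  assert_that(length(community) >= 1L, "empty community")
  assert_count(read_length, "read_length", min = 30L)
  assert_count(n_reads, "n_reads", min = 0L)
  assert_fraction(error_rate, "error_rate", lo = 0, hi = 0.2, hi_open = TRUE)

  empty <- data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), source_protein = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("read_set", "data.frame")
  if (n_reads == 0L) return(empty)

  present <- names(community)
  by_genus <- split(seq_len(nrow(proteomes)), proteomes$taxon_id)
  assert_that(all(present %in% names(by_genus)),
              "community genus missing from proteome store")

  with_seed(seed, {
    genus_draw <- sample(present, n_reads, replace = TRUE,
                         prob = as.numeric(community))
    prot_idx <- vapply(genus_draw, function(g) {
      idx <- by_genus[[g]]
      idx[sample.int(length(idx), 1L)]
    }, integer(1), USE.NAMES = FALSE)

    need <- sort(unique(prot_idx))
    cds <- setNames(reverse_translate(proteomes$sequence[need]),
                    proteomes$protein_id[need])
    # proteins whose CDS is shorter than a read cannot be sampled; redraw
    # them onto the longest protein of the same genus (degenerate configs)
    pid <- proteomes$protein_id[prot_idx]
    cds_len <- nchar(cds)[pid]
    short <- which(cds_len < read_length)
    for (i in short) {
      idx <- by_genus[[genus_draw[i]]]
      lens <- nchar(proteomes$sequence[idx]) * 3L + 3L
      j <- idx[which.max(lens)]
      pid[i] <- proteomes$protein_id[j]
      if (!pid[i] %in% names(cds))
        cds[pid[i]] <- reverse_translate(proteomes$sequence[j])
      cds_len[i] <- nchar(cds[[pid[i]]])
      assert_that(cds_len[i] >= read_length,
                  "no coding sequence long enough for read_length")
    }

    start0 <- vapply(cds_len - read_length,
                     function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    frag <- stringi::stri_sub(cds[pid], start0 + 1L, start0 + read_length)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    neg <- strand == "-"
    frag[neg] <- revcomp(frag[neg])

    if (error_rate > 0) {
      n_err <- stats::rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(read_length, n_err[i])
        ch <- strsplit(frag[i], "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(ch[pos],
                          function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                          character(1), USE.NAMES = FALSE)
        frag[i] <- paste(ch, collapse = "")
      }
    }

    qual <- rep(strrep(intToUtf8(base_quality + 33L), read_length), n_reads)
    bad <- which(runif(n_reads) < low_quality_tail_fraction)
    if (length(bad) && tail_length > 0L) {
      tl <- min(tail_length, read_length)
      qual[bad] <- paste0(strrep(intToUtf8(base_quality + 33L), read_length - tl),
                          strrep(intToUtf8(tail_quality + 33L), tl))
    }

    out <- data.frame(
      read_id = sprintf("r%06d", seq_len(n_reads)),
      sequence = frag, quality = qual, source_protein = pid,
      strand = strand, start = start0, end = start0 + read_length,
      stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Quality-trim reads (sliding window) and drop short reads
#'
#' Emulates sliding-window quality trimming: scanning from the 5' end with a
#' window of 4 bases (truncated at the read end), the read is cut just
#' before the first window whose mean quality falls below
#' `min_mean_quality`; reads shorter than `min_length` after trimming are
#' dropped. Hidden source coordinates are adjusted so that the trimmed read
#' still maps exactly onto its source coding sequence.
#'
#' @param reads a `read_set`.
#' @param min_mean_quality window mean-quality threshold.
#' @param min_length minimum retained read length (>= 1).
#' @return A filtered/trimmed `read_set` (input order preserved).
#' @export
trim_reads <- function(reads, min_mean_quality = 20, min_length = 30L) {
  assert_count(min_length, "min_length", min = 1L)
  if (nrow(reads) == 0L) return(reads)
  keep_len <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    q <- utf8ToInt(reads$quality[i]) - 33L
    n <- length(q)
    cut <- n
    for (s in seq_len(n)) {
      w <- q[s:min(s + 3L, n)]
      if (mean(w) < min_mean_quality) { cut <- s - 1L; break }
    }
    keep_len[i] <- cut
  }
  trimmed <- keep_len < nchar(reads$sequence)
  out <- reads
  out$sequence <- stringi::stri_sub(out$sequence, 1L, keep_len)
  out$quality <- stringi::stri_sub(out$quality, 1L, keep_len)
  loss <- nchar(reads$sequence) - keep_len
  plus <- out$strand == "+"
  out$end[plus] <- out$end[plus] - loss[plus]
  out$start[!plus] <- out$start[!plus] + loss[!plus]
  out <- out[keep_len >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}
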