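# In-silico tryptic digestion.

# Internal: 0-based cut positions (after residue i) for trypsin rules:
# cleave C-terminal to K or R unless the next residue is P.
cut_sites <- function(chars) {
  n <- length(chars)
  if (n < 2L) return(integer(0))
  i <- which(chars[-n] %in% c("K", "R"))
  i[chars[i + 1L] != "P"]
}

#' Tryptic digestion of one protein sequence
#'
#' Cleaves C-terminal to K or R except before P, and returns every product
#' with at most `max_missed_cleavages` internal uncut sites and length
#' within `[min_len, max_len]`. The result is a set (unique peptides).
#'
#' @param sequence amino-acid string (20-letter alphabet).
#' @param max_missed_cleavages 0 to 3.
#' @param min_len,max_len product length bounds.
#' @return Character vector of unique peptides.
#' @examples
#' digest("AKPLRGK", 0, 1, 50)   # "AKPLR", "GK"
#' @export
digest <- function(sequence, max_missed_cleavages = 2L, min_len = 6L,
                   max_len = 40L) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "`sequence` must be a single string")
  assert_count(max_missed_cleavages, "max_missed_cleavages")
  assert_that(max_missed_cleavages <= 3L, "max_missed_cleavages must be <= 3")
  assert_count(min_len, "min_len", min = 1L)
  assert_that(min_len <= max_len, "min_len must be <= max_len")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% AA20))
    stopf("non-amino-acid character in sequence: '%s'",
          setdiff(chars, AA20)[1])
  bounds <- c(0L, cut_sites(chars), length(chars))
  nb <- length(bounds)
  peps <- character(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(i + max_missed_cleavages + 1L, nb)
    for (j in (i + 1L):jmax) {
      len <- bounds[j] - bounds[i]
      if (len >= min_len && len <= max_len)
        peps <- c(peps, substr(sequence, bounds[i] + 1L, bounds[j]))
    }
  }
  unique(peps)
}

# Vectorised digestion over many sequences; returns a data.table with
# columns (peptide, seq_idx). Used for peptide-index construction and the
# peptidome ground-truth index.
digest_many <- function(sequences, max_missed_cleavages = 2L, min_len = 6L,
                        max_len = 40L) {
  lists <- lapply(sequences, function(s) {
    # tolerate the odd unknown residue by splitting on it: fragments between
    # invalid characters are digested independently
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (all(chars %in% AA20)) {
      digest(s, max_missed_cleavages, min_len, max_len)
    } else {
      parts <- strsplit(gsub("[^ACDEFGHIKLMNPQRSTVWY]", " ", s), " +")[[1]]
      parts <- parts[nchar(parts) > 0]
      unique(unlist(lapply(parts, digest, max_missed_cleavages,
                           min_len, max_len)))
    }
  })
  data.table::data.table(
    peptide = unlist(lists, use.names = FALSE),
    seq_idx = rep(seq_along(sequences), lengths(lists))
  )
}
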