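# Internal helpers: alphabets, codon table, seeded evaluation, validation.

.datatable.aware <- TRUE

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

# Fixed one-codon-per-amino-acid table: the alphabetically first codon of the
# standard genetic code for each residue. Using a single codon per residue
# keeps six-frame ORF recovery exact (reverse translation is injective).
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- sort(unique(gc[gc != "*"]))
  vapply(aa, function(a) sort(names(gc)[gc == a])[1], character(1))
}
AA_TO_CODON <- codon_table()
CODON_TO_AA <- Biostrings::GENETIC_CODE

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 0L) {
  assert_that(length(x) == 1L && is.numeric(x) && !is.na(x) &&
                x == floor(x) && x >= min,
              "`%s` must be a single integer >= %d", name, min)
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  assert_that(ok, "`%s` must lie in %s%g, %g%s", name,
              if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
}

assert_seed <- function(seed) {
  assert_that(length(seed) == 1L && is.numeric(seed) && !is.na(seed) &&
                seed == floor(seed), "`seed` must be a single integer")
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators funnel through this.
with_seed <- function(seed, code) {
  assert_seed(seed)
  withr::with_seed(as.integer(seed), code)
}

# Deterministic fan-out of one experiment seed into per-stage seeds.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
stage_seed <- function(seed, stage) {
  offsets <- c(taxonomy = 11L, proteomes = 23L, community = 37L, reads = 53L,
               peptidome_gel_based = 71L, peptidome_gel_free = 89L,
               search = 101L, misc = 113L)
  off <- offsets[[stage]]
  as.integer((abs(as.numeric(seed)) * 48271 + off * 16807) %% 2147483563) + 1L
}

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# Reverse-translate an amino-acid string with the fixed codon table and
# append a TAA stop.
reverse_translate <- function(aa_seq, add_stop = TRUE) {
  vapply(aa_seq, function(s) {
    codons <- AA_TO_CODON[strsplit(s, "", fixed = TRUE)[[1]]]
    if (anyNA(codons)) stopf("sequence contains a non-amino-acid character")
    paste0(paste(codons, collapse = ""), if (add_stop) "TAA" else "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate a nucleotide string in frame 0 (first base). Codons containing
# any non-ACGT character translate to "*" (treated as a stop, conservative).
translate_frame <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- stringi::stri_sub(nt, starts, starts + 2L)
  aa <- CODON_TO_AA[codons]
  aa[is.na(aa)] <- "*"
  paste(aa, collapse = "")
}

random_aa <- function(n_chars) {
  paste(sample(AA20, n_chars, replace = TRUE), collapse = "")
}

# Substitute each position with probability `rate` by one of the 19 other
# residues (never the original), vectorised over one sequence.
mutate_aa <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    repl <- vapply(chars[hit],
                   function(a) sample(setdiff(AA20, a), 1L),
                   character(1), USE.NAMES = FALSE)
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

phred_to_string <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1), USE.NAMES = FALSE)
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}
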