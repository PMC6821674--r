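# Read trimming, gene prediction, assembly, taxon detection, deduplication
# and database merging.

mk_reads <- function(seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))   # Q40
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  out <- data.frame(read_id = ids, sequence = seqs, quality = quals,
                    source_protein = rep(NA_character_, n),
                    strand = rep("+", n), start = rep(0L, n),
                    end = nchar(seqs), stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

phred_string <- function(q) intToUtf8(q + 33L)

test_that("trim_reads is a no-op on clean reads and drops short ones", {
  rd <- mk_reads(c(strrep("ACGT", 25), strrep("AC", 30)))
  out <- trim_reads(rd, 20, 30)
  expect_identical(out$sequence, rd$sequence)

  short <- mk_reads(strrep("A", 25))
  expect_equal(nrow(trim_reads(short, 20, 30)), 0L)
  expect_equal(nrow(trim_reads(mk_reads(character(0)), 20, 30)), 0L)
})

test_that("trim_reads matches a brute-force window scan", {
  brute_keep <- function(q, thr) {
    n <- length(q)
    for (s in seq_len(n)) {
      w <- q[s:min(s + 3L, n)]
      if (mean(w) < thr) return(s - 1L)
    }
    n
  }
  # worked case: 100-base read, last 20 bases at Q2, threshold 20
  q <- c(rep(38L, 80), rep(2L, 20))
  rd <- mk_reads(strrep("ACGT", 25), phred_string(q))
  out <- trim_reads(rd, 20, 30)
  expect_lte(nchar(out$sequence), 80L)
  expect_equal(nchar(out$sequence), brute_keep(q, 20))

  # randomised qualities against the independent scan
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(40:120, 1)
      q <- sample(0:40, n, replace = TRUE)
      rd <- mk_reads(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = ""), phred_string(q))
      out <- trim_reads(rd, 20, 1)
      keep <- brute_keep(q, 20)
      if (keep == 0) expect_equal(nrow(out), 0L)
      else expect_equal(nchar(out$sequence), keep)
    }
  })
})

test_that("trimming preserves read-source consistency", {
  tp <- tiny_proteomes()
  cm <- simulate_community(tp$tree, 3, 1, seed = 2)
  rd <- simulate_reads(cm, tp$proteomes, 150, 120, 0, seed = 8,
                       low_quality_tail_fraction = 0.5)
  tt <- trim_reads(rd, 20, 30)
  expect_true(any(nchar(tt$sequence) < 150))   # something was trimmed
  cds <- setNames(
    vapply(unique(tt$source_protein), function(p) paste0(paste(
      mproteo:::AA_TO_CODON[strsplit(
        tp$proteomes$sequence[tp$proteomes$protein_id == p], "")[[1]]],
      collapse = ""), "TAA"), character(1)), unique(tt$source_protein))
  for (i in seq_len(nrow(tt))) {
    window <- substr(cds[[tt$source_protein[i]]], tt$start[i] + 1L, tt$end[i])
    obs <- tt$sequence[i]
    if (tt$strand[i] == "-")
      obs <- stringi::stri_reverse(chartr("ACGT", "TGCA", obs))
    expect_identical(obs, window)
  }
})

test_that("six-frame ORF prediction recovers in-frame translations", {
  tp <- tiny_proteomes()
  prot <- tp$proteomes$sequence[1]
  aa30 <- substr(prot, 11, 40)
  nt <- paste(mproteo:::AA_TO_CODON[strsplit(aa30, "")[[1]]], collapse = "")
  expect_equal(nchar(nt), 90L)
  db <- predict_genes_from_reads(mk_reads(nt), min_orf_aa = 10)
  expect_true(aa30 %in% db$entries$sequence)
  # the full 30-aa in-frame translation is one of the entries
  expect_true(any(nchar(db$entries$sequence) == 30 &
                    db$entries$sequence == aa30))

  # a read whose six frames are all stop-broken yields nothing
  # (a plain TAA repeat does NOT work: its +1 frame is an Asn run)
  orf_free <- "TATTAGTGATTTTAATCTAGTTTAAGCAAGGTAGGG"
  allstop <- predict_genes_from_reads(mk_reads(orf_free), min_orf_aa = 8)
  expect_equal(nrow(allstop$entries), 0L)

  expect_error(predict_genes_from_reads(mk_reads("ACGT"), min_orf_aa = 2),
               "min_orf_aa")
})

test_that("every NAM entry from error-free reads is a reference substring", {
  tp <- tiny_proteomes()
  cm <- simulate_community(tp$tree, 4, 1, seed = 5)
  rd <- simulate_reads(cm, tp$proteomes, 150, 1000, 0, seed = 6)
  db <- predict_genes_from_reads(rd, min_orf_aa = 30)
  expect_gt(nrow(db$entries), 0L)
  refs <- tp$proteomes$sequence
  in_frame <- vapply(db$entries$sequence, function(s)
    any(stringi::stri_detect_fixed(refs, s)), logical(1))
  # in-frame entries are literal substrings; out-of-frame stop-free ORFs
  # are not, so check the guaranteed direction: each read's true-frame
  # translation appears among entries that ARE substrings
  expect_gt(sum(in_frame), 0L)
  # and entries that match the recorded source are always substrings
  src <- db$entries$source_protein
  seqs <- db$entries$sequence
  hit <- vapply(seq_along(seqs), function(i) {
    ref <- refs[tp$proteomes$protein_id == src[i]]
    stringi::stri_detect_fixed(ref, seqs[i])
  }, logical(1))
  expect_true(all(in_frame[hit]))
  # the majority of reads contribute their in-frame fragment
  expect_gt(mean(in_frame), 0.15)
})

test_that("greedy assembly merges exact overlaps and keeps determinism", {
  x <- "ATCGGATTCAAGGCTTACGGAT"
  a <- substr(x, 1, 15); b <- substr(x, 6, 22)   # overlap 10
  ctg <- assemble_reads(mk_reads(c(a, b)), min_overlap = 10,
                        drop_singletons = FALSE)
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$sequence %in% c(x, stringi::stri_reverse(
    chartr("ACGT", "TGCA", x))))
  expect_equal(ctg$support, 2L)

  # disjoint reads stay singleton contigs (and are droppable); note the
  # two sequences must not overlap via reverse complement either
  rd <- mk_reads(c("ATCGATTGCAAGCTTACGGA", "CCGTAACTGGTCAGTCCAAT"))
  keep <- assemble_reads(rd, min_overlap = 12, drop_singletons = FALSE)
  expect_equal(nrow(keep), 2L)
  expect_equal(nrow(assemble_reads(rd, min_overlap = 12)), 0L)

  expect_error(assemble_reads(rd, min_overlap = 5), "min_overlap")
})

test_that("assembly reconstructs a tiled CDS", {
  tp <- tiny_proteomes()
  prot <- tp$proteomes$sequence[3]
  cds <- paste(mproteo:::AA_TO_CODON[strsplit(substr(prot, 1, 100),
                                              "")[[1]]], collapse = "")
  starts <- seq(1, nchar(cds) - 99, by = 25)   # 100-mers, 75 nt overlaps
  reads <- vapply(starts, function(s) substr(cds, s, s + 99), character(1))
  ctg <- assemble_reads(mk_reads(reads), min_overlap = 20)
  rc <- function(z) stringi::stri_reverse(chartr("ACGT", "TGCA", z))
  expect_true(any(stringi::stri_detect_fixed(ctg$sequence, cds) |
                    stringi::stri_detect_fixed(ctg$sequence, rc(cds))))
})

test_that("contig gene calling equals read gene calling on singletons", {
  tp <- tiny_proteomes()
  cm <- simulate_community(tp$tree, 3, 1, seed = 5)
  rd <- simulate_reads(cm, tp$proteomes, 150, 60, 0, seed = 7)
  # min_overlap too strict for any merge -> singleton contigs = reads
  ctg <- assemble_reads(rd, min_overlap = 149, drop_singletons = FALSE)
  expect_equal(nrow(ctg), nrow(rd))
  am <- predict_genes_from_contigs(ctg, min_orf_aa = 30)
  nam <- predict_genes_from_reads(rd, min_orf_aa = 30)
  expect_setequal(unique(am$entries$sequence), unique(nam$entries$sequence))

  empty <- ctg[0, , drop = FALSE]
  expect_equal(nrow(predict_genes_from_contigs(empty, 30)$entries), 0L)
})

test_that("marker detection finds present genera and respects min_hits", {
  tp <- tiny_proteomes()
  mi <- build_marker_index(tp$proteomes)
  g <- "g03"
  cm1 <- structure(setNames(1, g), class = "community_profile")
  rd <- simulate_reads(cm1, tp$proteomes, 150, 200, 0, seed = 9)
  det <- detect_taxa(rd, mi, min_hits = 2)
  expect_true(g %in% det)

  expect_equal(detect_taxa(rd, mi, min_hits = 10000L), character(0))
  expect_error(detect_taxa(rd, structure(list(
    table = data.table::data.table(kmer = character(0),
                                   genus = character(0)), k = 21L),
    class = "marker_index"), 1), "empty")
})

test_that("all five abundant genera are detected in >= 19/20 seeds", {
  # dedicated detection-scale world: small genomes, ample reads
  tr <- generate_taxonomy(5, c(1, 5, 1, 1, 1), seed = 2)
  pr <- generate_reference_proteomes(tr, 30, n_families = 0, seed = 2)
  mi <- build_marker_index(pr)
  cm <- structure(setNames(c(0.40, 0.25, 0.15, 0.12, 0.08), tax_genera(tr)),
                  class = "community_profile")
  ok <- vapply(1:20, function(s) {
    rd <- simulate_reads(cm, pr, 150, 1000, 0.01, seed = s)
    det <- detect_taxa(rd, mi, min_hits = 1)
    all(tax_genera(tr) %in% det)
  }, logical(1))
  expect_gte(sum(ok), 19L)
})

test_that("taxonomy database pulls whole proteomes of detected genera", {
  tp <- tiny_proteomes()
  one <- build_taxonomy_db("g02", tp$proteomes)
  expect_equal(nrow(one$entries),
               length(unique(tp$proteomes$sequence[
                 tp$proteomes$taxon_id == "g02"])))
  expect_equal(nrow(build_taxonomy_db(character(0), tp$proteomes)$entries),
               0L)
  expect_error(build_taxonomy_db("g99", tp$proteomes), "g99")
})

test_that("TAX database dominates NAM under the default desk world", {
  dbs <- desk_dbs()
  expect_gte(nrow(dbs$TAX$entries), nrow(dbs$NAM$entries))
  expect_gte(nrow(dbs$NAM$entries), nrow(dbs$AM$entries))
})

test_that("deduplication collapses exact duplicates and is idempotent", {
  db <- protein_db("NAM", 1L, data.frame(
    entry_id = c("b", "a", "c"), sequence = c("MKK", "MKK", "MR"),
    origin = "x", stringsAsFactors = FALSE))
  dd <- deduplicate(db)
  expect_equal(nrow(dd$entries), 2L)
  expect_true("a" %in% dd$entries$entry_id)    # smallest id kept
  expect_false("b" %in% dd$entries$entry_id)

  uniq <- protein_db("NAM", 1L, data.frame(
    entry_id = c("a", "b"), sequence = c("MK", "MR"), origin = "x",
    stringsAsFactors = FALSE))
  expect_identical(deduplicate(uniq)$entries, uniq$entries)

  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(1:12, 1)
      e <- data.frame(
        entry_id = sprintf("e%02d", seq_len(n)),
        sequence = sample(c("MAK", "MCK", "MDK", "MEK"), n, TRUE),
        origin = "x", stringsAsFactors = FALSE)
      db <- protein_db("AM", 1L, e)
      once <- deduplicate(db)
      twice <- deduplicate(once)
      expect_identical(once$entries, twice$entries)
      expect_setequal(unique(e$sequence), once$entries$sequence)
    }
  })
})

test_that("merge_dbs unions targets, deduplicates, and rebuilds decoys", {
  mk <- function(ids, seqs, name = "NAM") protein_db(name, 2L, data.frame(
    entry_id = ids, sequence = seqs, origin = "x", stringsAsFactors = FALSE))
  d1 <- mk(c("a1", "a2", "a3"), c("MAKL", "MCKL", "MDKL"))
  d2 <- mk(c("b1", "b2", "b3", "b4"), c("MEKL", "MFKL", "MGKL", "MHKL"))
  comb <- merge_dbs(list(d1, d2))
  expect_equal(nrow(comb$entries), 7L)
  expect_equal(nrow(comb$decoys), 7L)
  expect_equal(comb$db_name, "Comb")

  same <- merge_dbs(list(d1, d1), name = "NAM")
  expect_identical(same$entries[, c("entry_id", "sequence")],
                   deduplicate(d1)$entries[, c("entry_id", "sequence")])

  # |Comb| <= sum of parts with equality iff pairwise sequence-disjoint
  d3 <- mk(c("c1", "c2"), c("MAKL", "MIKL"))   # shares MAKL with d1
  partial <- merge_dbs(list(d1, d3))
  expect_lt(nrow(partial$entries), nrow(d1$entries) + nrow(d3$entries))
  expect_equal(nrow(merge_dbs(list(d1, d2))$entries),
               nrow(d1$entries) + nrow(d2$entries))

  expect_error(merge_dbs(list()), "non-empty")
})

test_that("read databases out-collect assembled databases in true peptides
           (stochastic, 10 seeds)", {
  wins <- vapply(1:10, function(s) {
    tr <- generate_taxonomy(4, c(2, 2, 1, 1, 1), seed = s)
    pr <- generate_reference_proteomes(tr, 60, n_families = 10, seed = s)
    cm <- simulate_community(tr, 3, 1.5, seed = s)
    rd <- trim_reads(simulate_reads(cm, pr, 150, 200, 0.01, seed = s))
    nam <- deduplicate(predict_genes_from_reads(rd, 40))
    am <- deduplicate(predict_genes_from_contigs(
      assemble_reads(rd, 30, drop_singletons = TRUE), 40))
    ref_peps <- unique(build_truth_index(pr)$table$peptide)
    true_peps <- function(db) {
      if (nrow(db$entries) == 0L) return(0L)
      peps <- unique(mproteo:::digest_many(db$entries$sequence)$peptide)
      sum(peps %in% ref_peps)
    }
    true_peps(nam) - true_peps(am)
  }, numeric(1))
  expect_gte(median(wins), 0)
  expect_gte(sum(wins >= 0), 8L)
})
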