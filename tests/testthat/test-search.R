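# Digestion, decoys, exact-match search, protein grouping, FDR filtering,
# two-round search and the workflow summary.

# independent digestion oracle: enumerate all cut-site interval pairs
brute_digest <- function(seq, mc, min_len, max_len) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  sites <- integer(0)
  for (i in seq_len(max(n - 1L, 0L)))
    if (chars[i] %in% c("K", "R") && chars[i + 1L] != "P")
      sites <- c(sites, i)
  bounds <- c(0L, sites, n)
  out <- character(0)
  for (i in seq_along(bounds)) for (j in seq_along(bounds)) {
    if (j <= i) next
    if (j - i - 1L > mc) next
    len <- bounds[j] - bounds[i]
    if (len >= min_len && len <= max_len)
      out <- c(out, substr(seq, bounds[i] + 1L, bounds[j]))
  }
  unique(out)
}

random_protein <- function(n) paste(sample(mproteo:::AA20, n, TRUE),
                                    collapse = "")

# ordered, duplicate-preserving full cleavage (digest() returns a set)
fully_cleave <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  sites <- integer(0)
  for (i in seq_len(max(n - 1L, 0L)))
    if (chars[i] %in% c("K", "R") && chars[i + 1L] != "P")
      sites <- c(sites, i)
  bounds <- c(0L, sites, n)
  vapply(seq_len(length(bounds) - 1L), function(i)
    substr(seq, bounds[i] + 1L, bounds[i + 1L]), character(1))
}

test_that("digest applies the tryptic rule", {
  expect_setequal(digest("AKPLRGK", 0, 1, 50), c("AKPLR", "GK"))
  expect_setequal(digest("MKRAPK", 1, 1, 50),
                  c("MK", "R", "APK", "MKR", "RAPK"))
  expect_error(digest("MKXK", 0, 1, 50), "non-amino-acid")
  expect_error(digest("MK", 5, 1, 50), "max_missed_cleavages")
})

test_that("fully-cleaved products concatenate back to the sequence", {
  withr::with_seed(2, {
    for (i in 1:20) {
      s <- random_protein(sample(10:60, 1))
      expect_identical(paste(fully_cleave(s), collapse = ""), s)
      expect_setequal(digest(s, 0, 1, 10000), unique(fully_cleave(s)))
    }
  })
})

test_that("digest equals brute-force cut-site enumeration", {
  withr::with_seed(3, {
    for (i in 1:40) {
      s <- random_protein(sample(15:50, 1))
      mc <- sample(0:3, 1)
      expect_setequal(digest(s, mc, 1, 100), brute_digest(s, mc, 1, 100))
      expect_setequal(digest(s, mc, 6, 20), brute_digest(s, mc, 6, 20))
    }
  })
})

test_that("pseudo-reversal keeps cut sites and peptide lengths", {
  db <- protein_db("NAM", 1L, data.frame(
    entry_id = "t1", sequence = "ABCKDEFR", origin = "x",
    stringsAsFactors = FALSE))
  dec <- build_decoys(db)
  expect_equal(dec$decoys$sequence, "CBAKFEDR")
  expect_equal(dec$decoys$entry_id, "DECOY_t1")

  withr::with_seed(5, {
    for (i in 1:30) {
      s <- random_protein(sample(20:80, 1))
      d <- mproteo:::pseudo_reverse(s)
      expect_equal(nchar(d), nchar(s))
      expect_identical(sort(nchar(fully_cleave(d))),
                       sort(nchar(fully_cleave(s))))
    }
  })
})

test_that("decoy peptides rarely collide with target peptides", {
  withr::with_seed(6, {
    seqs <- vapply(1:100, function(i) random_protein(150), character(1))
  })
  db <- build_decoys(protein_db("TAX", 1L, data.frame(
    entry_id = sprintf("t%03d", 1:100), sequence = seqs, origin = "x",
    stringsAsFactors = FALSE)))
  tgt <- unique(mproteo:::digest_many(db$entries$sequence)$peptide)
  dec <- unique(mproteo:::digest_many(db$decoys$sequence)$peptide)
  expect_lt(mean(dec %in% tgt), 0.05)
})

test_that("exact-match search identifies and conserves spectra", {
  db <- build_decoys(protein_db("TAX", 1L, data.frame(
    entry_id = c("t1", "t2"),
    sequence = c("MAAAGILKEEEPTIDEK", "MCCCGILKWWWPTIDEK"),
    origin = "x", stringsAsFactors = FALSE)))
  pep <- structure(list(
    label = "gel_free",
    observations = data.frame(peptide = c("EEEPTIDEK", "GGGGGGGGK"),
                              count = c(3L, 2L), stringsAsFactors = FALSE),
    truth = list(), n_spectra = 5L), class = "observed_peptidome")
  raw <- search_peptidome(pep, db)
  expect_equal(raw$matches$entry_id, "t1")
  expect_equal(raw$matches$count, 3L)
  expect_equal(raw$unidentified$peptide, "GGGGGGGGK")
  # conservation: identified + unidentified = total observed counts
  expect_equal(sum(raw$matches$count[!duplicated(raw$matches$peptide)]) +
                 sum(raw$unidentified$count), 5L)
})

test_that("search spectra totals equal a brute-force recount", {
  tp <- tiny_proteomes()
  cm <- simulate_community(tp$tree, 3, 1, seed = 2)
  pep <- simulate_peptidome(cm, tp$proteomes, "gel_free", 500,
                            noise_fraction = 0.1, seed = 12)
  db <- build_decoys(build_taxonomy_db(tax_genera(tp$tree), tp$proteomes))
  raw <- search_peptidome(pep, db)
  idx_peps <- unique(c(
    mproteo:::digest_many(db$entries$sequence)$peptide,
    mproteo:::digest_many(db$decoys$sequence)$peptide))
  brute_total <- sum(pep$observations$count[
    pep$observations$peptide %in% idx_peps])
  expect_equal(sum(raw$matches$count[!duplicated(raw$matches$peptide)]),
               brute_total)
  expect_equal(brute_total + sum(raw$unidentified$count), pep$n_spectra)
})

test_that("protein grouping collapses identical and nested peptide sets", {
  # A {p1,p2}, B {p1} -> one group anchored at A with B absorbed
  db <- protein_db("TAX", 1L, data.frame(
    entry_id = c("A", "B"),
    sequence = c("MAAAAAAAKWDDDDDDDR", "MAAAAAAAK"),
    origin = "x", stringsAsFactors = FALSE))
  pep <- structure(list(
    label = "gel_free",
    observations = data.frame(peptide = c("MAAAAAAAK", "WDDDDDDDR"),
                              count = c(2L, 1L), stringsAsFactors = FALSE),
    truth = list(), n_spectra = 3L), class = "observed_peptidome")
  g <- infer_protein_groups(search_peptidome(pep, db), db)
  expect_equal(nrow(g), 1L)
  expect_equal(g$anchor, "A")
  expect_setequal(g$members[[1]], c("A", "B"))
  expect_equal(g$score, 3)
  expect_equal(g$n_distinct_peptides, 2L)
})

test_that("grouping matches the brute-force nested-set partition", {
  oracle_check <- function(g, matched_sets) {
    keys <- lapply(g$peptides, sort)
    # 1. no group's peptide set is a subset of another group's
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      if (i == j) next
      expect_false(all(keys[[i]] %in% keys[[j]]))
    }
    # 2. group peptide sets are exactly the maximal matched sets
    maximal <- Filter(function(s) !any(vapply(matched_sets, function(t)
      length(s) < length(t) && all(s %in% t), logical(1))), matched_sets)
    expect_setequal(vapply(keys, paste, character(1), collapse = "|"),
                    unique(vapply(lapply(maximal, sort), paste,
                                  character(1), collapse = "|")))
    # 3. every entry is a member of a group whose set contains its set
    for (gi in seq_len(nrow(g))) {
      for (m in g$members[[gi]]) {
        expect_true(all(matched_sets[[m]] %in% keys[[gi]]))
      }
    }
  }
  withr::with_seed(8, {
    for (rep in 1:5) {
      # 50 proteins stitched from a shared peptide pool (~30% sharing)
      pool <- vapply(1:60, function(i)
        paste0(random_protein(8), sample(c("K", "R"), 1)), character(1))
      seqs <- vapply(1:50, function(i)
        paste(sample(pool, 5), collapse = ""), character(1))
      db <- protein_db("TAX", 1L, data.frame(
        entry_id = sprintf("e%02d", 1:50), sequence = seqs, origin = "x",
        stringsAsFactors = FALSE))
      db <- deduplicate(db)
      obs_peps <- sample(pool, 35)
      pep <- structure(list(
        label = "gel_free",
        observations = data.frame(peptide = obs_peps,
                                  count = sample(1:4, 35, TRUE),
                                  stringsAsFactors = FALSE),
        truth = list(), n_spectra = 100L), class = "observed_peptidome")
      raw <- search_peptidome(pep, db)
      g <- infer_protein_groups(raw, db)
      matched_sets <- lapply(split(raw$matches$peptide, raw$matches$entry_id),
                             function(p) sort(unique(p)))
      oracle_check(g, matched_sets)
      # group score equals the sum of its peptides' spectrum counts
      cnts <- setNames(pep$observations$count, pep$observations$peptide)
      expect_equal(g$score, vapply(g$peptides, function(p)
        sum(cnts[p]), numeric(1)))
    }
  })
})

test_that("FDR prefix acceptance follows the hand-walked example", {
  # targets scored 10..1 plus one decoy at 9.5: accepting past the decoy
  # means 1/1 = 100% FDR, so only the score-10 target survives
  g <- make_groups(c(10:1, 9.5), c(rep(FALSE, 10), TRUE))
  res <- protein_fdr_filter(g, 0.01)
  expect_equal(res$n_proteins_validated, 1L)
  expect_equal(res$groups$score, 10)

  # no decoys: everything accepted
  res2 <- protein_fdr_filter(make_groups(5:1, rep(FALSE, 5)), 0.01)
  expect_equal(res2$n_proteins_validated, 5L)

  expect_error(protein_fdr_filter(g, 0), "fdr")
  expect_error(protein_fdr_filter(g, 1), "fdr")
})

test_that("FDR acceptance equals an exhaustive threshold scan", {
  brute_accept <- function(groups, fdr) {
    g <- groups[order(-groups$score, -groups$n_distinct_peptides,
                      groups$anchor), ]
    best <- 0L
    for (k in seq_len(nrow(g))) {
      d <- sum(g$is_decoy[1:k]); t <- k - d
      ratio <- if (t == 0L) { if (d == 0L) 0 else Inf } else d / t
      if (ratio <= fdr) best <- k
    }
    g$anchor[seq_len(best)]
  }
  withr::with_seed(9, {
    for (rep in 1:30) {
      n <- sample(5:40, 1)
      g <- make_groups(sample(1:20, n, TRUE) + runif(n),
                       runif(n) < 0.3)
      fdr <- sample(c(0.01, 0.05, 0.2, 0.5), 1)
      res <- protein_fdr_filter(g, fdr)
      brute <- brute_accept(g, fdr)
      expect_setequal(res$groups$anchor, setdiff(brute, g$anchor[g$is_decoy]))
      # maximality: the accepted prefix cannot be extended within fdr
      ord <- g[order(-g$score, -g$n_distinct_peptides, g$anchor), ]
      k <- length(brute)
      if (k < nrow(ord)) {
        for (k2 in (k + 1):nrow(ord)) {
          d <- sum(ord$is_decoy[1:k2]); t <- k2 - d
          expect_gt(if (t == 0) Inf else d / t, fdr)
        }
      }
    }
  })
})

test_that("single-peptide validation applies the documented proxy rule", {
  ok <- make_groups(3, FALSE, n_peptides = 1L)
  ok$peptides[[1]] <- "LLLLLLLLLLLK"      # length 12
  ok$peptide_counts[[1]] <- 3L
  expect_true(validate_single_peptide(ok[1, ]))

  short <- make_groups(3, FALSE, n_peptides = 1L)
  short$peptides[[1]] <- "LLLLLLK"        # length 7
  short$peptide_counts[[1]] <- 3L
  expect_false(validate_single_peptide(short[1, ]))

  once <- make_groups(1, FALSE, n_peptides = 1L)
  once$peptides[[1]] <- "LLLLLLLLLLLK"
  once$peptide_counts[[1]] <- 1L
  expect_false(validate_single_peptide(once[1, ]))

  expect_error(validate_single_peptide(make_groups(4, FALSE)[1, ]),
               "single-peptide")
})

test_that("the validation rule strictly reduces one-hit-wonder acceptance", {
  withr::with_seed(10, {
    kept <- 0L; total <- 0L
    for (i in 1:20) {
      n <- 30L
      lens <- sample(6:20, n, TRUE)
      cnts <- sample(1:3, n, TRUE, prob = c(0.6, 0.3, 0.1))
      g <- make_groups(cnts + runif(n), rep(FALSE, n), n_peptides = 1L)
      for (j in seq_len(n)) {
        g$peptides[[j]] <- paste(c(sample(c("A", "L", "G"), lens[j] - 1,
                                          TRUE), "K"), collapse = "")
        g$peptide_counts[[j]] <- cnts[j]
      }
      res <- protein_fdr_filter(g, 0.5)
      kept <- kept + res$n_proteins_validated
      total <- total + n
    }
    expect_lt(kept, total)   # without the rule every group passes FDR here
    expect_gt(kept, 0L)
  })
})

test_that("two-round search is closed under a covering database", {
  withr::with_seed(11, {
    seqs <- vapply(1:10, function(i)
      paste0(vapply(1:6, function(j)
        paste0(random_protein(9), sample(c("K", "R"), 1)), character(1)),
        collapse = ""), character(1))
  })
  db <- build_decoys(protein_db("TAX", 1L, data.frame(
    entry_id = sprintf("t%02d", 1:10), sequence = seqs, origin = "x",
    stringsAsFactors = FALSE)))
  # observe 3 fully-cleaved peptides of every protein, twice each
  obs <- unlist(lapply(seqs, function(s) head(digest(s, 0, 6, 40), 3)))
  pep <- structure(list(
    label = "gel_free",
    observations = data.frame(peptide = obs, count = rep(2L, length(obs)),
                              stringsAsFactors = FALSE),
    truth = list(), n_spectra = sum(rep(2L, length(obs)))),
    class = "observed_peptidome")
  trs <- two_round_search(pep, db)
  expect_lte(nrow(trs$restricted_db$entries), 10L)
  expect_equal(trs$round2$n_proteins_validated, 10L)
  expect_equal(trs$round2$coverage_percent, 100)

  # garbage peptidome: empty round 1 leads to empty round 2, no error
  junk <- structure(list(
    label = "gel_free",
    observations = data.frame(peptide = "WWWWWWWWWK", count = 1L,
                              stringsAsFactors = FALSE),
    truth = list(), n_spectra = 1L), class = "observed_peptidome")
  trs2 <- two_round_search(junk, db)
  expect_equal(trs2$round2$n_proteins_validated, 0L)
  expect_equal(nrow(trs2$restricted_db$entries), 0L)
})

test_that("workflow summary has the canonical two-round layout", {
  wf <- desk_workflow()
  s <- wf$summary
  expect_equal(nrow(s), 14L)
  expect_equal(sum(s$round == 1L), 6L)
  expect_equal(sum(s$round == 2L), 8L)
  expect_setequal(unique(s$db[s$round == 1L]), c("NAM", "AM", "TAX"))
  expect_setequal(unique(s$db[s$round == 2L]),
                  c("NAM", "AM", "TAX", "Comb"))
  count_cols <- c("n_proteins_in_db", "n_spectra_identified",
                  "coverage_percent", "n_distinct_peptides",
                  "n_proteins_validated")
  expect_true(all(count_cols %in% names(s)))
  # coverage recomputed from counts matches the stored value to 0.1
  for (i in seq_len(nrow(s))) {
    lab <- s$label[i]
    tot <- desk_world()$peptidomes[[lab]]$n_spectra
    expect_equal(s$coverage_percent[i],
                 round(100 * s$n_spectra_identified[i] / tot, 1),
                 tolerance = 0.1)
  }
  # per-result internal consistency
  for (res in wf$results) {
    expect_equal(res$coverage_percent,
                 100 * res$n_spectra_identified / res$total_spectra)
    expect_equal(res$n_proteins_validated, nrow(res$groups))
  }
})

test_that("identical peptidomes give identical rows for both labels", {
  tr <- generate_taxonomy(3, c(1, 3, 1, 1, 1), seed = 2)
  pr <- generate_reference_proteomes(tr, 30, n_families = 5, seed = 2)
  cm <- simulate_community(tr, 3, 1, seed = 2)
  rd <- simulate_reads(cm, pr, 150, 80, 0, seed = 2)
  idx <- build_truth_index(pr)
  pep <- simulate_peptidome(cm, pr, "gel_free", 400, seed = 3,
                            truth_index = idx)
  pep_b <- pep; pep_b$label <- "gel_based"
  nam <- deduplicate(predict_genes_from_reads(rd, 40))
  am <- deduplicate(predict_genes_from_contigs(
    assemble_reads(rd, 30, drop_singletons = FALSE), 40))
  tax <- build_taxonomy_db(tax_genera(tr), pr)
  wf <- run_workflow(list(gel_free = pep, gel_based = pep_b),
                     list(NAM = nam, AM = am, TAX = tax))
  s <- wf$summary
  for (r in unique(s$round)) for (d in unique(s$db[s$round == r])) {
    a <- s[s$round == r & s$db == d & s$label == "gel_free",
           -match("label", names(s))]
    b <- s[s$round == r & s$db == d & s$label == "gel_based",
           -match("label", names(s))]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})
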