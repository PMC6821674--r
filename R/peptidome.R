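# Observed peptidome simulation: the stand-in for one MS/MS dataset.

#' Precompute the tryptic peptide -> protein truth index of a proteome store
#'
#' Digests every reference protein and maps each peptide to the set of
#' proteins whose digest contains it. Expensive relative to everything else
#' in the simulator, so it can be computed once and passed to
#' [simulate_peptidome()] for both fractionation labels.
#'
#' @param proteomes a [generate_reference_proteomes()] table.
#' @param max_missed_cleavages,min_len,max_len digestion parameters.
#' @return An object of class `peptide_truth_index`.
#' @export
build_truth_index <- function(proteomes, max_missed_cleavages = 2L,
                              min_len = 6L, max_len = 40L) {
  dt <- digest_many(proteomes$sequence, max_missed_cleavages, min_len, max_len)
  dt[, protein_id := proteomes$protein_id[seq_idx]]
  structure(list(table = dt[, .(peptide, protein_id)],
                 params = list(max_missed_cleavages = max_missed_cleavages,
                               min_len = min_len, max_len = max_len)),
            class = "peptide_truth_index")
}

truth_lookup <- function(index, peptides) {
  tab <- index$table[peptide %in% peptides]
  split(tab$protein_id, tab$peptide)
}

#' Simulate an observed peptidome (spectrum counts per tryptic peptide)
#'
#' Spectra are draws of tryptic peptides from proteins selected
#' proportionally to genus abundance times a per-protein log-normal(0, 1)
#' expression weight; a fraction of spectra are noise peptides (random
#' sequences of length 8-20 ending in K/R, absent from every reference
#' digest). Counts are aggregated per distinct peptide and the hidden truth
#' (peptide -> source proteins, or "noise") is recorded.
#'
#' The two fractionation labels share the same machinery; `gel_based` runs
#' are shallow (fewer spectra) and may concentrate on high-abundance
#' proteins via `detectability_bias` (sampling weight raised to
#' `1 + detectability_bias`), the package's scalar stand-in for gel-slice
#' detectability.
#'
#' @param community a `community_profile`.
#' @param proteomes a [generate_reference_proteomes()] table.
#' @param label `"gel_based"` or `"gel_free"`.
#' @param n_spectra number of spectra to draw (>= 0).
#' @param max_missed_cleavages,min_len,max_len digestion parameters.
#' @param noise_fraction fraction of noise spectra, in \[0, 0.5).
#' @param detectability_bias non-negative scalar; 0 disables the bias.
#' @param seed integer seed.
#' @param truth_index optional prebuilt [build_truth_index()] (must use the
#'   same digestion parameters).
#' @return List of class `observed_peptidome` with elements `label`,
#'   `observations` (data.frame peptide/count), `truth` (named list:
#'   peptide -> character vector of protein ids, or `"noise"`),
#'   `n_spectra`.
#' @export
simulate_peptidome <- function(community, proteomes,
                               label = c("gel_free", "gel_based"),
                               n_spectra = 2000L,
                               max_missed_cleavages = 2L, min_len = 6L,
                               max_len = 40L, noise_fraction = 0.05,
                               detectability_bias = 0, seed = 0L,
                               truth_index = NULL) {
  label <- match.arg(label)
  assert_count(n_spectra, "n_spectra")
  assert_fraction(noise_fraction, "noise_fraction", lo = 0, hi = 0.5,
                  hi_open = TRUE)
  assert_that(detectability_bias >= 0, "detectability_bias must be >= 0")
  if (is.null(truth_index))
    truth_index <- build_truth_index(proteomes, max_missed_cleavages,
                                     min_len, max_len)
  all_ref_peptides <- unique(truth_index$table$peptide)

  present <- names(community)
  rows <- which(proteomes$taxon_id %in% present)
  genus_ab <- as.numeric(community)[match(proteomes$taxon_id[rows], present)]

  with_seed(seed, {
    expr <- rlnorm(length(rows), 0, 1)
    w <- (genus_ab * expr)^(1 + detectability_bias)
    w <- w / sum(w)

    n_noise <- if (noise_fraction > 0) stats::rbinom(1L, n_spectra, noise_fraction) else 0L
    n_true <- n_spectra - n_noise

    # digest lazily: only proteins actually sampled
    counts <- if (n_true > 0L) {
      draw <- sample(seq_along(rows), n_true, replace = TRUE, prob = w)
      tab <- table(draw)
      sampled <- as.integer(names(tab))
      peps <- character(0); reps <- integer(0)
      for (si in seq_along(sampled)) {
        p_row <- rows[sampled[si]]
        prods <- digest(proteomes$sequence[p_row], max_missed_cleavages,
                        min_len, max_len)
        if (length(prods) == 0L) next
        k <- as.integer(tab[si])
        peps <- c(peps, prods[sample.int(length(prods), k, replace = TRUE)])
      }
      peps
    } else character(0)

    noise_peps <- character(0)
    if (n_noise > 0L) {
      for (i in seq_len(n_noise)) {
        repeat {
          len <- sample(8:20, 1L)
          p <- paste0(paste(sample(setdiff(AA20, c("K", "R", "P")), len - 1L,
                                   replace = TRUE), collapse = ""),
                      sample(c("K", "R"), 1L))
          if (!p %in% all_ref_peptides) break
        }
        noise_peps <- c(noise_peps, p)
      }
    }

    all_peps <- c(counts, noise_peps)
    if (length(all_peps) == 0L) {
      obs <- data.frame(peptide = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
      truth <- list()
    } else {
      tab <- table(all_peps)
      obs <- data.frame(peptide = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
      obs <- obs[order(obs$peptide), , drop = FALSE]
      rownames(obs) <- NULL
      truth <- truth_lookup(truth_index, obs$peptide)
      truth <- truth[obs$peptide]
      names(truth) <- obs$peptide
      is_noise <- obs$peptide %in% noise_peps
      truth[is_noise] <- list("noise")
      # defensive: a "true" draw must be found in the reference index
      stopifnot(!anyNA(names(truth)), all(lengths(truth) > 0L))
    }
    structure(list(label = label, observations = obs, truth = truth,
                   n_spectra = as.integer(n_spectra)),
              class = "observed_peptidome")
  })
}

#' @export
print.observed_peptidome <- function(x, ...) {
  cat(sprintf("<observed_peptidome> %s: %d spectra, %d distinct peptides\n",
              x$label, x$n_spectra, nrow(x$observations)))
  invisible(x)
}
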