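# Synthetic reference proteomes and community profiles.

# Pool of function names typical of marine surface-water metaproteomes.
# Entries flagged variable = TRUE carry per-member designators (subunit,
# numeric suffix, ...) so that consensus-name normalisation has work to do.
FUNCTION_POOL <- data.frame(
  name = c(
    "60 kDa chaperonin", "10 kDa chaperonin", "chaperone protein DnaK",
    "elongation factor Tu", "elongation factor G",
    "ATP synthase", "50S ribosomal protein", "30S ribosomal protein",
    "amino-acid ABC transporter binding protein",
    "TonB-dependent receptor",
    "ribulose bisphosphate carboxylase large chain",
    "photosystem II protein", "phycobilisome linker polypeptide",
    "superoxide dismutase", "thioredoxin", "glutamine synthetase",
    "ammonium transporter",
    "phosphate ABC transporter substrate-binding protein",
    "DNA-binding protein HU", "enolase",
    "glyceraldehyde-3-phosphate dehydrogenase", "citrate synthase",
    "malate dehydrogenase", "isocitrate dehydrogenase",
    "ATP-dependent protease ClpP", "trigger factor",
    "peptidyl-prolyl isomerase", "outer membrane porin", "flagellin",
    "proteorhodopsin", "alkaline phosphatase", "urease",
    "nitrate reductase", "glutamate dehydrogenase", "aconitate hydratase",
    "glutathione peroxidase"
  ),
  variable = c(
    FALSE, FALSE, FALSE, FALSE, FALSE,
    TRUE,  TRUE,  TRUE,
    FALSE, FALSE, FALSE,
    TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE
  ),
  stringsAsFactors = FALSE
)

DESIGNATORS <- c("subunit alpha", "subunit beta", "subunit gamma",
                 "L2", "L7", "S1", "S9", "D1", "D2", "1", "2")

#' Generate an annotated reference proteome store
#'
#' Creates `n_proteins_per_genus` protein records for every genus of the
#' taxonomy: the stand-in for a public reference repository from which a
#' taxonomy-derived search database downloads whole proteomes. `n_families`
#' homolog families are seeded from ancestral sequences and their members
#' are spread over at least two genera (point substitutions at rate
#' `1 - within_family_identity` per site); all remaining proteins are
#' singleton families. Members of one family share a base function name,
#' possibly with differing subunit/isoform designators.
#'
#' @param tree a [taxonomy_tree()].
#' @param n_proteins_per_genus records per genus (>= 1).
#' @param n_families number of multi-genus homolog families (>= 0); member
#'   counts cycle 2, 3, 4. `0` makes every protein a singleton family.
#' @param within_family_identity expected per-site identity of each member
#'   to the family ancestor, in \[0.5, 1\].
#' @param seed integer seed.
#' @param length_range amino-acid length range (uniform draw per family /
#'   singleton).
#' @return data.frame of class `reference_proteomes` with columns
#'   `protein_id`, `sequence`, `taxon_id`, `function_name`, `family_id`.
#' @export
generate_reference_proteomes <- function(tree, n_proteins_per_genus,
                                         n_families = 0L,
                                         within_family_identity = 0.9,
                                         seed = 0L,
                                         length_range = c(80L, 400L)) {
  assert_count(n_proteins_per_genus, "n_proteins_per_genus", min = 1L)
  assert_count(n_families, "n_families", min = 0L)
  assert_fraction(within_family_identity, "within_family_identity",
                  lo = 0.5, hi = 1)
  genera <- tax_genera(tree)
  n_g <- length(genera)
  total <- n_g * n_proteins_per_genus
  sizes <- if (n_families > 0) rep_len(c(2L, 3L, 4L), n_families) else integer(0)
  assert_that(sum(sizes) <= total,
              "n_families too large for the proteome store")
  if (n_families > 0)
    assert_that(n_g >= 2L, "multi-genus families need >= 2 genera")

  with_seed(seed, {
    slot_used <- setNames(integer(n_g), genera)
    recs <- vector("list", total)
    k <- 0L

    place <- function(genus, sequence, fam, fun) {
      slot_used[[genus]] <<- slot_used[[genus]] + 1L
      k <<- k + 1L
      recs[[k]] <<- data.frame(
        protein_id = sprintf("%s_p%04d", genus, slot_used[[genus]]),
        sequence = sequence, taxon_id = genus,
        function_name = fun, family_id = fam,
        stringsAsFactors = FALSE)
    }

    mut_rate <- 1 - within_family_identity
    pool_n <- nrow(FUNCTION_POOL)
    for (f in seq_len(n_families)) {
      size <- sizes[f]
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      anc <- random_aa(len)
      base <- FUNCTION_POOL$name[(f - 1L) %% pool_n + 1L]
      variable <- FUNCTION_POOL$variable[(f - 1L) %% pool_n + 1L]
      # spread members over distinct genera, round-robin with spill-over
      g_idx <- ((f - 1L + seq_len(size) - 1L) %% n_g) + 1L
      for (j in seq_len(size)) {
        g <- genera[g_idx[j]]
        if (slot_used[[g]] >= n_proteins_per_genus) {
          free <- genera[slot_used < n_proteins_per_genus]
          g <- free[1]
        }
        fun <- if (variable)
          paste(base, DESIGNATORS[(j - 1L) %% length(DESIGNATORS) + 1L])
        else base
        place(g, mutate_aa(anc, mut_rate), sprintf("fam%04d", f), fun)
      }
    }

    s <- 0L
    for (g in genera) {
      while (slot_used[[g]] < n_proteins_per_genus) {
        s <- s + 1L
        len <- sample(seq(length_range[1], length_range[2]), 1L)
        fun <- FUNCTION_POOL$name[(n_families + s - 1L) %% pool_n + 1L]
        place(g, random_aa(len), sprintf("sng%05d", s), fun)
      }
    }

    out <- do.call(rbind, recs)
    out <- out[order(out$protein_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("reference_proteomes", "data.frame")
    out
  })
}

#' Simulate a skewed community abundance profile
#'
#' Draws relative abundances for `n_present` genera from a log-normal
#' distribution with meanlog 0 and sdlog `skew`, then normalises to sum 1.
#' `skew = 0` degenerates to equal abundances. The skew emulates the typical
#' dominance structure of surface seawater communities, where one or two
#' orders carry most of the protein signal.
#'
#' @param tree a [taxonomy_tree()].
#' @param n_present number of genera present (1 to number of genera).
#' @param skew log-normal sigma (>= 0).
#' @param seed integer seed.
#' @return Named numeric vector of class `community_profile` (genus
#'   taxon_id -> relative abundance, sums to 1).
#' @export
simulate_community <- function(tree, n_present, skew = 1.5, seed = 0L) {
  genera <- tax_genera(tree)
  assert_count(n_present, "n_present", min = 1L)
  assert_that(n_present <= length(genera),
              "n_present (%d) exceeds number of genera (%d)",
              n_present, length(genera))
  assert_that(is.numeric(skew) && length(skew) == 1L && skew >= 0,
              "`skew` must be a single non-negative number")
  with_seed(seed, {
    present <- sort(sample(genera, n_present))
    ab <- rlnorm(n_present, meanlog = 0, sdlog = skew)
    ab <- ab / sum(ab)
    structure(setNames(ab, present), class = "community_profile")
  })
}
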