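---
title: "Methods: simulating and comparing metaproteomic workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing metaproteomic workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A community metaproteome is only as good as the protein search database it
was identified against. Databases can be built from the same metagenome in
at least three ways — calling gene fragments directly on unassembled reads,
assembling reads into contigs first, or profiling the community's taxa and
downloading their complete reference proteomes — and the peptide data
themselves can come from shallow gel-based or deep gel-free fractionation.
Each combination yields a different set of identified proteins, a different
taxonomic structure, and a different functional profile from the *same*
sample. `mproteo` packages a desk-scale, fully synthetic re-creation of that
comparison so every step — database construction, two-round target–decoy
search, LCA and consensus-function annotation, comparative analytics — is
testable against ground truth.

## The simulated world

The generators state one world; the defaults are the package's model of the
regime the comparison lives in, chosen once and documented here.

* **Taxonomy** — six fixed ranks (domain > phylum > class > order > family >
  genus). Trees are built deterministically from per-rank branching factors,
  with children assigned contiguously so related genera share deep ancestors.
* **Reference proteomes** — `n_proteins_per_genus` records per genus
  (default 1200; 300 in `desk_config()`). A fraction of proteins (~25%)
  belong to homolog families of 2–4 members spread over at least two genera
  and derived from a common ancestral sequence by point substitutions at
  rate `1 - within_family_identity` (default identity 0.9). Families are
  what make protein inference and LCA annotation non-trivial: members share
  tryptic peptides and align to each other above the bit-score cutoff, so
  their groups annotate above genus rank. The store is deliberately much
  larger than what the reads sample: in the real regime the
  taxonomy-derived database dwarfs the read-derived one by an order of
  magnitude, and the defaults preserve that ordering structurally.
* **Community** — `n_present` genera with log-normal(0, `skew`) relative
  abundances (default skew 1.5), echoing the strong dominance structure of
  surface seawater communities. `skew = 0` degenerates to equal shares.
* **Reads** — drawn from the reverse-translated coding sequences (a fixed
  one-codon-per-residue table plus TAA stop, so six-frame recovery is exact
  and reverse translation is injective), genus chosen by abundance,
  protein uniformly within the genus — reads are DNA, so expression plays
  no role. Default 1500 reads of 150 nt with 1% substitution errors:
  deliberately low coverage (a few percent of the coding space), which is
  what makes assembly lossy and the read-derived database fragmentary.
  Qualities are constant except for a low-quality 3′ tail on 10% of reads,
  so the trimming stage has real work.
* **Peptidomes** — spectra are draws of tryptic peptides from proteins
  weighted by genus abundance × per-protein log-normal(0,1) expression;
  counts aggregate per peptide. The two labels differ in depth (20000
  gel-free vs 2000 gel-based spectra, the ~10× asymmetry of the two
  instruments' yields) and in a single scalar `detectability_bias`
  (default 0.5 for gel-based) that sharpens the sampling weight towards
  abundant proteins — an acknowledged stand-in: gel-based workflows are
  observed to yield fewer spectra concentrated on abundant proteins, and
  the scalar models that outcome without claiming a mechanism. 5% of spectra are noise peptides: random tryptic-looking
  sequences (length 8–20, C-terminal K/R) verified absent from every
  reference digest.

What a green test does **not** establish: the generator has no codon-usage
model, no indels or chimeras, no paired-end structure, no fragment-ion
spectra (a peptide with a count *is* the spectrum), and noise is uniform
rather than homology-biased. Conclusions about absolute identification
rates therefore do not transfer to real data; the package's claims are
set-level and directional.

## Database construction

* Gene calling is six-frame extraction of maximal stop-free stretches, no
  start codon required — reads are fragments, and keeping edge-truncated
  genes is the property that matters downstream. `min_orf_aa` defaults to
  40 residues: on 150 nt reads this keeps near-full-length coding
  stretches while suppressing most spurious stop-free runs in the five
  wrong frames. Non-ACGT characters translate as stops (conservative).
* Assembly is greedy exact suffix–prefix overlap (both strands, overlap ≥
  30 nt, deterministic tie-breaks). Contigs supported by a single read are
  dropped by default, mirroring real assemblers' minimum-contig behaviour;
  this flag is what creates the read-vs-assembly contrast at low coverage.
* Taxon detection counts marker k-mers (k = 21) on reads. The marker index
  uses the **full coding sequence** of 5 designated proteins per genus
  rather than a short peptide prefix: with hundreds rather than millions
  of reads, a small marker region is simply never sampled, and a
  desk-scale profiler must make the designated genes fully visible. One
  supporting read suffices in the pipeline default (`marker_min_hits = 1`)
  for the same reason. Because homolog families share coding k-mers,
  related absent genera are sometimes detected too — inflating the
  taxonomy-derived database exactly the way indiscriminate proteome
  download does in practice.
* Deduplication collapses identical sequences only (the lexicographically
  smallest id survives); sub-100% clustering is out of scope.

## Search engine

Exact peptide-sequence matching replaces spectrum scoring; a peptide's
spectrum count is the score currency. Digestion cleaves C-terminal to K/R
except before P, ≤ 2 missed cleavages, peptide length 6–40 (standard
practice; the source is silent). Decoys are pseudo-reversed per target:
residues are reversed within each tryptic segment while **every K, R and P
stays in place**. Pinning P as well as K/R is a deliberate strengthening of
plain segment reversal, which can drag a P to a segment start or split an
internal K–P pair and silently change the digest; with the full cleavage
pattern pinned, the decoy peptide-length multiset equals the target's by
construction.

Protein inference merges entries with identical matched-peptide sets and
absorbs entries whose set is a strict subset of another's; shared peptides
count for every containing group but are flagged non-distinct. The FDR
filter sorts groups by score (ties: more distinct peptides, then anchor id)
and accepts the largest prefix with decoys/targets ≤ 1%. The estimator is
decoys/targets, not 2d/(t+d). Note the running ratio itself is not
monotone in the prefix (each added target lowers it), so the invariant the
tests assert is *maximality*: no extension of the accepted prefix stays
within the threshold. Mixed target/decoy groups anchor on a target and
count as targets — a decoy colliding with a real peptide must not suppress
the protein that generated it.

Single-peptide groups pass an automated proxy for manual fragment-spectrum
inspection: peptide length ≥ 9 and spectrum count ≥ 2. The real criterion
(five consecutive b/y ions) needs spectra this package does not model; the
proxy keeps exactly the long, repeatedly-observed peptides whose ion series
would have been inspectable.

**Two-round search.** Round 1 reports the strictly FDR-validated result,
but the *restricted* database keeps every target entry with at least one
matched peptide, before FDR. Published two-round workflows force this
reading: their restricted databases are far larger than their first-round
validated lists, so restriction must use a looser pre-filter than
validation. Round 2 rebuilds decoys for the restricted database
(decoys always reflect the searched space) and repeats the full pipeline.
With exact matching, identification does not depend on database size, so at
desk scale the two-round gain is neutral-to-positive (the tests assert the
direction as ≥); in the real workflow the gain is driven by score-threshold
dynamics this engine intentionally does not model.

## Annotation

Accepted groups are aligned (anchor sequence, Smith–Waterman via
`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 11 / extend 1) against
the annotated reference store. Bit score = (0.267·S − ln 0.041)/ln 2; hits
must clear bit score > 80 — the cutoff is applied to the bit score (the
MEGAN-style, matrix-independent quantity) rather than the raw alignment
score, which the threshold is sometimes loosely attached to. Up to 20 hits are kept. A shared-5-mer
prefilter (≥ 2 shared words, top 200 candidates) keeps desk-scale runtime
sane; an exhaustive `prefilter = FALSE` mode is the oracle the tests
compare against. A hit clearing 80 bits needs a raw score near 200, which
in practice requires dozens of shared 5-mers, so the prefilter is
score-safe for everything the generator produces; adversarial alignments
with positive score but no 5-residue identity stretch could in principle
evade it.

The taxonomic annotation is the LCA of the hits' genera; the functional
annotation is the modal normalised name if its frequency strictly exceeds
0.8, else the group is flagged for manual review. Name normalisation
lowercases and iteratively strips trailing designators (subunit/chain/
isoform plus argument, greek letters, short numeric suffixes) so isoforms
and subunits vote as one function. The consensus tolerance is read as
modal-name frequency among hits; a string-similarity-between-names reading
was considered and rejected as ill-defined. The designator list is
configurable since naming conventions vary across reference stores.

## Comparative analytics

Distribution tables roll groups up to a rank (or to normalised function),
weight them by distinct-peptide count (or 1 per protein), compute
proportions on the annotated-at-rank total, and pool labels below 1% into
"Other" — pooling happens on unrounded proportions, display rounds to one
decimal with half-away-from-zero rounding (base `round()`'s banker's rule
would print 18.15 as 18.1, not the conventional 18.2). Mean ± SEM
summaries use the sample standard deviation (n−1) over √n; this definition
reproduces the published in-text statistics from their printed table rows
exactly. Venn partitions, complete-linkage/Euclidean clustering (via
`hclust`, raw peptide counts, no default scaling since the source states
none) and an order × function peptide-count matrix complete the analytics.
Ground-truth reporting (genus-rank Spearman against true abundances,
expressed-protein recovery, function recovery) closes the loop for the
acceptance criteria.

## Numerical and design choices

* All generators are pure functions of (arguments, seed); one master seed
  fans out to per-stage seeds by a fixed affine hash below 2^31.
* Tie-breaks everywhere are deterministic (score, then distinct peptides,
  then lexicographic id; overlap length, then id pair, then orientation).
* Coordinates are 0-based half-open; strands `+`/`−`; frames 0–2 per
  strand.
* Degenerate inputs (empty read sets, empty databases, empty hit lists,
  empty results) return empty containers, never errors; undefined metrics
  are `NA`.
* Desk-scale test configurations shrink the store, read count and spectra
  proportionally for runtime, preserving the database-size ordering and
  peptidome depth asymmetry; stochastic criteria run 20 fixed seeds and
  assert medians.

## Known limitations

Assembly ignores base qualities and cannot correct indels (none are
simulated). Full containment of one read inside another does not merge
them. The one reference store serves both taxonomic and functional
annotation, collapsing a distinction (nr vs Swiss-Prot) that matters on
real data. Identification counts, per-cell proportions and Venn counts
from full-scale ocean-survey datasets are not reproducible at this scale
and serve only as directional anchors.
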