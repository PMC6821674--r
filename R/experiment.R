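# Orchestration: configuration, the one-command experiment, and the
# simulated world that every stage consumes.

#' Experiment configuration
#'
#' All tunable parameters of the eight-metaproteome experiment with their
#' defaults. Thresholds follow the canonical workflow values: 1%
#' protein-level FDR, up to 20 alignment hits, bit score > 80, consensus
#' tolerance > 80%, sub-1% pooling into "Other". Simulation defaults state
#' a low-coverage desk-scale world: a reference store much larger than what
#' the reads sample (so the taxonomy-derived database dwarfs read-derived
#' ones) and a deep gel-free versus shallow gel-based peptidome (10x).
#'
#' @param seed integer master seed; per-stage seeds are fanned out
#'   deterministically from it.
#' @param ... overrides for any listed parameter.
#' @return Named list of class `experiment_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # community / reference store
    n_genera = 8L, branching = c(2L, 2L, 2L, 1L, 1L), n_present = 6L,
    n_proteins_per_genus = 1200L, n_families = NULL,
    within_family_identity = 0.9, community_skew = 1.5,
    # metagenome
    n_reads = 1500L, read_length = 150L, error_rate = 0.01,
    low_quality_tail_fraction = 0.1, trim_min_mean_quality = 20,
    trim_min_length = 50L,
    # database construction
    min_orf_aa = 40L, min_overlap = 30L, drop_singletons = TRUE,
    marker_min_hits = 1L,
    # peptidomes
    n_spectra_gel_free = 20000L, n_spectra_gel_based = 2000L,
    noise_fraction = 0.05, detectability_bias_gel_based = 0.5,
    # search
    max_missed_cleavages = 2L, min_len = 6L, max_len = 40L, fdr = 0.01,
    # annotation
    max_hits = 20L, min_bitscore = 80, tolerance = 0.8,
    # analytics
    other_threshold = 1.0,
    # optional per-stage seed override: when set, the two peptidome stages
    # use this seed base instead of the master fan-out, leaving the
    # metagenome-derived stages untouched (dependency isolation)
    peptidome_seed = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config parameter '%s'", unknown[1])
  cfg[names(dots)] <- dots
  if (!is.null(cfg$peptidome_seed))
    cfg$peptidome_seed <- as.integer(cfg$peptidome_seed)
  if (is.null(cfg$n_families))
    cfg$n_families <- (cfg$n_genera * cfg$n_proteins_per_genus) %/% 12L
  structure(cfg, class = "experiment_config")
}

#' Scaled-down configuration for tests and stochastic benchmarks
#'
#' Same stated world as [default_config()], shrunk proportionally (store,
#' read count, spectra) so that 20-seed loops finish in seconds-to-minutes
#' on one CPU. The size *ordering* of the constructed databases and the
#' depth asymmetry of the two peptidomes are preserved.
#'
#' @inheritParams default_config
#' @return An `experiment_config`.
#' @export
desk_config <- function(seed = 1L, ...) {
  default_config(seed = seed, n_genera = 6L, branching = c(2L, 2L, 2L, 1L, 1L),
                 n_present = 5L, n_proteins_per_genus = 300L,
                 n_reads = 300L, n_spectra_gel_free = 3000L,
                 n_spectra_gel_based = 600L, ...)
}

#' Simulate the complete synthetic world of one experiment
#'
#' Taxonomy, reference proteomes, community, reads (trimmed), the two
#' observed peptidomes and the genus marker index, all derived from the
#' per-stage seeds of `config$seed`.
#'
#' @param config an [default_config()].
#' @return List of class `sim_world`.
#' @export
simulate_world <- function(config) {
  tree <- generate_taxonomy(config$n_genera, config$branching,
                            stage_seed(config$seed, "taxonomy"))
  proteomes <- generate_reference_proteomes(
    tree, config$n_proteins_per_genus, config$n_families,
    config$within_family_identity, stage_seed(config$seed, "proteomes"))
  community <- simulate_community(tree, config$n_present,
                                  config$community_skew,
                                  stage_seed(config$seed, "community"))
  reads_raw <- simulate_reads(
    community, proteomes, config$read_length, config$n_reads,
    config$error_rate, stage_seed(config$seed, "reads"),
    config$low_quality_tail_fraction)
  reads <- trim_reads(reads_raw, config$trim_min_mean_quality,
                      config$trim_min_length)
  truth_index <- build_truth_index(proteomes, config$max_missed_cleavages,
                                   config$min_len, config$max_len)
  pep_base <- config$peptidome_seed %||% config$seed
  peptidomes <- list(
    gel_free = simulate_peptidome(
      community, proteomes, "gel_free", config$n_spectra_gel_free,
      config$max_missed_cleavages, config$min_len, config$max_len,
      config$noise_fraction, 0,
      stage_seed(pep_base, "peptidome_gel_free"), truth_index),
    gel_based = simulate_peptidome(
      community, proteomes, "gel_based", config$n_spectra_gel_based,
      config$max_missed_cleavages, config$min_len, config$max_len,
      config$noise_fraction, config$detectability_bias_gel_based,
      stage_seed(pep_base, "peptidome_gel_based"), truth_index))
  marker_index <- build_marker_index(proteomes)
  structure(list(config = config, tree = tree, proteomes = proteomes,
                 community = community, reads_raw = reads_raw,
                 reads = reads, peptidomes = peptidomes,
                 marker_index = marker_index, truth_index = truth_index),
            class = "sim_world")
}

#' Build the three round-1 databases from a simulated world
#'
#' @param world a [simulate_world()].
#' @return Named list of round-1 `protein_db`s: `NAM`, `AM`, `TAX`.
#' @export
build_round1_dbs <- function(world) {
  cfg <- world$config
  nam <- deduplicate(predict_genes_from_reads(world$reads, cfg$min_orf_aa))
  contigs <- assemble_reads(world$reads, cfg$min_overlap,
                            cfg$drop_singletons)
  am <- deduplicate(predict_genes_from_contigs(contigs, cfg$min_orf_aa))
  detected <- detect_taxa(world$reads, world$marker_index,
                          cfg$marker_min_hits)
  tax <- build_taxonomy_db(detected, world$proteomes)
  list(NAM = nam, AM = am, TAX = tax, contigs = contigs,
       detected = detected)
}

#' Run the complete eight-metaproteome experiment
#'
#' One command: simulate the world, build the three round-1 databases, run
#' the two-round searches and the combined-database searches, annotate all
#' eight metaproteomes, emit comparative tables, and write everything as
#' plain-text files under `out_dir` together with a manifest (seed,
#' parameter hash, per-file checksums). Reruns with the same config are
#' bit-identical.
#'
#' @param config an [default_config()].
#' @param out_dir output directory (created if missing).
#' @param write_files write the output tree (set `FALSE` to only return
#'   objects).
#' @return List of class `experiment_result` with `world`, `dbs`,
#'   `workflow`, `annotated` (8 `annotated_metaproteome`s), `analysis`,
#'   `manifest`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           write_files = !is.null(out_dir)) {
  world <- simulate_world(config)
  dbs <- build_round1_dbs(world)
  params <- digest_params(config$max_missed_cleavages, config$min_len,
                          config$max_len)
  wf <- run_workflow(world$peptidomes, dbs[c("NAM", "AM", "TAX")], params,
                     config$fdr)

  annotated <- lapply(wf$results, function(res)
    annotate_all(res, world$proteomes, world$tree, config$max_hits,
                 config$min_bitscore, config$tolerance))

  rates <- annotation_rate_profile(annotated)
  order_dists <- lapply(annotated, taxon_distribution, rank = "order",
                        other_threshold = config$other_threshold,
                        tree = world$tree)
  fun_dists <- lapply(annotated, function_distribution,
                      other_threshold = config$other_threshold)
  analysis <- list(rates = rates, order_distributions = order_dists,
                   function_distributions = fun_dists)

  manifest <- NULL
  if (write_files) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    p <- function(...) file.path(out_dir, ...)
    dir.create(p("dbs"), showWarnings = FALSE)
    dir.create(p("results"), showWarnings = FALSE)
    dir.create(p("annotations"), showWarnings = FALSE)
    dir.create(p("analysis"), showWarnings = FALSE)
    write_taxonomy_tsv(world$tree, p("taxonomy.tsv"))
    paths <- c(paths, p("taxonomy.tsv"), p("taxonomy.names.tsv"))
    write_reference_fasta(world$proteomes, p("reference_proteomes.fasta"))
    paths <- c(paths, p("reference_proteomes.fasta"))
    comm <- data.frame(taxon_id = names(world$community),
                       abundance = as.numeric(world$community))
    write.table(comm, p("community.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p("community.tsv"))
    write_fastq(world$reads, p("reads_trimmed.fastq"))
    paths <- c(paths, p("reads_trimmed.fastq"))
    for (lab in names(world$peptidomes)) {
      f <- p(sprintf("peptidome_%s.tsv", lab))
      write_peptidome_tsv(world$peptidomes[[lab]], f)
      paths <- c(paths, f)
    }
    for (dbn in c("NAM", "AM", "TAX")) {
      f <- p("dbs", sprintf("%s_round1.fasta", dbn))
      write_db_fasta(dbs[[dbn]], f)
      paths <- c(paths, f)
    }
    for (lab in names(wf$comb_dbs)) {
      f <- p("dbs", sprintf("Comb_%s.fasta", lab))
      write_db_fasta(wf$comb_dbs[[lab]], f)
      paths <- c(paths, f)
    }
    for (nm in names(wf$results)) {
      f <- p("results", sprintf("%s.tsv", nm))
      write_result_tsv(wf$results[[nm]], f)
      paths <- c(paths, f)
    }
    for (nm in names(annotated)) {
      f <- p("annotations", sprintf("%s.tsv", nm))
      write_annotations_tsv(annotated[[nm]], f)
      paths <- c(paths, f)
    }
    write.table(wf$summary, p("summary_two_round.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p("summary_two_round.tsv"))
    write.table(as.data.frame(rates), p("analysis", "annotation_rates.tsv"),
                sep = "\t", quote = FALSE)
    paths <- c(paths, p("analysis", "annotation_rates.tsv"))

    cfg_flat <- config
    cfg_flat$branching <- paste(config$branching, collapse = ",")
    manifest <- c(
      sprintf("package_version=%s",
              as.character(utils::packageVersion("mproteo"))),
      sprintf("seed=%d", config$seed),
      sprintf("parameter_hash=%s", config_hash(config)),
      sprintf("checksum %s %s", unname(tools::md5sum(paths)),
              basename(paths)))
    writeLines(manifest, p("manifest.txt"))
  }

  structure(list(world = world, dbs = dbs, workflow = wf,
                 annotated = annotated, analysis = analysis,
                 manifest = manifest),
            class = "experiment_result")
}

config_hash <- function(config) {
  flat <- paste(names(config),
                vapply(config, function(v) paste(format(v), collapse = ","),
                       character(1)),
                sep = "=", collapse = ";")
  # small deterministic FNV-1a style hash; avoids extra dependencies
  bytes <- utf8ToInt(flat)
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
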