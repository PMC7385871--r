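#' Experiment configuration
#'
#' Describes a complete synthetic mapping experiment: genome, population
#' structure, variant selection modes, simulation parameters and
#' replication. Defaults are desk-scale versions of the study conditions:
#' a 200-kb genome at the variant density of a well-sampled cattle
#' chromosome, three study populations of 20 diploids plus an outgroup
#' population supplying unphased random variants, an alternate allele
#' frequency threshold of 0.03 for the graph-type comparison, and ten
#' replicates of selection, simulation and mapping.
#'
#' @param genome_length genome size (bp)
#' @param pops named integer vector population -> diploids; the last
#'   population is treated as the outgroup for `random` graphs
#' @param n_variants panel size; default one variant per 80 bp
#' @param af_threshold frequency threshold for the graph-type comparison
#' @param thresholds frequency grid for threshold sweeps (0 to 0.1 by 0.01,
#'   then 0.1 to 1 by 0.1)
#' @param modes graph/reference types to run; subset of `"empty"`,
#'   `"threshold"`, `"targeted"`, `"across"`, `"pan"`, `"random"`,
#'   `"personalized"`, `"consensus"`, `"consensus_snp"`
#' @param sim a [sim_params()] object (its `n_pairs` is per cell)
#' @param map a [map_params()] object
#' @param target_pop population reads are simulated from (default first)
#' @param n_replicates replicates of selection + simulation + mapping
#' @param base_seed base seed; replicate r uses `base_seed + r`
#' @param outdir optional output directory for report files
#' @export
experiment_config <- function(genome_length = 200000L,
                              pops = c(A = 20L, B = 20L, C = 20L, OUT = 20L),
                              n_variants = NULL,
                              af_threshold = 0.03,
                              thresholds = c(seq(0, 0.09, by = 0.01),
                                             seq(0.1, 1, by = 0.1)),
                              modes = c("empty", "targeted", "across", "pan",
                                        "random", "personalized"),
                              sim = sim_params(n_pairs = 10000L),
                              map = map_params(),
                              target_pop = NULL,
                              n_replicates = 10L,
                              base_seed = 1L,
                              outdir = NULL) {
  if (is.null(n_variants)) n_variants <- as.integer(genome_length / 80)
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0,1]")
  thresholds <- sort(thresholds)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(target_pop)) target_pop <- names(pops)[1]
  structure(list(genome_length = as.integer(genome_length), pops = pops,
                 n_variants = as.integer(n_variants),
                 af_threshold = af_threshold, thresholds = thresholds,
                 modes = modes, sim = sim, map = map,
                 target_pop = target_pop,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed), outdir = outdir),
            class = "experiment_config")
}

# study populations = all but the outgroup (last) population
.study_pops <- function(config) {
  p <- names(config$pops)
  if (length(p) > 1) p[-length(p)] else p
}

# build the variant set for one mode/replicate; returns list(vset, hap_samples)
.mode_variant_set <- function(mode, panel, config, sim_sample, seed,
                              threshold = NULL) {
  study <- .study_pops(config)
  own <- config$target_pop
  others <- setdiff(study, own)
  thr <- if (is.null(threshold)) config$af_threshold else threshold
  switch(mode,
    empty = NULL,
    threshold = select_variants(panel, "threshold", pops = own,
                                threshold = thr,
                                exclude_samples = sim_sample, seed = seed),
    targeted = select_variants(panel, "count_matched", pops = study,
                               threshold = thr, exclude_samples = sim_sample,
                               seed = seed)[[own]],
    across = select_variants(panel, "count_matched", pops = study,
                             threshold = thr, exclude_samples = sim_sample,
                             seed = seed)[[others[1]]],
    pan = {
      cm <- select_variants(panel, "count_matched", pops = study,
                            threshold = thr, exclude_samples = sim_sample,
                            seed = seed)
      m <- length(cm[[1]]$ids)
      ps <- select_variants(panel, "pan", pops = study, threshold = thr,
                            exclude_samples = sim_sample, seed = seed)
      if (length(ps$ids) > m) {
        ps$ids <- sort(sample(ps$ids, m))
        ps$variants <- panel$variants[match(ps$ids, panel$variants$id), ]
      }
      ps
    },
    random = {
      cm <- select_variants(panel, "count_matched", pops = study,
                            threshold = thr, exclude_samples = sim_sample,
                            seed = seed)
      m <- length(cm[[1]]$ids)
      outg <- setdiff(names(config$pops), study)
      pool <- if (length(outg) > 0) {
        hap_pop <- rep(panel$samples$pop, each = 2)
        inr <- which(hap_pop %in% study)
        our <- which(hap_pop %in% outg)
        priv <- colSums(panel$haplotypes[our, , drop = FALSE]) > 0 &
          colSums(panel$haplotypes[inr, , drop = FALSE]) == 0
        panel$variants$id[priv]
      } else panel$variants$id
      m <- min(m, length(pool))
      select_variants(panel, "random_pool", n_target = m, pool = pool,
                      seed = seed)
    },
    personalized = select_variants(panel, "personalized", sample = sim_sample,
                                   seed = seed),
    stop("unknown mode: ", mode))
}

# run one cell: build reference structure, map the replicate's reads,
# classify; returns list(summary row fields, roc)
.run_cell <- function(mode, threshold, panel, ref, reads, config, sim_sample,
                      seed) {
  if (mode %in% c("consensus", "consensus_snp")) {
    cons <- build_consensus(ref, panel, pop = config$target_pop,
                            snp_only = mode == "consensus_snp")
    idx <- build_index(cons$consensus, k = config$map$k,
                       chain = chain_invert(cons$chain))
  } else {
    vset <- .mode_variant_set(mode, panel, config, sim_sample, seed,
                              threshold = threshold)
    graph <- build_graph(ref, vset)
    hap <- NULL
    if (!is.null(vset) && length(vset$ids) > 0 && mode != "random") {
      smpls <- if (mode == "personalized") sim_sample
               else setdiff(panel$samples$sample[
                 panel$samples$pop %in% .study_pops(config)], sim_sample)
      # cap the number of embedded haplotype walks for index construction
      if (length(smpls) > 30) smpls <- smpls[seq_len(30)]
      hap <- embed_haplotypes(graph, panel, smpls)
    }
    idx <- build_index(graph, k = config$map$k, hapindex = hap,
                       flank = config$sim$read_len)
  }
  al <- map_reads(reads, idx, config$map)
  ev <- classify_alignments(al, reads, k = config$sim$read_len)
  sm <- mapping_summary(al, ev)
  roc <- pseudo_roc(ev)
  list(summary = sm, roc = roc)
}

#' Run a full synthetic mapping experiment
#'
#' Generates the genome and panel once, then for every replicate simulates
#' reads from one target-population sample and maps them against every
#' configured reference structure (the simulated sample's private alleles
#' are excluded from all non-personalized graphs). Returns per-cell error
#' rates and summaries plus replicate-averaged aggregates. Fully
#' deterministic for a given configuration.
#'
#' @param config an [experiment_config()] object
#' @param quiet suppress progress messages
#' @return object of class `experiment_report`: list with `cells` (tibble),
#'   `aggregate` (tibble of means and standard errors), `roc` (list),
#'   `config`
#' @export
run_experiment <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  ref <- generate_reference(config$genome_length, seed = config$base_seed)
  panel <- simulate_population(ref, config$pops, config$n_variants,
                               seed = config$base_seed + 1L)
  sim_sample <- panel$samples$sample[panel$samples$pop == config$target_pop][1]
  ann <- attr(ref, "annotations")
  cells <- list()
  rocs <- list()
  for (r in seq_len(config$n_replicates)) {
    seed_r <- config$base_seed + r
    sim <- config$sim
    sim$seed <- seed_r
    haps <- lapply(1:2, function(h)
      extract_haplotype(ref, panel, sim_sample, h))
    reads <- simulate_reads(haps, sim)
    reads <- annotate_reads(reads, panel, ann)
    for (mode in config$modes) {
      thr_grid <- if (mode == "threshold") config$thresholds else NA_real_
      for (thr in thr_grid) {
        say("replicate %d: mode=%s%s", r, mode,
            if (!is.na(thr)) sprintf(" thr=%.2f", thr) else "")
        cell <- .run_cell(mode, if (is.na(thr)) NULL else thr, panel, ref,
                          reads, config, sim_sample, seed_r)
        sm <- cell$summary
        key <- sprintf("%s%s_r%d", mode,
                       if (!is.na(thr)) sprintf("_%.2f", thr) else "", r)
        cells[[key]] <- tibble::tibble(
          mode = mode, threshold = thr, replicate = r,
          error_rate = sm$error_rate, prop_perfect = sm$prop_perfect,
          prop_unique = sm$prop_unique, prop_unmapped = sm$prop_unmapped,
          err_prop_mq_gt10 = sm$err_prop_mq_gt10,
          err_prop_nonref = sm$err_prop_nonref)
        rocs[[key]] <- cell$roc
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  agg <- dplyr::summarise(
    dplyr::group_by(cells, mode, threshold),
    n = dplyr::n(),
    mean_error = mean(error_rate),
    se_error = stats::sd(error_rate) / sqrt(dplyr::n()),
    mean_perfect = mean(prop_perfect),
    mean_unique = mean(prop_unique),
    .groups = "drop")
  rep <- structure(list(cells = cells, aggregate = agg, roc = rocs,
                        config = config, sim_sample = sim_sample),
                   class = "experiment_report")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cells, file.path(config$outdir, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(agg, file.path(config$outdir, "aggregate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", nrow(x$cells), " cells\n", sep = "")
  print(as.data.frame(x$aggregate))
  invisible(x)
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; `sim` and
#' `map` sub-maps are passed to [sim_params()] and [map_params()].
#'
#' @param path YAML file
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$pops)) y$pops <- unlist(y$pops)
  if (!is.null(y$sim)) y$sim <- do.call(sim_params, y$sim)
  if (!is.null(y$map)) y$map <- do.call(map_params, y$map)
  do.call(experiment_config, y)
}

#' Run the reference-allele-bias experiment
#'
#' Builds a diploid individual from the target population, constructs a
#' graph containing a chosen fraction of its alternate alleles (the rest
#' stay graph-excluded, mirroring sites absent from an augmented reference),
#' simulates reads at the requested depth, maps them to both the graph and
#' the linear reference, genotypes by pileup and profiles the allelic ratio
#' at truly heterozygous sites by signed variant length.
#'
#' @param genome_length genome size (bp)
#' @param n_variants panel size
#' @param depth target sequencing depth
#' @param graph_fraction fraction of the sample's variants included in the
#'   graph
#' @param max_indel maximum indel length (bp)
#' @param seed integer seed
#' @param sim,map parameter objects; `n_pairs` is derived from `depth`
#' @return list with `profile_graph`, `profile_linear` (tibbles from
#'   [allelic_ratio_profile()]), `pileup_graph`, `pileup_linear`, `het`
#'   (heterozygous truth sites with `in_graph` flag)
#' @export
run_bias_experiment <- function(genome_length = 200000L, n_variants = NULL,
                                depth = 30, graph_fraction = 0.85,
                                max_indel = 40L, seed = 1L,
                                sim = sim_params(), map = map_params()) {
  if (is.null(n_variants)) n_variants <- as.integer(genome_length / 150)
  ref <- generate_reference(genome_length, seed = seed)
  panel <- simulate_population(ref, c(P = 25L), n_variants,
                               indel_fraction = 0.45, max_indel = max_indel,
                               seed = seed + 1L)
  smp <- panel$samples$sample[1]
  rows <- .hap_rows(panel, sample = smp)
  dos <- colSums(panel$haplotypes[rows, , drop = FALSE])
  het <- panel$variants[dos == 1L, , drop = FALSE]
  carried <- panel$variants$id[dos > 0L]
  set.seed(seed + 2L)
  in_graph_ids <- sort(sample(carried,
                              as.integer(round(graph_fraction *
                                               length(carried)))))
  vset <- select_variants(panel, "personalized", sample = smp)
  vset$ids <- in_graph_ids
  vset$variants <- panel$variants[match(in_graph_ids, panel$variants$id), ]
  graph <- build_graph(ref, vset)
  hap <- embed_haplotypes(graph, panel, smp)
  idx_g <- build_index(graph, k = map$k, hapindex = hap, flank = sim$read_len)
  idx_l <- build_index(ref, k = map$k)
  n_pairs <- as.integer(ceiling(depth * genome_length / (2 * sim$read_len)))
  sim$n_pairs <- n_pairs
  sim$seed <- seed + 3L
  haps <- lapply(1:2, function(h) extract_haplotype(ref, panel, smp, h))
  reads <- simulate_reads(haps, sim)
  al_g <- map_reads(reads, idx_g, map)
  al_l <- map_reads(reads, idx_l, map)
  pu_g <- pileup_and_call(al_g, idx_g, ref, het)
  pu_l <- pileup_and_call(al_l, idx_l, ref, het)
  het$in_graph <- het$id %in% in_graph_ids
  list(profile_graph = allelic_ratio_profile(pu_g, het, het$in_graph),
       profile_linear = allelic_ratio_profile(pu_l, het, het$in_graph),
       pileup_graph = pu_g, pileup_linear = pu_l, het = het)
}

#' Run the genotype-recovery experiment
#'
#' Simulates error-free reads from one sample, maps them to a personalized
#' graph, genotypes all panel sites by pileup and compares calls with the
#' sample's truth genotypes, together with concordance metrics on an
#' array-like subset.
#'
#' @param genome_length genome size (bp)
#' @param n_variants panel size
#' @param depth target depth
#' @param seed integer seed
#' @return list with `calls`, `truth`, `concordance`, `n_compared`,
#'   `n_mismatched` (restricted to sites with DP above the depth filter)
#' @export
run_genotyping_experiment <- function(genome_length = 100000L,
                                      n_variants = 600L, depth = 25,
                                      seed = 1L) {
  ref <- generate_reference(genome_length, seed = seed)
  panel <- simulate_population(ref, c(P = 20L), n_variants, seed = seed + 1L)
  smp <- panel$samples$sample[1]
  vset <- select_variants(panel, "personalized", sample = smp)
  graph <- build_graph(ref, vset)
  hap <- embed_haplotypes(graph, panel, smp)
  map <- map_params()
  idx <- build_index(graph, k = map$k, hapindex = hap)
  sim <- sim_params(sub_rate = 0, indel_rate = 0,
                    n_pairs = as.integer(ceiling(depth * genome_length / 300)),
                    seed = seed + 2L)
  haps <- lapply(1:2, function(h) extract_haplotype(ref, panel, smp, h))
  reads <- simulate_reads(haps, sim)
  calls <- pileup_and_call(map_reads(reads, idx, map), idx, ref,
                           panel$variants,
                           filters = list(min_QD = 2, min_MQ = 20,
                                          min_DP = 19))
  truth <- emulate_truth_sets(panel, smp,
                              n_array_sites = min(200L, n_variants),
                              seed = seed + 3L)
  # recovery is assessed on confidently called sites: depth >= 20 and the
  # quality filters passed (sites inside recent duplications lose cross-
  # mapping reads and are flagged by the filters, as on real genomes)
  deep <- calls$DP >= 20 & calls$filter_status == "pass"
  tg <- truth$genotypes$gt[match(calls$id, truth$genotypes$id)]
  conc <- concordance_metrics(calls, truth)
  list(calls = calls, truth = truth, concordance = conc,
       n_compared = sum(deep),
       n_mismatched = sum(calls$genotype[deep] != tg[deep]),
       n_flagged = sum(calls$DP >= 20 & calls$filter_status != "pass"))
}
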