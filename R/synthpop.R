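#' Repeat structure specification for synthetic references
#'
#' Real mammalian chromosomes are roughly half repetitive, and mapping errors
#' concentrate in recently duplicated (low-divergence) elements. The synthetic
#' reference therefore carries interspersed repeat families whose copies are
#' mutated away from a family consensus by a per-copy divergence drawn from a
#' uniform spectrum (young, nearly identical copies through old, diverged
#' ones), occasional tandem double copies, and short microsatellite runs.
#'
#' @param fraction fraction of the genome covered by short interspersed
#'   elements
#' @param unit_len short-element length (bp)
#' @param n_families number of short-element families
#' @param divergence length-2 numeric, lower/upper per-copy divergence
#'   (shared by both element classes)
#' @param tandem_prob probability that a short-element copy is placed as a
#'   tandem pair
#' @param segdup_fraction fraction of the genome covered by segmental
#'   duplications: existing genomic segments re-copied elsewhere with low
#'   divergence. Their length exceeds the sequencing fragment, so read pairs
#'   falling inside cannot be rescued by a uniquely mapping mate, and their
#'   youngest (least diverged) copies are the main source of mapping
#'   ambiguity, as on real genomes
#' @param segdup_len length-2 numeric, min/max duplication length (bp)
#' @param segdup_div length-2 numeric, min/max divergence of a duplicated
#'   copy from its source segment
#' @param low_complexity fraction of the genome covered by microsatellite runs
#' @param run_len microsatellite run length (bp)
#' @return a list with class `repeat_spec`
#' @export
repeat_spec <- function(fraction = 0.18, unit_len = 300L, n_families = 8L,
                        divergence = c(0.01, 0.08), tandem_prob = 0.15,
                        segdup_fraction = 0.08, segdup_len = c(1500, 5000),
                        segdup_div = c(0, 0.02),
                        low_complexity = 0.02, run_len = 60L) {
  structure(list(fraction = fraction, unit_len = as.integer(unit_len),
                 n_families = as.integer(n_families), divergence = divergence,
                 tandem_prob = tandem_prob,
                 segdup_fraction = segdup_fraction,
                 segdup_len = as.numeric(segdup_len),
                 segdup_div = as.numeric(segdup_div),
                 low_complexity = low_complexity,
                 run_len = as.integer(run_len)),
            class = "repeat_spec")
}

.rand_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Generate a pseudo-random reference sequence
#'
#' Draws an i.i.d. ACGT backbone at the requested GC content, then (unless
#' `repeats = NULL`) overlays interspersed repeat-family copies and
#' low-complexity runs as described in [repeat_spec()]. The locations of
#' repetitive material are recorded as a BED-style annotation table attached
#' as the `annotations` attribute (labels `"repeat"` and `"low_complexity"`).
#'
#' @param length sequence length in bp (positive)
#' @param gc_content target GC fraction in \[0, 1\]
#' @param seed integer seed; the same inputs and seed reproduce the identical
#'   sequence
#' @param name sequence name
#' @param repeats a [repeat_spec()], or `NULL` for a plain i.i.d. sequence
#' @return an object of class `reference_seq`: list with `name`, `sequence`,
#'   `length`
#' @export
generate_reference <- function(length, gc_content = 0.42, seed = NULL,
                               name = "chrS", repeats = repeat_spec()) {
  length <- as.integer(length)
  if (is.na(length) || length < 1) stop("length must be a positive integer")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  seq <- .rand_dna(length, gc_content)
  ann <- data.frame(start = integer(0), end = integer(0),
                    label = character(0))
  if (!is.null(repeats) && length >= 4L * repeats$unit_len) {
    rs <- repeats
    fam <- vapply(seq_len(rs$n_families),
                  function(i) .rand_dna(rs$unit_len, gc_content), "")
    n_copies <- max(0L, as.integer(round(rs$fraction * length / rs$unit_len)))
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    placed <- 0L
    while (placed < n_copies) {
      f <- sample.int(rs$n_families, 1)
      div <- stats::runif(1, rs$divergence[1], rs$divergence[2])
      copy <- .mutate_seq(fam[f], div)
      tandem <- stats::runif(1) < rs$tandem_prob && placed + 1L < n_copies
      unit <- if (tandem) paste0(copy, .mutate_seq(fam[f], div)) else copy
      ulen <- nchar(unit)
      p <- sample.int(length - ulen, 1)  # 1-based start
      ch[p:(p + ulen - 1)] <- strsplit(unit, "", fixed = TRUE)[[1]]
      ann <- rbind(ann, data.frame(start = p - 1L, end = p - 1L + ulen,
                                   label = "repeat"))
      placed <- placed + if (tandem) 2L else 1L
    }
    # segmental duplications: re-copy existing segments at low divergence,
    # creating fragment-scale near-identical locus pairs
    dup_bp <- 0
    target_bp <- rs$segdup_fraction * length
    while (dup_bp < target_bp && length > 4 * rs$segdup_len[2]) {
      dl <- as.integer(round(stats::runif(1, rs$segdup_len[1],
                                          rs$segdup_len[2])))
      src <- sample.int(length - dl, 1)
      unit <- .mutate_seq(paste(ch[src:(src + dl - 1)], collapse = ""),
                          stats::runif(1, rs$segdup_div[1], rs$segdup_div[2]))
      p <- sample.int(length - dl, 1)
      ch[p:(p + dl - 1)] <- strsplit(unit, "", fixed = TRUE)[[1]]
      ann <- rbind(ann,
                   data.frame(start = c(src - 1L, p - 1L),
                              end = c(src - 1L + dl, p - 1L + dl),
                              label = "repeat"))
      dup_bp <- dup_bp + dl
    }
    n_runs <- as.integer(round(rs$low_complexity * length / rs$run_len))
    units <- c("A", "AT", "CA", "AG", "T")
    for (i in seq_len(n_runs)) {
      u <- sample(units, 1)
      run <- strsplit(strrep(u, ceiling(rs$run_len / nchar(u))), "",
                      fixed = TRUE)[[1]][seq_len(rs$run_len)]
      p <- sample.int(length - rs$run_len, 1)
      ch[p:(p + rs$run_len - 1)] <- run
      ann <- rbind(ann, data.frame(start = p - 1L, end = p - 1L + rs$run_len,
                                   label = "low_complexity"))
    }
    seq <- paste(ch, collapse = "")
  }
  structure(list(name = name, sequence = seq, length = length),
            class = "reference_seq", annotations = ann)
}

#' @export
print.reference_seq <- function(x, ...) {
  cat("<reference_seq> ", x$name, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

# default site-frequency-class weights; the singleton proportion follows the
# cattle estimate (14%), the remainder spreads over frequency classes so that
# roughly a third of segregating sites are below 5% frequency, as observed in
# the bovine populations the generator emulates.
.default_sfs <- c(singleton = 0.14, rare = 0.24, f05_10 = 0.12,
                  f10_20 = 0.14, f20_50 = 0.22, common = 0.14)
.sfs_bounds <- data.frame(
  class = c("singleton", "rare", "f05_10", "f10_20", "f20_50", "common"),
  lo = c(NA, 0.01, 0.05, 0.10, 0.20, 0.50),
  hi = c(NA, 0.05, 0.10, 0.20, 0.50, 0.999))

#' Simulate a multi-population phased variant panel
#'
#' Places `n_variants` biallelic SNPs and short indels at non-overlapping
#' positions on the reference, assigns each variant a frequency class per
#' population from a controllable site-frequency spectrum, and draws phased
#' diploid haplotypes matching the target allele counts. A fraction
#' `shared_fraction` of variants belongs to a pool shared by all populations
#' (with population-specific frequencies); the rest are private to one
#' population.
#'
#' @param ref a [generate_reference()] result (or compatible list)
#' @param pops named integer vector: population label -> number of diploids
#' @param n_variants number of variants to place
#' @param sfs named numeric weights over the frequency classes
#'   `singleton`, `rare` (1-5 percent), `f05_10`, `f10_20`, `f20_50`,
#'   `common` (above 50 percent); normalised internally
#' @param indel_fraction fraction of variants that are indels (split evenly
#'   between insertions and deletions)
#' @param max_indel maximum indel length in bp (< 50)
#' @param shared_fraction fraction of variants drawn from the shared pool
#' @param seed integer seed
#' @return an object of class `variant_panel` with elements `variants`
#'   (tibble: id, chrom, pos, ref, alt, vclass, length_delta), `samples`
#'   (tibble: sample, pop), `haplotypes` (0/1 integer matrix, two rows per
#'   sample), and `af` (population x variant matrix of alternate allele
#'   frequencies)
#' @export
simulate_population <- function(ref, pops, n_variants, sfs = .default_sfs,
                                indel_fraction = 0.11, max_indel = 40L,
                                shared_fraction = 0.6, seed = NULL) {
  stopifnot(n_variants >= 0, indel_fraction >= 0, indel_fraction <= 1,
            shared_fraction >= 0, shared_fraction <= 1, max_indel < 50)
  if (!is.null(seed)) set.seed(seed)
  pops <- stats::setNames(as.integer(pops), names(pops))
  if (is.null(names(pops)) || any(names(pops) == ""))
    stop("pops must be a named vector of diploid counts")
  w <- sfs[.sfs_bounds$class]
  if (anyNA(w)) stop("sfs must name all frequency classes")
  w <- w / sum(w)
  L <- ref$length
  samples <- tibble::tibble(
    sample = unlist(lapply(names(pops), function(p)
      sprintf("%s_s%02d", p, seq_len(pops[[p]])))),
    pop = rep(names(pops), pops))
  hap_names <- paste0(rep(samples$sample, each = 2), "_h", 1:2)
  hap_pop <- rep(samples$pop, each = 2)

  variants <- tibble::tibble(id = character(0), chrom = character(0),
                             pos = integer(0), ref = character(0),
                             alt = character(0), vclass = character(0),
                             length_delta = integer(0))
  H <- matrix(0L, nrow = length(hap_names), ncol = 0,
              dimnames = list(hap_names, NULL))
  if (n_variants > 0) {
    # oversample candidate sites, then greedily keep non-overlapping ones
    n_try <- min(as.integer(L / 2), n_variants * 4L)
    pos <- sort(sample.int(L - max_indel - 2L, n_try)) # 1-based draw
    pos <- as.integer(pos)                             # use as 0-based offset
    cls <- sample(c("SNP", "INS", "DEL"), n_try, replace = TRUE,
                  prob = c(1 - indel_fraction, indel_fraction / 2,
                           indel_fraction / 2))
    ilen <- ifelse(cls == "SNP", 0L, sample.int(max_indel, n_try, replace = TRUE))
    span <- ifelse(cls == "DEL", 1L + ilen, 1L)
    keep <- logical(n_try); prev_end <- -1L
    for (i in seq_len(n_try)) {
      if (pos[i] > prev_end) { keep[i] <- TRUE; prev_end <- pos[i] + span[i] }
    }
    idx <- which(keep)
    if (length(idx) < n_variants)
      stop("n_variants exceeds the number of placeable non-overlapping sites")
    idx <- sort(sample(idx, n_variants))
    pos <- pos[idx]; cls <- cls[idx]; ilen <- as.integer(ilen[idx])
    bases <- c("A", "C", "G", "T")
    refb <- substring(ref$sequence, pos + 1L, pos + ifelse(cls == "DEL",
                                                           1L + ilen, 1L))
    alt <- character(n_variants)
    for (i in seq_len(n_variants)) {
      if (cls[i] == "SNP") {
        alt[i] <- sample(setdiff(bases, refb[i]), 1)
      } else if (cls[i] == "INS") {
        alt[i] <- paste0(refb[i], .rand_dna(ilen[i], 0.42))
      } else {
        alt[i] <- substr(refb[i], 1, 1)
      }
    }
    delta <- nchar(alt) - nchar(refb)
    variants <- tibble::tibble(
      id = sprintf("v%05d", seq_len(n_variants)), chrom = ref$name,
      pos = pos, ref = refb, alt = alt, vclass = cls,
      length_delta = as.integer(delta))

    # frequency assignment
    shared <- stats::runif(n_variants) < shared_fraction
    home <- sample(names(pops), n_variants, replace = TRUE)
    H <- matrix(0L, nrow = length(hap_names), ncol = n_variants,
                dimnames = list(hap_names, variants$id))
    for (p in names(pops)) {
      rows <- which(hap_pop == p)
      n_h <- length(rows)
      if (n_h < 2) stop("each population needs at least one diploid")
      seg <- which(shared | home == p)
      cl <- sample(.sfs_bounds$class, length(seg), replace = TRUE, prob = w)
      for (k in seq_along(seg)) {
        b <- .sfs_bounds[.sfs_bounds$class == cl[k], ]
        cnt <- if (cl[k] == "singleton") 1L else {
          f <- stats::runif(1, b$lo, b$hi)
          min(n_h - 1L, max(2L, as.integer(round(f * n_h))))
        }
        H[rows[sample.int(n_h, cnt)], seg[k]] <- 1L
      }
    }
  }
  af <- .panel_af(H, hap_pop, names(pops))
  structure(list(variants = variants, samples = samples, haplotypes = H,
                 af = af, ref_name = ref$name),
            class = "variant_panel")
}

.panel_af <- function(H, hap_pop, pops) {
  af <- matrix(0, nrow = length(pops), ncol = ncol(H),
               dimnames = list(pops, colnames(H)))
  for (p in pops) af[p, ] <- colMeans(H[hap_pop == p, , drop = FALSE])
  af
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("<variant_panel> ", nrow(x$variants), " variants, ",
      nrow(x$samples), " samples in ",
      length(unique(x$samples$pop)), " population(s)\n", sep = "")
  invisible(x)
}

#' Recompute per-population alternate allele frequencies from haplotypes
#' @param panel a [simulate_population()] panel
#' @return population x variant matrix
#' @export
panel_af <- function(panel) {
  hap_pop <- rep(panel$samples$pop, each = 2)
  .panel_af(panel$haplotypes, hap_pop, unique(panel$samples$pop))
}

# haplotype row indices of a population or sample
.hap_rows <- function(panel, pop = NULL, sample = NULL) {
  hp <- rep(panel$samples$pop, each = 2)
  hs <- rep(panel$samples$sample, each = 2)
  if (!is.null(sample)) which(hs %in% sample) else which(hp %in% pop)
}

#' Windowed nucleotide diversity
#'
#' Per-site nucleotide diversity is `2 j (n - j) / (n (n - 1))` with `j` the
#' alternate allele count and `n` the number of haplotypes in the population;
#' window values are the sum of per-site diversity over sites in each
#' non-overlapping window divided by the window length.
#'
#' @param panel a [simulate_population()] panel
#' @param pop population label
#' @param window window size in bp
#' @return tibble with `start` (0-based window start) and `pi`
#' @export
windowed_pi <- function(panel, pop, window = 10000L) {
  if (window < 1) stop("window must be >= 1")
  if (!pop %in% panel$samples$pop) stop("unknown population: ", pop)
  rows <- .hap_rows(panel, pop = pop)
  n <- length(rows)
  if (n < 2) stop("need at least 2 haplotypes to compute diversity")
  if (ncol(panel$haplotypes) == 0)
    return(tibble::tibble(start = integer(0), pi = numeric(0)))
  j <- colSums(panel$haplotypes[rows, , drop = FALSE])
  site_pi <- 2 * j * (n - j) / (n * (n - 1))
  win <- as.integer(panel$variants$pos %/% window) * as.integer(window)
  agg <- tapply(site_pi, win, sum)
  tibble::tibble(start = as.integer(names(agg)),
                 pi = as.numeric(agg) / window)
}

#' Derive truth genotypes and a microarray-like site subset for one sample
#'
#' @param panel a [simulate_population()] panel
#' @param sample sample id
#' @param n_array_sites number of panel sites in the array-like subset
#' @param seed integer seed for the subset draw
#' @return object of class `truth_genotypes`: list with `sample`, `genotypes`
#'   (tibble id, pos, gt in 0/0, 0/1, 1/1) and `array_subset` (variant ids)
#' @export
emulate_truth_sets <- function(panel, sample, n_array_sites, seed = NULL) {
  if (!sample %in% panel$samples$sample) stop("unknown sample: ", sample)
  if (n_array_sites > nrow(panel$variants))
    stop("n_array_sites exceeds the number of panel variants")
  if (!is.null(seed)) set.seed(seed)
  rows <- .hap_rows(panel, sample = sample)
  h <- panel$haplotypes[rows, , drop = FALSE]
  dos <- colSums(h)
  gt <- c("0/0", "0/1", "1/1")[dos + 1L]
  sub <- sample(panel$variants$id, n_array_sites)
  structure(list(sample = sample,
                 genotypes = tibble::tibble(id = panel$variants$id,
                                            pos = panel$variants$pos,
                                            gt = gt),
                 array_subset = sub),
            class = "truth_genotypes")
}
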