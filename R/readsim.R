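#' Extract one phased haplotype sequence with its coordinate map
#'
#' Applies the sample's alleles on the requested haplotype to the reference
#' in coordinate order and records every indel-induced shift in a
#' [chain_map()] whose forward direction maps haplotype to reference
#' coordinates.
#'
#' @param ref a [generate_reference()] reference
#' @param panel a [simulate_population()] panel
#' @param sample sample id
#' @param hap haplotype index, 1 or 2
#' @return object of class `haplotype_seq`: list with `sample`, `hap`,
#'   `sequence`, `coord_map` (haplotype -> reference chain) and `carried`
#'   (ids of alternate alleles applied)
#' @export
extract_haplotype <- function(ref, panel, sample, hap = 1L) {
  if (!sample %in% panel$samples$sample) stop("unknown sample: ", sample)
  stopifnot(hap %in% 1:2)
  rows <- .hap_rows(panel, sample = sample)
  carried <- if (ncol(panel$haplotypes) > 0)
    colnames(panel$haplotypes)[panel$haplotypes[rows[hap], ] == 1L]
  else character(0)
  v <- panel$variants[panel$variants$id %in% carried, , drop = FALSE]
  ap <- apply_variants(ref$sequence, v)
  structure(list(sample = sample, hap = as.integer(hap),
                 sequence = ap$sequence,
                 coord_map = chain_invert(ap$chain),  # hap -> ref
                 carried = carried),
            class = "haplotype_seq")
}

# leftmost / rightmost mappable reference coordinates of a haplotype interval
.lift_interval <- function(coord_map, start, end) {
  s <- liftover(coord_map, start, "forward", nearest = TRUE)
  e <- liftover(coord_map, end - 1L, "forward", nearest = TRUE)
  c(s, e + 1L)
}

#' Read simulation parameters
#'
#' Defaults follow common short-read simulation settings: 150 bp reads,
#' fragment length 500 +/- 50, substitution error rate 0.01 per base and
#' indel error rate 0.002 per base.
#'
#' @param read_len read length (bp)
#' @param n_pairs number of fragments (pairs in paired mode, reads otherwise)
#' @param frag_mean,frag_sd fragment length distribution (bp)
#' @param sub_rate per-base substitution error rate in \[0, 1)
#' @param indel_rate per-base indel error rate in \[0, 1); errors are 1 bp,
#'   insertion and deletion equiprobable
#' @param paired simulate read pairs
#' @param seed integer seed
#' @export
sim_params <- function(read_len = 150L, n_pairs = 1000L, frag_mean = 500,
                       frag_sd = 50, sub_rate = 0.01, indel_rate = 0.002,
                       paired = TRUE, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            read_len >= 1, frag_mean >= read_len)
  structure(list(read_len = as.integer(read_len), n_pairs = as.integer(n_pairs),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 paired = isTRUE(paired), seed = seed),
            class = "sim_params")
}

.revcomp <- function(x) cpp_revcomp(x)

# inject substitution and 1-bp indel errors into a vector of read sequences;
# returns list(seq, n_sub, n_indel)
.inject_errors <- function(seqs, read_len, sub_rate, indel_rate) {
  n <- length(seqs)
  n_sub <- stats::rbinom(n, read_len, sub_rate)
  n_ind <- stats::rbinom(n, read_len, indel_rate)
  bases <- c("A", "C", "G", "T")
  todo <- which(n_sub + n_ind > 0)
  for (i in todo) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (n_sub[i] > 0) {
      pos <- sample.int(length(ch), min(n_sub[i], length(ch)))
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    for (e in seq_len(n_ind[i])) {
      p <- sample.int(length(ch), 1)
      if (stats::runif(1) < 0.5) {
        ch <- append(ch, sample(bases, 1), after = p)   # insertion error
      } else {
        ch <- ch[-p]                                     # deletion error
      }
    }
    # re-trim / pad to the nominal read length
    if (length(ch) > read_len) ch <- ch[seq_len(read_len)]
    while (length(ch) < read_len) ch <- c(ch, sample(bases, 1))
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seq = seqs, n_sub = n_sub, n_indel = n_ind)
}

#' Simulate error-bearing reads from haplotype sequences
#'
#' Fragments are drawn uniformly along each haplotype (equal fragment counts
#' per haplotype) with lengths Normal(`frag_mean`, `frag_sd`) truncated at
#' `read_len`; in paired mode mate 1 is taken from the 5' fragment end and
#' mate 2 reverse-complemented from the 3' end, with the fragment orientation
#' flipped for a random half of the fragments. Truth coordinates (leftmost
#' reference coordinate of the error-free source segment) are recorded via
#' the haplotype coordinate maps before substitution and 1-bp indel errors
#' are injected.
#'
#' @param haps list of [extract_haplotype()] haplotypes
#' @param params a [sim_params()] object
#' @return tibble of simulated reads: id, mate, seq, sample, hap, hap_start,
#'   frag_len, strand, true_ref_start, true_ref_end, n_sub_err, n_indel_err,
#'   contains_nonref (NA until [annotate_reads()])
#' @export
simulate_reads <- function(haps, params = sim_params()) {
  if (inherits(haps, "haplotype_seq")) haps <- list(haps)
  if (!is.null(params$seed)) set.seed(params$seed)
  rl <- params$read_len
  out <- list()
  n_each <- ceiling(params$n_pairs / length(haps))
  for (hi in seq_along(haps)) {
    h <- haps[[hi]]
    hl <- nchar(h$sequence)
    if (hl < params$frag_mean + 4 * params$frag_sd)
      stop("haplotype shorter than frag_mean + 4*frag_sd")
    n <- n_each
    fl <- pmin(hl, pmax(rl, as.integer(round(
      stats::rnorm(n, params$frag_mean, params$frag_sd)))))
    st <- as.integer(floor(stats::runif(n, 0, hl - fl + 1)))  # 0-based
    flip <- stats::runif(n) < 0.5
    pre <- sprintf("%s_h%d_f%06d", h$sample, h$hap, seq_len(n))
    m1_start <- ifelse(flip, st + fl - rl, st)
    m2_start <- ifelse(flip, st, st + fl - rl)
    m1_fwd <- !flip
    m1_seq <- substring(h$sequence, m1_start + 1L, m1_start + rl)
    m2_seq <- substring(h$sequence, m2_start + 1L, m2_start + rl)
    m1_seq[!m1_fwd] <- .revcomp(m1_seq[!m1_fwd])
    m2_seq[m1_fwd] <- .revcomp(m2_seq[m1_fwd])
    tr <- function(s) {
      a <- liftover(h$coord_map, s, "forward", nearest = TRUE)
      b <- liftover(h$coord_map, s + rl - 1L, "forward", nearest = TRUE)
      cbind(a, b + 1L)
    }
    t1 <- tr(m1_start); t2 <- tr(m2_start)
    if (params$paired) {
      tb <- tibble::tibble(
        id = rep(pre, 2),
        mate = rep(1:2, each = n),
        seq = c(m1_seq, m2_seq),
        sample = h$sample, hap = h$hap,
        hap_start = c(m1_start, m2_start),
        frag_len = rep(fl, 2),
        strand = c(ifelse(m1_fwd, "+", "-"), ifelse(m1_fwd, "-", "+")),
        true_ref_start = c(t1[, 1], t2[, 1]),
        true_ref_end = c(t1[, 2], t2[, 2]))
    } else {
      tb <- tibble::tibble(
        id = pre, mate = 0L, seq = m1_seq, sample = h$sample, hap = h$hap,
        hap_start = m1_start, frag_len = fl,
        strand = ifelse(m1_fwd, "+", "-"),
        true_ref_start = t1[, 1], true_ref_end = t1[, 2])
    }
    out[[hi]] <- tb
  }
  reads <- dplyr::bind_rows(out)
  err <- .inject_errors(reads$seq, rl, params$sub_rate, params$indel_rate)
  reads$seq <- err$seq
  reads$n_sub_err <- err$n_sub
  reads$n_indel_err <- err$n_indel
  reads$contains_nonref <- NA
  reads$id <- paste0(reads$id, ifelse(reads$mate > 0,
                                      paste0("/", reads$mate), ""))
  reads
}

#' Annotate reads with non-reference content and region labels
#'
#' `contains_nonref` is `TRUE` when the source haplotype carries at least one
#' alternate allele whose reference span overlaps the read's true reference
#' interval. Region labels are assigned from the interval(s) containing the
#' true-origin midpoint.
#'
#' @param reads a [simulate_reads()] tibble
#' @param panel the panel the source haplotypes come from
#' @param annotations optional BED-like data frame (`start`, `end`, `label`,
#'   0-based half-open), e.g. the `annotations` attribute of a synthetic
#'   reference
#' @return the reads tibble with `contains_nonref` and `region_labels` filled
#' @export
annotate_reads <- function(reads, panel, annotations = NULL) {
  v <- panel$variants
  hap_key <- paste0(reads$sample, "_h", reads$hap)
  reads$contains_nonref <- FALSE
  if (nrow(v) > 0) {
    vr <- IRanges::IRanges(start = v$pos + 1L, end = v$pos + nchar(v$ref))
    for (hk in unique(hap_key)) {
      carried <- panel$haplotypes[hk, ] == 1L
      if (!any(carried)) next
      sel <- which(hap_key == hk)
      rr <- IRanges::IRanges(start = reads$true_ref_start[sel] + 1L,
                             end = reads$true_ref_end[sel])
      ov <- IRanges::countOverlaps(rr, vr[carried])
      reads$contains_nonref[sel] <- ov > 0
    }
  }
  mid <- (reads$true_ref_start + reads$true_ref_end) %/% 2L
  labels <- rep("", nrow(reads))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ar <- IRanges::IRanges(start = annotations$start + 1L,
                           end = annotations$end)
    mr <- IRanges::IRanges(start = mid + 1L, width = 1L)
    hits <- IRanges::findOverlaps(mr, ar)
    if (length(hits) > 0) {
      lab <- tapply(annotations$label[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) paste(sort(unique(x)), collapse = ","))
      labels[as.integer(names(lab))] <- as.character(lab)
    }
  }
  reads$region_labels <- labels
  reads
}
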