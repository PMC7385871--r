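#' Mapping parameters
#'
#' Scoring follows common seed-and-extend defaults (match +1, mismatch -4,
#' gap open -6, gap extend -1) with mapping quality
#' `MQ = min(60, 6 * (best - second_best))` and `MQ = 0` on exact ties. The
#' extension band (12 bp) bounds the largest indel the aligner can place as a
#' gap; longer indels are soft-clipped, as linear aligners tend to do.
#'
#' @param k seed length (bp, >= 8)
#' @param stride seed sampling stride along the read
#' @param occ_cap ignore seeds occurring more often than this
#' @param max_cand extend at most this many candidate loci per read
#' @param match,mismatch,gap_open,gap_ext alignment scores (positive values)
#' @param band extension band half-width (bp)
#' @param frag_mean,frag_sd fragment-length prior for paired scoring
#' @param dedup_slop candidates surjecting within this many bp are one locus
#' @param unpaired_pen score penalty for improper pairs
#' @export
map_params <- function(k = 21L, stride = 10L, occ_cap = 255L, max_cand = 8L,
                       match = 1L, mismatch = 4L, gap_open = 6L, gap_ext = 1L,
                       band = 12L, frag_mean = 500, frag_sd = 50,
                       dedup_slop = 50L, unpaired_pen = 40L) {
  if (k < 8) stop("seed length k must be >= 8")
  structure(as.list(environment()), class = "map_params")
}

.new_index <- function(kind, contigs, names, chains, offsets, ref_len, k,
                       capped = FALSE) {
  structure(list(kind = kind, contigs = contigs, names = names,
                 chains = chains, offsets = as.integer(offsets),
                 ref_len = as.integer(ref_len), k = as.integer(k),
                 capped = capped),
            class = "map_index")
}

#' @export
print.map_index <- function(x, ...) {
  cat("<map_index> kind=", x$kind, ", ", length(x$contigs), " contig(s), k=",
      x$k, if (x$capped) ", capped", "\n", sep = "")
  invisible(x)
}

#' Build a mapping index
#'
#' For a linear reference the index is the set of all overlapping k-mers with
#' their positions. For a variation graph the searchable sequence space is the
#' backbone plus one alternate contig per allele combination of each variant
#' cluster (variants closer than `flank` are clustered so that no read can
#' span two clusters): with a haplotype index only haplotype-observed
#' combinations are represented (the graph analogue of haplotype-restricted
#' k-mer paths); without one, all combinations are enumerated up to
#' `combo_cap` per cluster, falling back to single-variant contigs with
#' `capped = TRUE`. Every contig carries an exact coordinate chain to the
#' reference, used for surjection.
#'
#' @param target a `reference_seq` or `variation_graph`
#' @param k seed k-mer length (>= 8)
#' @param ... passed on to methods
#' @export
build_index <- function(target, k = 21L, ...) UseMethod("build_index")

#' @rdname build_index
#' @param chain optional chain mapping the sequence onto an original
#'   reference (used for consensus references); defaults to identity
#' @export
build_index.reference_seq <- function(target, k = 21L, chain = NULL, ...) {
  if (k < 8) stop("seed length k must be >= 8")
  if (k > target$length) stop("k exceeds the target length")
  if (is.null(chain)) chain <- chain_identity(target$length)
  .new_index("linear", contigs = target$sequence, names = target$name,
             chains = list(chain), offsets = chain$blocks$tgt_start[1] -
               chain$blocks$src_start[1],
             ref_len = chain$tgt_len, k = k)
}

# carriage matrix (walks x variants in graph) derived from haplotype walks:
# SNP/INS alleles are carried when the alternate node lies on the walk,
# deletions when the first bypassed backbone node is absent from it
.walk_carriage <- function(graph, hapindex) {
  bt <- graph$bubble_tbl
  first_skip <- vapply(graph$bubbles, function(b)
    if (length(b$skip) > 0) b$skip[1] else NA_integer_, 0L)[bt$id]
  M <- matrix(0L, nrow = length(hapindex), ncol = nrow(bt),
              dimnames = list(names(hapindex), bt$id))
  for (w in seq_along(hapindex)) {
    walk <- hapindex[[w]]
    has_alt <- !is.na(match(bt$alt, walk))
    has_skip <- !is.na(match(first_skip, walk))
    M[w, ] <- ifelse(!is.na(bt$alt), as.integer(has_alt),
                     as.integer(!has_skip))
  }
  M
}

#' @rdname build_index
#' @param hapindex a [embed_haplotypes()] index restricting the searchable
#'   paths, or `NULL` for full enumeration
#' @param flank flanking bases around each variant cluster (>= read length)
#' @param combo_cap maximum allele combinations enumerated per cluster
#' @export
build_index.variation_graph <- function(target, k = 21L, hapindex = NULL,
                                        flank = 150L, combo_cap = 64L, ...) {
  graph <- target
  ref <- graph$ref
  if (k < 8) stop("seed length k must be >= 8")
  if (k > ref$length) stop("k exceeds the target length")
  v <- graph$variants
  contigs <- ref$sequence
  names <- "backbone"
  chains <- list(chain_identity(ref$length))
  offsets <- 0L
  capped <- FALSE
  if (nrow(v) > 0) {
    vend <- v$pos + nchar(v$ref)
    newc <- c(TRUE, v$pos[-1] - vend[-nrow(v)] >= flank)
    cl <- cumsum(newc)
    carr <- if (!is.null(hapindex)) .walk_carriage(graph, hapindex) else NULL
    for (g in unique(cl)) {
      rows <- which(cl == g)
      m <- length(rows)
      ws <- max(0L, v$pos[rows[1]] - flank)
      we <- min(ref$length, vend[rows[m]] + flank)
      combos <- if (!is.null(carr)) {
        u <- unique(carr[, v$id[rows], drop = FALSE])
        u <- u[rowSums(u) > 0, , drop = FALSE]
        if (nrow(u) > combo_cap) { capped <- TRUE; u <- u[seq_len(combo_cap), , drop = FALSE] }
        u
      } else if (2^m - 1 <= combo_cap) {
        u <- as.matrix(expand.grid(rep(list(0:1), m)))[-1, , drop = FALSE]
        colnames(u) <- v$id[rows]
        u
      } else {
        capped <- TRUE
        diag(m)[, , drop = FALSE]
      }
      if (is.null(colnames(combos))) colnames(combos) <- v$id[rows]
      for (ci in seq_len(nrow(combos))) {
        sel <- v[rows[combos[ci, ] == 1L], , drop = FALSE]
        if (nrow(sel) == 0) next
        ap <- apply_variants(ref$sequence, sel, from = ws, to = we)
        contigs <- c(contigs, ap$sequence)
        names <- c(names, sprintf("alt_c%03d_%s", g,
                                  paste(which(combos[ci, ] == 1L),
                                        collapse = "")))
        chains <- c(chains, list(chain_invert(ap$chain)))  # contig -> ref
        offsets <- c(offsets, ws)
      }
    }
  }
  idx <- .new_index("graph", contigs, names, chains, offsets,
                    ref_len = ref$length, k = k, capped = capped)
  idx$graph_variants <- v$id
  idx
}

#' Distinct k-mer sequences represented in an index
#'
#' Enumerates the k-mers of every contig in the index (the k-mer path
#' sequence space searched by the mapper). Intended for validation at toy
#' scale.
#'
#' @param index a [build_index()] index
#' @export
index_kmer_set <- function(index) {
  k <- index$k
  out <- character(0)
  for (s in index$contigs) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
  }
  sort(unique(out))
}

#' Map reads to an index
#'
#' Deterministic seed-and-extend mapping: seeds are looked up on both
#' strands, candidate loci extended with banded affine-gap alignment,
#' candidates surjecting to the same reference locus de-duplicated, and (in
#' paired mode) mates scored jointly under a Normal fragment-length prior.
#' `MQ = min(60, 6 * (best - second_best))`, 0 on ties; reads with no seed
#' hits are unmapped. Graph hits are surjected: `ref_pos` is the reference
#' offset of the first aligned base, with alignments starting inside
#' alternate-allele material assigned to the preceding backbone coordinate.
#'
#' @param reads a [simulate_reads()] tibble (columns `id`, `seq`, `mate`), or
#'   any tibble with those columns
#' @param index a [build_index()] index
#' @param params a [map_params()] object
#' @return tibble of alignment records: id, mapped, contig, ref_pos (0-based,
#'   surjected), strand, score, MQ, edit_distance, soft_clip, n_secondary,
#'   cigar, tpos, seq_aln (read oriented to the contig forward strand)
#' @export
map_reads <- function(reads, index, params = map_params()) {
  if (any(nchar(reads$seq) < params$k))
    stop("read length must be >= seed length k")
  paired <- all(c(1L, 2L) %in% reads$mate)
  if (paired) {
    base <- sub("/[12]$", "", reads$id)
    m1 <- reads[reads$mate == 1L, ]
    m2 <- reads[reads$mate == 2L, ]
    b1 <- sub("/[12]$", "", m1$id)
    m2 <- m2[match(b1, sub("/[12]$", "", m2$id)), ]
    res <- cpp_map_reads(index$contigs, index$offsets, m1$seq, m2$seq,
                         k = params$k, stride = params$stride,
                         occ_cap = params$occ_cap, max_cand = params$max_cand,
                         match = params$match, mismatch = params$mismatch,
                         gap_open = params$gap_open, gap_ext = params$gap_ext,
                         band = params$band, frag_mean = params$frag_mean,
                         frag_sd = params$frag_sd,
                         dedup_slop = params$dedup_slop,
                         unpaired_pen = params$unpaired_pen)
    ids <- c(m1$id, m2$id)
    seqs <- c(m1$seq, m2$seq)
  } else {
    res <- cpp_map_reads(index$contigs, index$offsets, reads$seq, character(0),
                         k = params$k, stride = params$stride,
                         occ_cap = params$occ_cap, max_cand = params$max_cand,
                         match = params$match, mismatch = params$mismatch,
                         gap_open = params$gap_open, gap_ext = params$gap_ext,
                         band = params$band, frag_mean = params$frag_mean,
                         frag_sd = params$frag_sd,
                         dedup_slop = params$dedup_slop,
                         unpaired_pen = params$unpaired_pen)
    ids <- reads$id
    seqs <- reads$seq
  }
  mapped <- res$mapped == 1L
  ref_pos <- rep(NA_integer_, length(ids))
  for (ci in unique(res$contig[mapped])) {
    sel <- which(mapped & res$contig == ci)
    ref_pos[sel] <- liftover(index$chains[[ci]], res$tpos[sel], "forward",
                             nearest = TRUE)
  }
  seq_aln <- seqs
  neg <- mapped & res$strand == -1L
  seq_aln[neg] <- .revcomp(seqs[neg])
  seq_aln[!mapped] <- NA_character_
  tibble::tibble(
    id = ids, mapped = mapped,
    contig = ifelse(mapped, index$names[res$contig], NA_character_),
    ref_pos = ref_pos,
    strand = ifelse(mapped, ifelse(res$strand > 0, "+", "-"), NA_character_),
    score = ifelse(mapped, res$score, NA_integer_),
    MQ = ifelse(mapped, res$mq, NA_integer_),
    edit_distance = ifelse(mapped, res$nm, NA_integer_),
    soft_clip = ifelse(mapped, res$soft_clip, NA_integer_),
    n_secondary = ifelse(mapped, res$n_secondary, NA_integer_),
    cigar = ifelse(mapped, res$cigar, NA_character_),
    tpos = ifelse(mapped, res$tpos, NA_integer_),
    contig_idx = ifelse(mapped, res$contig, NA_integer_),
    seq_aln = seq_aln)
}

#' Write alignments as a SAM-like TSV
#'
#' Read id, mapped flag, reference name, 1-based surjected position, strand,
#' MQ, CIGAR, NM and soft-clip summary.
#'
#' @param alignments a [map_reads()] tibble
#' @param path output file
#' @param ref_name reference sequence name
#' @export
write_alignments_tsv <- function(alignments, path, ref_name = "ref") {
  out <- data.frame(
    qname = alignments$id,
    flag = ifelse(!alignments$mapped, 4L,
                  ifelse(alignments$strand == "-", 16L, 0L)),
    rname = ifelse(alignments$mapped, ref_name, "*"),
    pos = ifelse(alignments$mapped, alignments$ref_pos + 1L, 0L),
    mapq = ifelse(alignments$mapped, alignments$MQ, 0L),
    cigar = ifelse(alignments$mapped, alignments$cigar, "*"),
    nm = ifelse(alignments$mapped, alignments$edit_distance, NA_integer_),
    soft_clip = ifelse(alignments$mapped, alignments$soft_clip, NA_integer_))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
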