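#' Monotone coordinate maps between two sequence coordinate systems
#'
#' A chain map is an ordered set of co-linear blocks `(src_start, tgt_start,
#' len)` in 0-based coordinates. Positions inside a block map 1:1; positions
#' falling in the gap between blocks (bases deleted from, or inserted into,
#' the target) are unmapped. Chains are produced when alleles are applied to
#' a reference (consensus building, haplotype extraction, alternate-allele
#' contigs) and consumed by [liftover()] and by alignment surjection.
#'
#' @param blocks data frame with integer columns `src_start`, `tgt_start`,
#'   `len` (strictly increasing, non-overlapping in both systems).
#' @param src_len,tgt_len total lengths of the two sequences.
#' @return an object of class `chain_map`.
#' @export
chain_map <- function(blocks, src_len, tgt_len) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("src_start", "tgt_start", "len") %in% names(blocks)))
  if (nrow(blocks) > 1) {
    se <- blocks$src_start + blocks$len
    te <- blocks$tgt_start + blocks$len
    if (any(diff(blocks$src_start) <= 0) || any(blocks$src_start[-1] < se[-nrow(blocks)]))
      stop("chain blocks overlap or are unsorted in source coordinates")
    if (any(blocks$tgt_start[-1] < te[-nrow(blocks)]))
      stop("chain blocks overlap in target coordinates")
  }
  structure(list(blocks = blocks, src_len = as.integer(src_len),
                 tgt_len = as.integer(tgt_len)),
            class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat("<chain_map> ", nrow(x$blocks), " block(s), source ", x$src_len,
      " bp -> target ", x$tgt_len, " bp\n", sep = "")
  invisible(x)
}

#' Identity chain of a sequence onto itself
#' @param len sequence length (bp)
#' @export
chain_identity <- function(len) {
  chain_map(data.frame(src_start = 0L, tgt_start = 0L, len = as.integer(len)),
            len, len)
}

#' Swap source and target of a chain
#' @param chain a [chain_map()]
#' @export
chain_invert <- function(chain) {
  b <- chain$blocks
  chain_map(data.frame(src_start = b$tgt_start, tgt_start = b$src_start,
                       len = b$len),
            chain$tgt_len, chain$src_len)
}

#' Map positions through a chain
#'
#' Converts 0-based positions between the source and target coordinate
#' systems of a chain. Positions inside deleted/inserted material are
#' unmapped and return `NA` unless `nearest = TRUE`, in which case the
#' closest mapped position at or before the query (or the first mapped
#' position if none precedes it) is returned -- the convention used when
#' surjecting alignments that start inside alternate-allele material.
#'
#' @param chain a [chain_map()]
#' @param pos integer vector of 0-based positions
#' @param direction `"forward"` (source to target) or `"reverse"`
#' @param nearest if `TRUE`, fall back to the nearest preceding mapped
#'   position instead of `NA`
#' @return integer vector of mapped positions (`NA` where unmapped)
#' @export
liftover <- function(chain, pos, direction = c("forward", "reverse"),
                     nearest = FALSE) {
  direction <- match.arg(direction)
  ch <- if (direction == "forward") chain else chain_invert(chain)
  lim <- ch$src_len
  if (any(!is.na(pos) & (pos < 0 | pos >= lim)))
    stop("position beyond sequence end")
  b <- ch$blocks
  idx <- findInterval(pos, b$src_start)
  out <- rep(NA_integer_, length(pos))
  inb <- !is.na(pos) & idx >= 1
  off <- pos[inb] - b$src_start[idx[inb]]
  hit <- off < b$len[idx[inb]]
  out[inb][hit] <- as.integer(b$tgt_start[idx[inb]][hit] + off[hit])
  if (nearest && anyNA(out)) {
    miss <- which(is.na(out) & !is.na(pos))
    for (i in miss) {
      j <- idx[i]
      out[i] <- if (j >= 1) as.integer(b$tgt_start[j] + b$len[j] - 1L)
                else as.integer(b$tgt_start[1])
    }
  }
  out
}

# Build (new sequence, chain) by applying variants to a subsequence of the
# reference. `variants` must be sorted by pos with non-overlapping ref spans.
# Coordinates in `variants$pos` are absolute on the full reference; `from`/`to`
# give the 0-based half-open window being rebuilt. The chain maps reference
# (absolute) -> new sequence (local, 0-based).
apply_variants <- function(sequence, variants, from = 0L,
                           to = nchar(sequence)) {
  from <- as.integer(from); to <- as.integer(to)
  win <- substr(sequence, from + 1L, to)
  if (is.null(variants) || nrow(variants) == 0) {
    ch <- chain_map(data.frame(src_start = from, tgt_start = 0L,
                               len = to - from),
                    src_len = nchar(sequence), tgt_len = to - from)
    return(list(sequence = win, chain = ch))
  }
  v <- variants[order(variants$pos), , drop = FALSE]
  rlen <- nchar(v$ref); alen <- nchar(v$alt)
  if (any(v$pos < from) || any(v$pos + rlen > to))
    stop("variant out of range of the window")
  if (any(v$pos[-1] < (v$pos + rlen)[-nrow(v)]))
    stop("overlapping variants")
  src_start <- integer(0); tgt_start <- integer(0); blen <- integer(0)
  segs <- character(0)
  cur_src <- from; cur_tgt <- 0L
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    # co-linear segment runs up to and including any shared leading anchor
    # base; SNPs (rlen == alen) keep the frame, so their span stays co-linear.
    # Deleted interior bases and inserted bases are unmapped between blocks.
    anchor <- if (rlen[i] == alen[i]) rlen[i] else 1L
    seg <- (p + anchor) - cur_src
    segs <- c(segs, substr(sequence, cur_src + 1L, p), v$alt[i])
    src_start <- c(src_start, cur_src); tgt_start <- c(tgt_start, cur_tgt)
    blen <- c(blen, seg)
    cur_tgt <- cur_tgt + seg + (alen[i] - anchor)
    cur_src <- p + rlen[i]
  }
  segs <- c(segs, substr(sequence, cur_src + 1L, to))
  src_start <- c(src_start, cur_src); tgt_start <- c(tgt_start, cur_tgt)
  blen <- c(blen, to - cur_src)
  newseq <- paste(segs, collapse = "")
  keep <- blen > 0
  ch <- chain_map(data.frame(src_start = src_start[keep],
                             tgt_start = tgt_start[keep], len = blen[keep]),
                  src_len = nchar(sequence), tgt_len = nchar(newseq))
  list(sequence = newseq, chain = ch)
}

#' Write a chain file (UCSC chain format)
#'
#' @param chain a [chain_map()]
#' @param path output file
#' @param src_name,tgt_name sequence names for the header lines
#' @export
write_chain <- function(chain, path, src_name = "source", tgt_name = "target") {
  b <- chain$blocks
  lines <- sprintf("chain 1000 %s %d + %d %d %s %d + %d %d 1",
                   src_name, chain$src_len, b$src_start[1],
                   b$src_start[nrow(b)] + b$len[nrow(b)],
                   tgt_name, chain$tgt_len, b$tgt_start[1],
                   b$tgt_start[nrow(b)] + b$len[nrow(b)])
  body <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    if (i < nrow(b)) {
      dt <- b$src_start[i + 1] - (b$src_start[i] + b$len[i])
      dq <- b$tgt_start[i + 1] - (b$tgt_start[i] + b$len[i])
      body[i] <- sprintf("%d\t%d\t%d", b$len[i], dt, dq)
    } else {
      body[i] <- sprintf("%d", b$len[i])
    }
  }
  writeLines(c(lines, body, ""), path)
  invisible(path)
}
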