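# parse a cigar string into (op, len) pairs
.parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[SMIDX]", cigar))[[1]]
  list(op = substr(m, nchar(m), nchar(m)),
       len = as.integer(substr(m, 1, nchar(m) - 1)))
}

# Project one alignment onto reference coordinates: returns an integer vector
# `refpos` of length nchar(seq_aln) giving, for each base of the contig-
# oriented read, its 0-based reference coordinate (NA for soft-clipped bases,
# insertion errors, and alternate-allele material absent from the reference).
.project_alignment <- function(cigar, tpos, chain) {
  cg <- .parse_cigar(cigar)
  qlen <- sum(cg$len[cg$op %in% c("S", "M", "I")])
  refpos <- rep(NA_integer_, qlen)
  qp <- 1L
  cp <- as.integer(tpos)  # 0-based contig position
  for (i in seq_along(cg$op)) {
    l <- cg$len[i]
    switch(cg$op[i],
      S = { qp <- qp + l },
      I = { qp <- qp + l },
      D = { cp <- cp + l },
      M = {
        refpos[qp:(qp + l - 1L)] <- liftover(chain, cp:(cp + l - 1L),
                                             "forward")
        qp <- qp + l; cp <- cp + l
      })
  }
  refpos
}

# allele support of one projected read at one variant site; returns
# "ref", "alt" or NA (overlapping but uninformative)
.support_at_site <- function(refpos, seq_aln, variant) {
  p <- variant$pos
  rlen <- nchar(variant$ref)
  i <- match(p, refpos)
  if (variant$vclass == "SNP") {
    if (is.na(i)) return(NA_character_)
    b <- substr(seq_aln, i, i)
    if (b == variant$alt) return("alt")
    if (b == variant$ref) return("ref")
    return(NA_character_)
  }
  if (variant$vclass == "INS") {
    j <- match(p + 1L, refpos)
    if (is.na(i) || is.na(j)) return(NA_character_)
    gap <- j - i - 1L
    if (gap == 0L) return("ref")
    ins <- substr(seq_aln, i + 1L, j - 1L)
    if (identical(ins, substr(variant$alt, 2L, nchar(variant$alt))))
      return("alt")
    return(NA_character_)
  }
  # DEL: ref span [p, p + rlen); deleted interior [p + 1, p + rlen)
  j <- match(p + rlen, refpos)
  if (is.na(i) || is.na(j)) return(NA_character_)
  if (j == i + 1L) return("alt")
  if (j - i == rlen) {
    spelled <- substr(seq_aln, i, i + rlen - 1L)
    if (identical(spelled, variant$ref)) return("ref")
  }
  NA_character_
}

#' Pileup-based diploid genotyping at known sites
#'
#' Counts, at every requested site, the reads whose projected alignment
#' spells the full reference or alternate allele span (indel support requires
#' the exact allele; soft-clipped or partially spanning reads are
#' uninformative -- no local realignment or soft-clip rescue is attempted).
#' Reads with `MQ < min_pileup_mq` are excluded from pileups. Genotypes are
#' called by maximum likelihood under a binomial read-sampling model (allele
#' balance 0.5 for heterozygotes, per-read support error `hom_error` for
#' homozygotes). `QUAL` is the phred-scaled likelihood ratio of the called
#' genotype against homozygous-reference, so it grows with supporting
#' evidence and `QD = QUAL/DP` is depth-stable, keeping the conventional
#' `QD > 10` threshold meaningful; calls are flagged against
#' quality-by-depth, mapping-quality and depth thresholds.
#'
#' @param alignments a [map_reads()] tibble
#' @param index the [build_index()] index the reads were mapped to (provides
#'   the contig-to-reference projections)
#' @param ref the reference the sites are expressed on
#' @param sites tibble of variants (columns pos, ref, alt, vclass, and
#'   optionally id)
#' @param filters list with `min_QD`, `min_MQ`, `min_DP`; a call passes when
#'   QD, mean MQ and DP strictly exceed them
#' @param min_pileup_mq minimum read MQ for pileup inclusion
#' @param hom_error read error rate assumed under homozygous genotypes
#' @return tibble of genotype calls: id, pos, ref, alt, vclass, AD_ref,
#'   AD_alt, DP, mean_MQ, genotype, QUAL, QD, filter_status, filter_reason
#' @export
pileup_and_call <- function(alignments, index, ref, sites,
                            filters = list(min_QD = 10, min_MQ = 40,
                                           min_DP = 25),
                            min_pileup_mq = 10, hom_error = 0.001) {
  al <- alignments[alignments$mapped & alignments$MQ >= min_pileup_mq, ,
                   drop = FALSE]
  if (nrow(sites) == 0)
    return(tibble::tibble(id = character(0), pos = integer(0)))
  if (!"id" %in% names(sites)) sites$id <- sprintf("s%05d", seq_len(nrow(sites)))
  span <- max(nchar(al$seq_aln), 0) + 60L
  arng <- IRanges::IRanges(start = al$ref_pos + 1L, width = span)
  srng <- IRanges::IRanges(start = sites$pos + 1L,
                           end = sites$pos + nchar(sites$ref) + 1L)
  hits <- IRanges::findOverlaps(srng, arng)
  proj_cache <- vector("list", nrow(al))
  get_proj <- function(r) {
    if (is.null(proj_cache[[r]])) {
      ch <- index$chains[[al$contig_idx[r]]]
      proj_cache[[r]] <<- .project_alignment(al$cigar[r], al$tpos[r], ch)
    }
    proj_cache[[r]]
  }
  n <- nrow(sites)
  AD_ref <- AD_alt <- DP <- integer(n)
  mMQ <- numeric(n)
  by_site <- split(S4Vectors::subjectHits(hits),
                   factor(S4Vectors::queryHits(hits), levels = seq_len(n)))
  for (s in seq_len(n)) {
    rr <- by_site[[s]]
    DP[s] <- length(rr)
    mMQ[s] <- if (length(rr) > 0) mean(al$MQ[rr]) else 0
    nr <- na <- 0L
    for (r in rr) {
      sup <- .support_at_site(get_proj(r), al$seq_aln[r], sites[s, ])
      if (is.na(sup)) next
      if (sup == "ref") nr <- nr + 1L else na <- na + 1L
    }
    AD_ref[s] <- nr; AD_alt[s] <- na
  }
  nn <- AD_ref + AD_alt
  ll <- cbind(stats::dbinom(AD_alt, nn, hom_error, log = TRUE),
              stats::dbinom(AD_alt, nn, 0.5, log = TRUE),
              stats::dbinom(AD_alt, nn, 1 - hom_error, log = TRUE))
  ll[nn == 0, ] <- log(1 / 3)
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  gidx <- max.col(post, ties.method = "first")
  genotype <- c("0/0", "0/1", "1/1")[gidx]
  # variant calls: evidence against hom-ref; hom-ref calls: evidence against
  # the best variant genotype
  ll_best <- ll[cbind(seq_len(n), gidx)]
  QUAL <- ifelse(gidx == 1L,
                 ll[, 1] - pmax(ll[, 2], ll[, 3]),
                 ll_best - ll[, 1])
  QUAL <- pmax(0, 10 / log(10) * QUAL)
  QD <- ifelse(DP > 0, QUAL / DP, 0)
  reasons <- character(n)
  ok_qd <- QD > filters$min_QD
  ok_mq <- mMQ > filters$min_MQ
  ok_dp <- DP > filters$min_DP
  reasons <- mapply(function(a, b, c) paste(c(if (!a) "QD", if (!b) "MQ",
                                              if (!c) "DP"), collapse = ";"),
                    ok_qd, ok_mq, ok_dp)
  tibble::tibble(id = sites$id, pos = sites$pos, ref = sites$ref,
                 alt = sites$alt, vclass = sites$vclass,
                 AD_ref = AD_ref, AD_alt = AD_alt, DP = DP, mean_MQ = mMQ,
                 genotype = genotype, QUAL = QUAL, QD = QD,
                 filter_status = ifelse(ok_qd & ok_mq & ok_dp, "pass", "fail"),
                 filter_reason = reasons)
}
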