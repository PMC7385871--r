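#' Classify alignments as correctly or incorrectly mapped
#'
#' A mapped read is correct when its surjected start position lies within
#' `k` bases (the read length by default, allowing for clipping at indels) of
#' its true position; unmapped reads count as incorrect.
#'
#' @param alignments a [map_reads()] tibble
#' @param truth the [simulate_reads()] tibble the reads came from (joined by
#'   read id)
#' @param k maximum distance between mapped and true start (bp)
#' @return tibble: id, correct, mapped, MQ, contains_nonref, region_labels
#' @export
classify_alignments <- function(alignments, truth, k = 150L) {
  m <- match(alignments$id, truth$id)
  if (anyNA(m)) stop("read id(s) missing from truth")
  tr <- truth[m, ]
  correct <- alignments$mapped &
    abs(alignments$ref_pos - tr$true_ref_start) <= k
  correct[is.na(correct)] <- FALSE
  tibble::tibble(id = alignments$id, correct = correct,
                 mapped = alignments$mapped,
                 MQ = alignments$MQ,
                 contains_nonref = tr$contains_nonref,
                 region_labels = if ("region_labels" %in% names(tr))
                   tr$region_labels else "")
}

#' Pseudo-ROC of mapping accuracy parameterized on mapping quality
#'
#' Counts correctly (TP) and incorrectly (FP) mapped reads per mapping-
#' quality bucket and accumulates them from the highest threshold down:
#' `TPR_i = sum(TP_k, k = i..60) / n`, `FPR_i` analogously, with `n` the
#' total number of mapped reads. Thresholds are 60, 50, 40, 30, 20, 10, 0;
#' bucket `k` covers MQ in `[k, next higher threshold)`, with MQ 60 its own
#' bucket.
#'
#' @param evals a [classify_alignments()] tibble
#' @return tibble with `threshold`, `TPR`, `FPR`
#' @export
pseudo_roc <- function(evals) {
  if (nrow(evals) == 0) stop("empty input")
  ev <- evals[evals$mapped, , drop = FALSE]
  n <- nrow(ev)
  thr <- c(60L, 50L, 40L, 30L, 20L, 10L, 0L)
  thr_asc <- rev(thr)
  bucket <- thr_asc[findInterval(ev$MQ, thr_asc)]
  tp <- tapply(ev$correct, factor(bucket, levels = thr), sum, default = 0L)
  fp <- tapply(!ev$correct, factor(bucket, levels = thr), sum, default = 0L)
  tibble::tibble(threshold = thr,
                 TPR = cumsum(as.numeric(tp)) / n,
                 FPR = cumsum(as.numeric(fp)) / n)
}

#' Mapping summary statistics
#'
#' Proportion of perfectly mapped reads (zero edit distance over the full
#' read, no clipping), uniquely mapped reads (single reported locus, or MQ
#' 60 despite secondary loci), the overall error rate (unmapped reads count
#' as errors), the split of errors by MQ above/below 10 and by non-reference
#' content, and per-region error rates.
#'
#' @param alignments a [map_reads()] tibble
#' @param evals the matching [classify_alignments()] tibble
#' @return list of scalars and a per-region tibble
#' @export
mapping_summary <- function(alignments, evals) {
  stopifnot(nrow(alignments) == nrow(evals))
  mapped <- alignments$mapped
  n <- nrow(alignments)
  perfect <- mapped & alignments$edit_distance == 0 & alignments$soft_clip == 0
  unique_ <- mapped & (alignments$n_secondary == 0 | alignments$MQ == 60)
  err <- !evals$correct
  err_mapped <- err & mapped
  res <- list(
    n_reads = n,
    prop_perfect = mean(perfect, na.rm = FALSE),
    prop_unique = mean(unique_),
    prop_unmapped = mean(!mapped),
    error_rate = mean(err),
    err_prop_mq_gt10 = if (any(err_mapped))
      mean(alignments$MQ[err_mapped] > 10) else NA_real_,
    err_prop_nonref = if (any(err) && !all(is.na(evals$contains_nonref)))
      mean(evals$contains_nonref[err], na.rm = TRUE) else NA_real_)
  labs <- evals$region_labels
  labs[is.na(labs) | labs == ""] <- "none"
  first <- vapply(strsplit(labs, ","), `[`, "", 1)
  per_region <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(region = first, err = err), region),
    n = dplyr::n(), error_rate = mean(err), .groups = "drop")
  res$per_region <- per_region
  res
}

#' Allelic-ratio profile by signed variant length
#'
#' The allelic ratio of a heterozygous site is `AD_alt / (AD_ref + AD_alt)`;
#' under unbiased mapping its expectation is 0.5. Sites are grouped by
#' signed variant length (negative deletions, 0 SNPs, positive insertions)
#' and by whether the site's alternate allele is represented in the graph.
#' Sites with no allele-informative reads are skipped with a message.
#'
#' @param pileups a [pileup_and_call()] tibble (needs AD_ref, AD_alt, pos)
#' @param het_truth variant tibble of truly heterozygous sites (pos,
#'   length_delta)
#' @param graph_membership logical vector (or function of pos) flagging sites
#'   whose alternate allele is in the graph; recycled if length 1
#' @param bin_breaks optional breaks for coarser length bins; by default each
#'   distinct signed length is its own bin
#' @return tibble: length (signed bp or bin midpoint), in_graph, n_sites,
#'   mean_ratio, sem
#' @export
allelic_ratio_profile <- function(pileups, het_truth, graph_membership = TRUE,
                                  bin_breaks = NULL) {
  m <- match(het_truth$pos, pileups$pos)
  keep <- !is.na(m)
  ht <- het_truth[keep, , drop = FALSE]
  pu <- pileups[m[keep], , drop = FALSE]
  denom <- pu$AD_ref + pu$AD_alt
  if (any(denom == 0))
    message(sum(denom == 0), " site(s) without allele-informative reads skipped")
  ok <- denom > 0
  ratio <- pu$AD_alt[ok] / denom[ok]
  len <- ht$length_delta[ok]
  ing <- rep_len(graph_membership, nrow(ht))[ok]
  grp <- if (is.null(bin_breaks)) len
         else {
           mids <- (bin_breaks[-1] + bin_breaks[-length(bin_breaks)]) / 2
           mids[findInterval(len, bin_breaks, all.inside = TRUE)]
         }
  tb <- tibble::tibble(length = grp, in_graph = ing, ratio = ratio)
  dplyr::summarise(dplyr::group_by(tb, length, in_graph),
                   n_sites = dplyr::n(),
                   mean_ratio = mean(ratio),
                   sem = stats::sd(ratio) / sqrt(dplyr::n()),
                   .groups = "drop")
}

#' Genotype concordance metrics against a truth set
#'
#' Builds the 3x3 confusion matrix over \{0/0, 0/1, 1/1\} at the truth
#' array subset and derives: genotype concordance (trace / total),
#' non-reference sensitivity (genotype-matching variant calls / truth
#' variant sites), precision (genotype-matching non-reference calls / all
#' non-reference calls) and non-reference discrepancy (discordant pairs /
#' (total - concordant homozygous-reference pairs)).
#'
#' @param calls a [pileup_and_call()] tibble (id + genotype); sites missing
#'   from `calls` count as 0/0
#' @param truth a [emulate_truth_sets()] object
#' @param positions variant ids to compare at (defaults to the truth array
#'   subset)
#' @return list with `genotype_concordance`, `nr_sensitivity`, `precision`,
#'   `nr_discrepancy`, `confusion` (3x3 matrix, rows = truth)
#' @export
concordance_metrics <- function(calls, truth, positions = NULL) {
  if (is.null(positions)) positions <- truth$array_subset
  tg <- truth$genotypes
  tg <- tg[match(positions, tg$id), , drop = FALSE]
  if (nrow(tg) == 0 || all(is.na(tg$gt))) stop("empty truth overlap")
  cg <- calls$genotype[match(positions, calls$id)]
  cg[is.na(cg)] <- "0/0"
  lv <- c("0/0", "0/1", "1/1")
  cm <- table(factor(tg$gt, levels = lv), factor(cg, levels = lv))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(truth = lv, called = lv))
  total <- sum(cm)
  conc <- sum(diag(cm)) / total
  truth_var <- sum(cm[2:3, ])
  nr_sens <- if (truth_var > 0) (cm[2, 2] + cm[3, 3]) / truth_var else NA_real_
  called_var <- sum(cm[, 2:3])
  prec <- if (called_var > 0) (cm[2, 2] + cm[3, 3]) / called_var else NA_real_
  disc <- total - sum(diag(cm))
  nr_disc <- if (total - cm[1, 1] > 0) disc / (total - cm[1, 1]) else 0
  list(genotype_concordance = conc, nr_sensitivity = nr_sens,
       precision = prec, nr_discrepancy = nr_disc, confusion = cm)
}
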