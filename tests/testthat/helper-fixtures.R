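# shared fixtures: hand-built references, panels and oracle implementations

toy_ref <- function(seq, name = "t") {
  structure(list(name = name, sequence = seq, length = nchar(seq)),
            class = "reference_seq")
}

toy_variants <- function(pos, ref, alt, chrom = "t") {
  vclass <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                   ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  tibble::tibble(id = sprintf("v%03d", seq_along(pos)), chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt, vclass = vclass,
                 length_delta = as.integer(nchar(alt) - nchar(ref)))
}

toy_vset <- function(variants, mode = "threshold", threshold = 0) {
  structure(list(ids = variants$id, variants = variants, mode = mode,
                 threshold = threshold, pop = "A"),
            class = "variant_set")
}

# panel from an explicit haplotype matrix (rows = haplotypes, 2 per sample)
toy_panel <- function(variants, H, pops, ref_name = "t") {
  n_h <- nrow(H)
  stopifnot(n_h %% 2 == 0, length(pops) == n_h / 2)
  samples <- tibble::tibble(
    sample = sprintf("%s_s%02d", pops, stats::ave(seq_along(pops), pops,
                                                  FUN = seq_along)),
    pop = pops)
  rownames(H) <- paste0(rep(samples$sample, each = 2), "_h", 1:2)
  colnames(H) <- variants$id
  af <- t(vapply(unique(pops), function(p)
    colMeans(H[rep(pops, each = 2) == p, , drop = FALSE]),
    numeric(ncol(H))))
  rownames(af) <- unique(pops)
  structure(list(variants = variants, samples = samples,
                 haplotypes = H, af = af, ref_name = ref_name),
            class = "variant_panel")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- oracles -----------------------------------------------------------------

# mean pairwise Hamming distance between haplotype indicator rows, per window
oracle_windowed_pi <- function(panel, pop, window) {
  rows <- which(rep(panel$samples$pop, each = 2) == pop)
  H <- panel$haplotypes[rows, , drop = FALSE]
  n <- nrow(H)
  pairs <- utils::combn(n, 2)
  win <- as.integer(panel$variants$pos %/% window) * as.integer(window)
  out <- vapply(sort(unique(win)), function(w) {
    cols <- which(win == w)
    d <- 0
    for (k in seq_len(ncol(pairs))) {
      d <- d + sum(H[pairs[1, k], cols] != H[pairs[2, k], cols])
    }
    d / ncol(pairs) / window
  }, 0)
  tibble::tibble(start = sort(unique(win)), pi = out)
}

# exhaustive enumeration of distinct k-mer paths over all source-sink paths
oracle_kmer_paths <- function(graph, k) {
  succ <- graphpop:::.graph_succ(graph)
  indeg <- rep(0L, nrow(graph$nodes))
  for (t in graph$edges$to) indeg[t] <- indeg[t] + 1L
  sources <- graph$nodes$id[indeg[graph$nodes$id] == 0L]
  paths <- list()
  walk <- function(node, acc) {
    acc <- c(acc, node)
    s <- succ[[node]]
    if (length(s) == 0) paths[[length(paths) + 1L]] <<- acc
    else for (x in s) walk(x, acc)
  }
  for (s in sources) walk(s, integer(0))
  sigs <- character(0)
  lens <- nchar(graph$nodes$seq)
  for (p in paths) {
    pl <- lens[match(p, graph$nodes$id)]
    cum <- cumsum(pl); start0 <- c(0, cum[-length(cum)])
    total <- cum[length(cum)]
    if (total < k) next
    for (s0 in 0:(total - k)) {
      ni <- findInterval(s0, start0)
      off <- s0 - start0[ni]
      nj <- findInterval(s0 + k - 1, start0)
      sigs <- c(sigs, paste(c(off, p[ni:nj]), collapse = "."))
    }
  }
  length(unique(sigs))
}

# exact rational concordance metrics from an integer confusion matrix
oracle_concordance <- function(cm) {
  total <- sum(cm)
  list(genotype_concordance = sum(diag(cm)) / total,
       nr_sensitivity = (cm[2, 2] + cm[3, 3]) / sum(cm[2:3, ]),
       precision = (cm[2, 2] + cm[3, 3]) / sum(cm[, 2:3]),
       nr_discrepancy = (total - sum(diag(cm))) / (total - cm[1, 1]))
}

# calls/truth pair realising a given confusion matrix (rows truth, cols called)
realise_confusion <- function(cm) {
  lv <- c("0/0", "0/1", "1/1")
  tg <- character(0); cg <- character(0)
  for (i in 1:3) for (j in 1:3) {
    tg <- c(tg, rep(lv[i], cm[i, j])); cg <- c(cg, rep(lv[j], cm[i, j]))
  }
  ids <- sprintf("v%03d", seq_along(tg))
  calls <- tibble::tibble(id = ids, genotype = cg)
  truth <- structure(list(sample = "s",
                          genotypes = tibble::tibble(id = ids,
                                                     pos = seq_along(ids),
                                                     gt = tg),
                          array_subset = ids),
                     class = "truth_genotypes")
  list(calls = calls, truth = truth)
}
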