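test_that("extract_haplotype applies alleles sequentially with a coord map", {
  ref <- toy_ref("ACGTACGT")
  v <- toy_variants(c(3, 4), c("T", "ACG"), c("G", "A"))
  H <- matrix(c(1L, 0L, 1L, 0L), nrow = 2)  # h1 carries both alleles
  p <- toy_panel(v, H, pops = "A")
  h1 <- extract_haplotype(ref, p, p$samples$sample[1], 1)
  expect_identical(h1$sequence, "ACGGAT")
  h2 <- extract_haplotype(ref, p, p$samples$sample[1], 2)
  expect_identical(h2$sequence, ref$sequence)
  expect_equal(liftover(h2$coord_map, 0:7), 0:7)
  # downstream of the 2-bp deletion the haplotype->reference shift is +2
  expect_equal(liftover(h1$coord_map, 5L), 7L)
  expect_error(extract_haplotype(ref, p, "nobody", 1), "unknown sample")
})

test_that("error-free reads are exact substrings found at their offsets", {
  ref <- generate_reference(30000, seed = 61, repeats = NULL)
  p <- simulate_population(ref, c(A = 6L), 150, indel_fraction = 0.3,
                           max_indel = 10, seed = 62)
  s <- p$samples$sample[1]
  haps <- lapply(1:2, function(h) extract_haplotype(ref, p, s, h))
  reads <- simulate_reads(haps, sim_params(n_pairs = 300, sub_rate = 0,
                                           indel_rate = 0, seed = 63))
  expect_equal(nrow(reads), 600L)
  expect_true(all(nchar(reads$seq) == 150L))
  hs <- vapply(haps, `[[`, "", "sequence")
  for (i in sample.int(nrow(reads), 60)) {
    r <- reads[i, ]
    seq <- if (r$strand == "-") graphpop:::.revcomp(r$seq) else r$seq
    src <- substr(hs[r$hap], r$hap_start + 1, r$hap_start + 150)
    expect_identical(seq, src)
    # exact string search recovers the recorded offset
    hit <- regexpr(seq, hs[r$hap], fixed = TRUE)[1]
    expect_true(hit >= 1)
  }
  expect_true(all(reads$true_ref_start <= reads$true_ref_end))
})

test_that("injected error rates and fragment lengths match their settings", {
  ref <- generate_reference(30000, seed = 64, repeats = NULL)
  p <- simulate_population(ref, c(A = 4L), 0, seed = 65)
  s <- p$samples$sample[1]
  hap <- extract_haplotype(ref, p, s, 1)
  reads <- simulate_reads(hap, sim_params(n_pairs = 1500, sub_rate = 0.01,
                                          indel_rate = 0, seed = 66))
  mm <- 0L; tot <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    seq <- if (r$strand == "-") graphpop:::.revcomp(r$seq) else r$seq
    src <- substr(hap$sequence, r$hap_start + 1, r$hap_start + 150)
    mm <- mm + sum(strsplit(seq, "")[[1]] != strsplit(src, "")[[1]])
    tot <- tot + 150L
  }
  se <- sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(mm / tot - 0.01), 3 * se)
  # realized fragment-length mean within 3 s.e. of 500
  fr <- reads$frag_len[reads$mate == 1]
  expect_lt(abs(mean(fr) - 500), 3 * 50 / sqrt(length(fr)))
  # indel error bookkeeping at the configured rate
  reads2 <- simulate_reads(hap, sim_params(n_pairs = 1500, sub_rate = 0,
                                           indel_rate = 0.002, seed = 67))
  rate <- sum(reads2$n_indel_err) / (nrow(reads2) * 150)
  se2 <- sqrt(0.002 * 0.998 / (nrow(reads2) * 150))
  expect_lt(abs(rate - 0.002), 3 * se2)
  expect_error(simulate_reads(hap, sim_params(n_pairs = 10, frag_mean = 5e5)),
               "shorter")
})

test_that("annotation flags non-reference content and region labels", {
  ref <- toy_ref(strrep("ACGTTGCA", 200))  # 1600 bp
  v <- toy_variants(c(400, 1000), c("T", "G"), c("A", "C"))
  v$ref <- substring(ref$sequence, v$pos + 1, v$pos + 1)
  v$alt <- c("A", "A")
  H <- matrix(c(1L, 0L, 0L, 0L), nrow = 2)  # h1 carries variant 1 only
  p <- toy_panel(v, H, pops = "A")
  reads <- tibble::tibble(
    id = c("r1", "r2", "r3"), mate = 0L, seq = "N",
    sample = p$samples$sample[1], hap = c(1L, 1L, 2L),
    hap_start = 0L, frag_len = 150L, strand = "+",
    true_ref_start = c(350L, 900L, 350L),
    true_ref_end = c(500L, 1050L, 500L))
  ann <- data.frame(start = c(300L), end = c(600L), label = "repeat")
  out <- annotate_reads(reads, p, ann)
  expect_equal(out$contains_nonref, c(TRUE, FALSE, FALSE))
  expect_equal(out$region_labels, c("repeat", "", "repeat"))
})

test_that("simulated coverage matches the configured fold depth", {
  ref <- generate_reference(30000, seed = 68, repeats = NULL)
  p <- simulate_population(ref, c(A = 4L), 0, seed = 69)
  hap <- extract_haplotype(ref, p, p$samples$sample[1], 1)
  n_pairs <- 1000L
  reads <- simulate_reads(hap, sim_params(n_pairs = n_pairs, seed = 70))
  fold <- sum(nchar(reads$seq)) / ref$length
  expect_equal(fold, 2 * n_pairs * 150 / ref$length, tolerance = 0.01)
})
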