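test_that("index construction enumerates the k-mer space", {
  set.seed(71)
  seq100 <- random_dna(100)
  while (length(unique(substring(seq100, 1:86, 15:100))) < 86)
    seq100 <- random_dna(100)
  idx <- build_index(toy_ref(seq100), k = 15)
  expect_length(index_kmer_set(idx), 86L)  # L - k + 1 positions
  expect_error(build_index(toy_ref("ACGTACGT"), k = 21), "exceeds")
  expect_error(build_index(toy_ref(seq100), k = 4), ">= 8")

  # unrestricted toy graph: index k-mers equal brute-force path enumeration
  r <- toy_ref(random_dna(60))
  b <- substr(r$sequence, 31, 31)
  vs <- toy_vset(toy_variants(30, b, setdiff(c("A", "C", "G", "T"), b)[1]))
  g <- build_graph(r, vs, max_node_len = 16)
  gi <- build_index(g, k = 8, flank = 60)
  succ_kmers <- index_kmer_set(gi)
  # oracle: k-mers of both full haplotype strings (ref path and alt path)
  alt_seq <- graphpop:::apply_variants(r$sequence, vs$variants)$sequence
  want <- unique(c(substring(r$sequence, 1:(60 - 7), 8:60),
                   substring(alt_seq, 1:(nchar(alt_seq) - 7),
                             8:nchar(alt_seq))))
  expect_setequal(succ_kmers, want)

  # haplotype restriction reduces the k-mer space to the walk sequences
  H <- matrix(c(0L, 0L), nrow = 2)
  p <- toy_panel(vs$variants, H, pops = "A")
  hi <- embed_haplotypes(g, p, p$samples$sample[1])
  gr <- build_index(g, k = 8, hapindex = hi, flank = 60)
  expect_setequal(index_kmer_set(gr),
                  unique(substring(r$sequence, 1:(60 - 7), 8:60)))
})

test_that("exact unique reads map perfectly with MQ 60", {
  ref <- generate_reference(20000, seed = 72, repeats = NULL)
  idx <- build_index(ref, k = 21)
  reads <- tibble::tibble(id = "r1", mate = 0L,
                          seq = substr(ref$sequence, 1001, 1150))
  al <- map_reads(reads, idx)
  expect_true(al$mapped)
  expect_equal(al$ref_pos, 1000L)
  expect_equal(al$edit_distance, 0L)
  expect_equal(al$soft_clip, 0L)
  expect_equal(al$MQ, 60L)
  expect_equal(al$strand, "+")
  # reverse-complemented copy maps to the same locus on the minus strand
  al2 <- map_reads(tibble::tibble(id = "r2", mate = 0L,
                                  seq = graphpop:::.revcomp(reads$seq)), idx)
  expect_equal(al2$ref_pos, 1000L)
  expect_equal(al2$strand, "-")
  # determinism
  expect_identical(map_reads(reads, idx), map_reads(reads, idx))
})

test_that("reads from duplicated loci tie at MQ 0 with secondaries", {
  set.seed(73)
  block <- random_dna(500)
  ref <- toy_ref(paste0(random_dna(2000), block, random_dna(2000), block,
                        random_dna(2000)))
  idx <- build_index(ref, k = 21)
  al <- map_reads(tibble::tibble(id = "r", mate = 0L,
                                 seq = substr(block, 101, 250)), idx)
  expect_true(al$mapped)
  expect_equal(al$MQ, 0L)
  expect_gte(al$n_secondary, 1L)
  # ties break to the lowest reference position
  expect_equal(al$ref_pos, 2100L)
})

test_that("a graph-represented insertion aligns full length; linear clips", {
  set.seed(74)
  ref <- toy_ref(random_dna(2000))
  ins <- random_dna(20)
  anchor <- substr(ref$sequence, 1001, 1001)
  vs <- toy_vset(toy_variants(1000, anchor, paste0(anchor, ins)))
  g <- build_graph(ref, vs)
  idx_g <- build_index(g, k = 21, flank = 150)
  idx_l <- build_index(ref, k = 21)
  hap <- graphpop:::apply_variants(ref$sequence, vs$variants)$sequence
  # read spanning the insertion, centred on it
  read <- substr(hap, 941, 1090)
  al_g <- map_reads(tibble::tibble(id = "r", mate = 0L, seq = read), idx_g)
  al_l <- map_reads(tibble::tibble(id = "r", mate = 0L, seq = read), idx_l)
  expect_equal(al_g$edit_distance, 0L)
  expect_equal(al_g$soft_clip, 0L)
  expect_true(al_l$soft_clip > 0 | al_l$edit_distance >= 20)
  # surjected start of the graph alignment stays on reference coordinates
  expect_equal(al_g$ref_pos, 940L)
})

test_that("linear and graph mappers agree on reference-matching reads", {
  ref <- generate_reference(20000, seed = 75, repeats = NULL)
  p <- simulate_population(ref, c(A = 6L), 100, seed = 76)
  s <- p$samples$sample[1]
  haps <- lapply(1:2, function(h) extract_haplotype(ref, p, s, h))
  reads <- simulate_reads(haps, sim_params(n_pairs = 200, sub_rate = 0,
                                           indel_rate = 0, seed = 77))
  reads <- annotate_reads(reads, p)
  vs <- select_variants(p, "threshold", pops = "A", threshold = 0)
  g <- build_graph(ref, vs)
  hi <- embed_haplotypes(g, p, p$samples$sample)
  al_l <- map_reads(reads, build_index(ref, k = 21))
  al_g <- map_reads(reads, build_index(g, k = 21, hapindex = hi))
  al_g <- al_g[match(al_l$id, al_g$id), ]
  nonref <- reads$contains_nonref[match(al_l$id, reads$id)]
  refonly <- !nonref & al_l$mapped & al_g$mapped
  expect_gt(sum(refonly), 50)
  expect_equal(al_g$ref_pos[refonly], al_l$ref_pos[refonly])
})

test_that("alignments starting inside alternate material surject to the
           preceding backbone coordinate", {
  set.seed(78)
  ref <- toy_ref(random_dna(1200))
  ins <- random_dna(40)
  anchor <- substr(ref$sequence, 601, 601)
  vs <- toy_vset(toy_variants(600, anchor, paste0(anchor, ins)))
  g <- build_graph(ref, vs)
  idx <- build_index(g, k = 21, flank = 150)
  hap <- graphpop:::apply_variants(ref$sequence, vs$variants)$sequence
  # read starting 10 bp inside the inserted material
  read <- substr(hap, 612, 761)
  al <- map_reads(tibble::tibble(id = "r", mate = 0L, seq = read), idx)
  expect_true(al$mapped)
  expect_equal(al$ref_pos, 600L)
})
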