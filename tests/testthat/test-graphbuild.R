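test_that("variant selection modes implement their contracts", {
  # three variants with pop-A frequencies 0.04, 0.05, 0.06 in 100 haplotypes
  v <- toy_variants(c(100, 200, 300), c("A", "C", "G"), c("T", "A", "C"))
  H <- matrix(0L, nrow = 100, ncol = 3)
  H[1:4, 1] <- 1L; H[1:5, 2] <- 1L; H[1:6, 3] <- 1L
  p <- toy_panel(v, H, pops = rep("A", 50))
  sel <- select_variants(p, "threshold", pops = "A", threshold = 0.05)
  expect_identical(sel$ids, "v003")  # strictly greater than the threshold
  expect_length(select_variants(p, "threshold", pops = "A",
                                threshold = 1)$ids, 0)
  expect_length(select_variants(p, "empty")$ids, 0)

  # count matching subsamples every population to the smallest passing count
  set.seed(1)
  n_v <- 30
  vv <- toy_variants(100 * seq_len(n_v), rep("A", n_v), rep("T", n_v))
  HH <- matrix(0L, nrow = 60, ncol = n_v)
  pops <- rep(c("X", "Y", "Z"), each = 10)
  hp <- rep(pops, each = 2)
  HH[hp == "X", 1:10] <- 1L
  HH[hp == "Y", 1:8] <- 1L
  HH[hp == "Z", 1:12] <- 1L
  pp <- toy_panel(vv, HH, pops = pops)
  cm <- select_variants(pp, "count_matched", pops = c("X", "Y", "Z"),
                        threshold = 0.5, seed = 3)
  expect_equal(vapply(cm, function(s) length(s$ids), 0L),
               c(X = 8L, Y = 8L, Z = 8L))
  expect_true(all(cm$X$ids %in% vv$id[1:10]))

  # personalized holds exactly the carried variants
  pers <- select_variants(p, "personalized", sample = p$samples$sample[1])
  expect_setequal(pers$ids, c("v001", "v002", "v003"))
  # personalized is a subset of the threshold(0) selection for the population
  thr0 <- select_variants(p, "threshold", pops = "A", threshold = 0)
  expect_true(all(pers$ids %in% thr0$ids))

  # random_pool respects n_target and errors beyond the pool size
  rp <- select_variants(p, "random_pool", n_target = 2, seed = 9)
  expect_length(rp$ids, 2)
  expect_error(select_variants(p, "random_pool", n_target = 99), "exceeds")

  # excluded samples' private alleles are removed before selection
  Hx <- matrix(0L, nrow = 100, ncol = 3)
  Hx[1:2, 1] <- 1L          # private to sample 1
  Hx[1:80, 2] <- 1L; Hx[5:80, 3] <- 1L
  px <- toy_panel(v, Hx, pops = rep("A", 50))
  ex <- select_variants(px, "threshold", pops = "A", threshold = 0,
                        exclude_samples = px$samples$sample[1])
  expect_setequal(ex$ids, c("v002", "v003"))
})

test_that("build_graph produces the expected toy bubbles", {
  ref <- toy_ref("ACGTACGT")
  # no variants: a single linear node
  g0 <- build_graph(ref, NULL, max_node_len = 32)
  expect_equal(nrow(g0$nodes), 1L)
  expect_equal(nrow(g0$edges), 0L)
  # SNP at offset 3, T->G
  g1 <- build_graph(ref, toy_vset(toy_variants(3, "T", "G")), 32)
  expect_equal(nrow(g1$nodes), 4L)
  expect_equal(nrow(g1$edges), 4L)
  expect_setequal(g1$nodes$seq, c("ACG", "T", "G", "ACGT"))
  # deletion of TA at offsets 3-4 (anchored at offset 2)
  g2 <- build_graph(ref, toy_vset(toy_variants(2, "GTA", "G")), 32)
  expect_equal(nrow(g2$nodes), 3L)
  expect_equal(nrow(g2$edges), 3L)
  expect_setequal(g2$nodes$seq, c("ACG", "TA", "CGT"))
  bypass <- g2$edges[g2$edges$to - g2$edges$from == 2L, ]
  expect_equal(nrow(bypass), 1L)
  # errors
  expect_error(build_graph(ref, toy_vset(toy_variants(7, "TA", "T"))),
               "out of range")
  expect_error(build_graph(ref, toy_vset(toy_variants(c(2, 3), c("GT", "T"),
                                                      c("G", "A")))),
               "overlapping")
})

test_that("backbone spells the reference and growth is monotone", {
  set.seed(11)
  ref <- generate_reference(5000, seed = 11, repeats = NULL)
  p <- simulate_population(ref, c(A = 10L), 60, seed = 12)
  prev_nodes <- prev_edges <- 0
  for (thr in c(0.5, 0.2, 0.05, 0)) {
    vs <- select_variants(p, "threshold", pops = "A", threshold = thr)
    g <- build_graph(ref, vs)
    spelled <- walk_sequence(g, g$backbone)
    expect_identical(spelled, ref$sequence)
    st <- graph_stats(g, k = 11, cap = 1e6)
    expect_gte(st$n_nodes, prev_nodes)
    expect_gte(st$n_edges, prev_edges)
    expect_gte(st$n_edges - st$n_nodes, prev_edges - prev_nodes)
    prev_nodes <- st$n_nodes; prev_edges <- st$n_edges
  }
  # empty graph of N backbone nodes: N - 1 edges, ratio below one
  g0 <- build_graph(ref, NULL)
  s0 <- graph_stats(g0, k = 11)
  expect_equal(s0$n_edges, s0$n_nodes - 1L)
  expect_lt(s0$edge_node_ratio, 1)
})

test_that("k-mer path counts match exhaustive enumeration", {
  ref <- toy_ref("ACGTACGT")
  g1 <- build_graph(ref, toy_vset(toy_variants(3, "T", "G")), 32)
  st <- graph_stats(g1, k = 3)
  expect_equal(st$n_nodes, 4L)
  expect_equal(st$n_edges, 4L)
  expect_equal(st$edge_node_ratio, 1.0)
  expect_equal(st$kmer_paths, oracle_kmer_paths(g1, 3))
  # random larger graphs
  set.seed(21)
  for (i in 1:5) {
    r <- toy_ref(random_dna(120))
    pos <- sort(sample(5:110, 4))
    pos <- pos[c(TRUE, diff(pos) > 6)]
    vs <- toy_vset(toy_variants(pos, substr(r$sequence, pos + 1, pos + 1),
                                vapply(pos, function(p)
                                  sample(setdiff(c("A", "C", "G", "T"),
                                                 substr(r$sequence, p + 1,
                                                        p + 1)), 1), "")))
    g <- build_graph(r, vs, max_node_len = 16)
    for (k in c(4, 9)) {
      expect_equal(graph_stats(g, k = k)$kmer_paths, oracle_kmer_paths(g, k),
                   info = sprintf("i=%d k=%d", i, k))
    }
  }
  # cap flags truncation
  capped <- graph_stats(g1, k = 3, cap = 2)
  expect_true(capped$capped)
})

test_that("haplotype walks spell their haplotype sequences", {
  set.seed(31)
  ref <- generate_reference(3000, seed = 31, repeats = NULL)
  p <- simulate_population(ref, c(A = 6L), 25, indel_fraction = 0.4,
                           max_indel = 8, seed = 32)
  vs <- select_variants(p, "threshold", pops = "A", threshold = 0)
  g <- build_graph(ref, vs)
  hi <- embed_haplotypes(g, p, p$samples$sample[1:3])
  for (s in p$samples$sample[1:3]) {
    for (h in 1:2) {
      hap <- extract_haplotype(ref, p, s, h)
      expect_identical(walk_sequence(g, hi[[paste0(s, "_h", h)]]),
                       hap$sequence)
    }
  }
  # reference-identical haplotype walks equal the backbone
  pr <- toy_panel(toy_variants(100, "A", "T"),
                  matrix(c(0L, 0L), nrow = 2), pops = "A")
  pr$variants$ref <- substr(ref$sequence, 101, 101)
  pr$variants$alt <- setdiff(c("A", "C", "G", "T"), pr$variants$ref)[1]
  gg <- build_graph(ref, toy_vset(pr$variants))
  ww <- embed_haplotypes(gg, pr, pr$samples$sample[1])
  expect_identical(ww[[1]], gg$backbone)
  # haplotype-restricted k-mers equal the k-mers of the walk sequences
  hs <- graph_stats(g, hapindex = hi[1], k = 21)
  hap1 <- extract_haplotype(ref, p, p$samples$sample[1], 1)$sequence
  expect_lte(hs$kmer_paths, nchar(hap1) - 21 + 1)
})

test_that("GFA output has consistent S, L and P lines", {
  ref <- toy_ref("ACGTACGTACGT")
  g <- build_graph(ref, toy_vset(toy_variants(5, "C", "T")), 4)
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "S")), nrow(g$nodes))
  expect_equal(sum(startsWith(lines, "L")), nrow(g$edges))
  expect_equal(sum(startsWith(lines, "P")), 1L)
  pline <- strsplit(grep("^P", lines, value = TRUE), "\t")[[1]]
  expect_equal(pline[3], paste0(g$backbone, "+", collapse = ","))
})
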