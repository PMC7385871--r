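test_that("generate_reference honours length, alphabet, GC and seed", {
  r <- generate_reference(1000, 0.42, seed = 1, repeats = NULL)
  expect_equal(r$length, 1000L)
  expect_equal(nchar(r$sequence), 1000L)
  expect_true(grepl("^[ACGT]+$", r$sequence))
  r2 <- generate_reference(1000, 0.42, seed = 1, repeats = NULL)
  expect_identical(r$sequence, r2$sequence)
  big <- generate_reference(100000, 0.42, seed = 1, repeats = NULL)
  gc <- mean(strsplit(big$sequence, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  se <- sqrt(0.42 * 0.58 / 100000)
  expect_lt(abs(gc - 0.42), 3 * se)
  expect_error(generate_reference(0), "positive")
})

test_that("repeat structure is recorded as annotations", {
  r <- generate_reference(50000, seed = 3)
  ann <- attr(r, "annotations")
  expect_true(nrow(ann) > 0)
  expect_setequal(unique(ann$label), c("repeat", "low_complexity"))
  expect_true(all(ann$end > ann$start))
  expect_true(all(ann$end <= r$length))
})

test_that("simulate_population meets its placement and frequency contracts", {
  ref <- generate_reference(100000, seed = 2, repeats = NULL)
  p0 <- simulate_population(ref, c(A = 5L), 0, seed = 1)
  expect_equal(nrow(p0$variants), 0L)
  expect_equal(ncol(p0$haplotypes), 0L)

  p <- simulate_population(ref, c(A = 20L, B = 20L), 500, seed = 7)
  v <- p$variants
  # non-overlapping reference intervals, sorted
  ends <- v$pos + nchar(v$ref)
  expect_true(all(v$pos[-1] >= ends[-nrow(v)]))
  # alleles anchored and classed correctly
  expect_true(all(nchar(v$ref[v$vclass == "SNP"]) == 1))
  expect_true(all(v$length_delta[v$vclass == "INS"] > 0))
  expect_true(all(v$length_delta[v$vclass == "DEL"] < 0))
  expect_true(all(substr(v$ref[v$vclass != "SNP"], 1, 1) ==
                  substr(v$alt[v$vclass != "SNP"], 1, 1)))
  expect_true(all(mapply(function(pos, r)
    substr(ref$sequence, pos + 1, pos + nchar(r)) == r, v$pos, v$ref)))
  # stored af equals af recomputed from haplotype columns, exactly
  expect_identical(p$af, panel_af(p))
  # every variant polymorphic in at least one population
  expect_true(all(colSums(p$haplotypes) > 0))
  # realized singleton proportion within 3 s.e. of the 14% default
  for (pop in c("A", "B")) {
    rows <- rep(p$samples$pop, each = 2) == pop
    j <- colSums(p$haplotypes[rows, , drop = FALSE])
    seg <- j > 0
    prop <- mean(j[seg] == 1)
    se <- sqrt(0.14 * 0.86 / sum(seg))
    expect_lt(abs(prop - 0.14), 3 * se)
  }
  # seeded reproducibility
  p2 <- simulate_population(ref, c(A = 20L, B = 20L), 500, seed = 7)
  expect_identical(p$haplotypes, p2$haplotypes)
  expect_identical(p$variants, p2$variants)
})

test_that("fully shared pools segregate in every population", {
  ref <- generate_reference(50000, seed = 4, repeats = NULL)
  p <- simulate_population(ref, c(A = 10L, B = 10L), 200,
                           shared_fraction = 1, seed = 5)
  hp <- rep(p$samples$pop, each = 2)
  jA <- colSums(p$haplotypes[hp == "A", , drop = FALSE])
  jB <- colSums(p$haplotypes[hp == "B", , drop = FALSE])
  expect_true(all(jA > 0 & jB > 0))
})

test_that("windowed nucleotide diversity matches the pairwise oracle", {
  # hand example: 4 haplotypes, one site with allele count 2
  v <- toy_variants(5000, "A", "C")
  H <- matrix(c(1L, 1L, 0L, 0L), ncol = 1)
  p <- toy_panel(v, H, pops = c("A", "A"))
  pi <- windowed_pi(p, "A", 10000)
  expect_equal(pi$pi, 2 * 2 * 2 / (4 * 3) / 10000)
  expect_equal(pi$pi, oracle_windowed_pi(p, "A", 10000)$pi)

  # 2 haplotypes, two singleton sites, window 100
  v2 <- toy_variants(c(10, 40), c("A", "G"), c("T", "C"))
  H2 <- matrix(c(1L, 0L, 0L, 1L), nrow = 2)
  p2 <- toy_panel(v2, H2, pops = "A")
  expect_equal(windowed_pi(p2, "A", 100)$pi, 0.02)

  # monomorphic window contributes zero
  expect_equal(windowed_pi(toy_panel(v, matrix(c(1L, 1L, 1L, 1L), ncol = 1),
                                     pops = c("A", "A")), "A", 10000)$pi, 0)

  # property: oracle equality on random panels, and window sums recover the
  # total per-site diversity
  set.seed(42)
  for (i in 1:10) {
    n_h <- 2 * sample(2:5, 1)
    n_v <- sample(5:50, 1)
    pos <- sort(sample.int(5000, n_v))
    vv <- toy_variants(pos, rep("A", n_v), rep("T", n_v))
    HH <- matrix(rbinom(n_h * n_v, 1, runif(1, 0.2, 0.8)), nrow = n_h)
    HH[1, colSums(HH) == 0] <- 1L  # keep polymorphic
    pp <- toy_panel(vv, HH, pops = rep("A", n_h / 2))
    w <- sample(c(500L, 1000L), 1)
    got <- windowed_pi(pp, "A", w)
    want <- oracle_windowed_pi(pp, "A", w)
    expect_equal(got$start, want$start)
    expect_equal(got$pi, want$pi, tolerance = 1e-12)
    j <- colSums(HH)
    expect_equal(sum(got$pi * w),
                 sum(2 * j * (n_h - j) / (n_h * (n_h - 1))),
                 tolerance = 1e-12)
  }
  expect_error(windowed_pi(p, "Z", 100), "unknown population")
})

test_that("truth genotypes derive from haplotypes and subset size holds", {
  v <- toy_variants(c(10, 20, 30), c("A", "C", "G"), c("T", "G", "A"))
  H <- matrix(c(1L, 1L, 0L, 1L, 0L, 0L), nrow = 2)  # sample1: 1/1, 0/1, 0/0
  p <- toy_panel(v, H, pops = "A")
  tr <- emulate_truth_sets(p, p$samples$sample[1], n_array_sites = 2, seed = 1)
  expect_equal(tr$genotypes$gt, c("1/1", "0/1", "0/0"))
  expect_length(tr$array_subset, 2)
  expect_true(all(tr$array_subset %in% v$id))
  expect_error(emulate_truth_sets(p, "nobody", 1), "unknown sample")
  expect_error(emulate_truth_sets(p, p$samples$sample[1], 99), "exceeds")
})
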