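mk_truth <- function(ids, starts) {
  tibble::tibble(id = ids, true_ref_start = starts,
                 contains_nonref = FALSE, region_labels = "")
}

mk_al <- function(ids, pos, mq = 60L, mapped = TRUE, nm = 0L, clip = 0L,
                  nsec = 0L) {
  tibble::tibble(id = ids, mapped = mapped,
                 ref_pos = ifelse(mapped, pos, NA_integer_),
                 MQ = ifelse(mapped, mq, NA_integer_),
                 edit_distance = ifelse(mapped, nm, NA_integer_),
                 soft_clip = ifelse(mapped, clip, NA_integer_),
                 n_secondary = ifelse(mapped, nsec, NA_integer_))
}

test_that("alignment classification applies the k-distance boundary", {
  tr <- mk_truth(c("a", "b", "c", "d"), c(1000L, 1000L, 1000L, 1000L))
  al <- mk_al(c("a", "b", "c", "d"), c(1000L, 1150L, 1151L, NA),
              mapped = c(TRUE, TRUE, TRUE, FALSE))
  ev <- classify_alignments(al, tr, k = 150)
  expect_equal(ev$correct, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(classify_alignments(mk_al("zz", 1L), tr), "missing")
  # brute-force agreement on random sets
  set.seed(91)
  ids <- sprintf("r%04d", 1:1000)
  truth <- mk_truth(ids, sample.int(1e6, 1000))
  alr <- mk_al(ids, truth$true_ref_start +
                 sample(c(-400:400), 1000, replace = TRUE),
               mapped = runif(1000) > 0.05)
  got <- classify_alignments(alr, truth, k = 150)
  want <- alr$mapped & !is.na(alr$ref_pos) &
    abs(alr$ref_pos - truth$true_ref_start) <= 150
  expect_equal(got$correct, unname(want))
})

test_that("pseudo-ROC accumulates per-bucket counts from MQ 60 down", {
  ev <- tibble::tibble(
    id = sprintf("r%02d", 1:10),
    correct = c(rep(TRUE, 8), FALSE, FALSE),
    mapped = TRUE,
    MQ = c(rep(60L, 6), 20L, 20L, 0L, 0L))
  roc <- pseudo_roc(ev)
  expect_equal(roc$threshold, c(60L, 50L, 40L, 30L, 20L, 10L, 0L))
  expect_equal(roc$TPR, c(0.6, 0.6, 0.6, 0.6, 0.8, 0.8, 0.8))
  expect_equal(roc$FPR[roc$threshold == 0], 0.2)
  # all correct at MQ 60
  ev2 <- tibble::tibble(id = "x", correct = TRUE, mapped = TRUE, MQ = 60L)
  roc2 <- pseudo_roc(ev2)
  expect_true(all(roc2$TPR == 1) && all(roc2$FPR == 0))
  # with every read mapped, TPR_0 + FPR_0 = 1
  expect_equal(roc$TPR[7] + roc$FPR[7], 1)
  # buckets are [k, next threshold): MQ 55 belongs to bucket 50
  ev3 <- tibble::tibble(id = c("a", "b"), correct = TRUE, mapped = TRUE,
                        MQ = c(55L, 60L))
  roc3 <- pseudo_roc(ev3)
  expect_equal(roc3$TPR[roc3$threshold == 60], 0.5)
  expect_equal(roc3$TPR[roc3$threshold == 50], 1.0)
  expect_error(pseudo_roc(ev[0, ]), "empty")
})

test_that("mapping summary applies the perfect and unique definitions", {
  ids <- sprintf("r%02d", 1:10)
  al <- mk_al(ids, rep(100L, 10))
  al$soft_clip[1] <- 5L                     # clipped: not perfect
  ev <- classify_alignments(al, mk_truth(ids, rep(100L, 10)), 150)
  sm <- mapping_summary(al, ev)
  expect_equal(sm$prop_perfect, 0.9)
  # secondary hits with MQ 60 still count as uniquely mapped
  al$n_secondary[2] <- 2L
  sm2 <- mapping_summary(al, ev)
  expect_equal(sm2$prop_unique, 1.0)
  al$MQ[2] <- 30L
  expect_equal(mapping_summary(al, ev)$prop_unique, 0.9)
  # unmapped reads count into the error rate
  al$mapped[3] <- FALSE
  ev3 <- classify_alignments(al, mk_truth(ids, rep(100L, 10)), 150)
  expect_equal(mapping_summary(al, ev3)$error_rate, 0.1)
})

test_that("allelic ratios bin by signed length and flag empty sites", {
  pu <- tibble::tibble(pos = c(10L, 20L, 30L, 40L),
                       AD_ref = c(10L, 5L, 3L, 0L),
                       AD_alt = c(10L, 15L, 9L, 0L))
  het <- tibble::tibble(pos = c(10L, 20L, 30L, 40L),
                        length_delta = c(-3L, 0L, 5L, 5L))
  expect_message(prof <- allelic_ratio_profile(pu, het, TRUE), "skipped")
  expect_equal(sort(prof$length), c(-3L, 0L, 5L))
  expect_equal(prof$mean_ratio[prof$length == -3], 0.5)
  expect_equal(prof$mean_ratio[prof$length == 0], 0.75)
  expect_equal(prof$n_sites[prof$length == 5], 1L)
})

test_that("concordance metrics match the rational-arithmetic oracle", {
  cm <- matrix(c(8L, 1L, 0L, 1L, 6L, 1L, 0L, 1L, 7L), 3, 3, byrow = TRUE)
  rc <- realise_confusion(cm)
  got <- concordance_metrics(rc$calls, rc$truth)
  expect_equal(got$genotype_concordance, 21 / 25)
  expect_equal(got$nr_discrepancy, 4 / 17)
  expect_equal(got$nr_sensitivity, 13 / 16)
  expect_equal(got$precision, 13 / 16)
  expect_equal(unname(got$confusion), unname(cm))
  # perfect agreement
  eye <- diag(c(5L, 5L, 5L))
  rce <- realise_confusion(eye)
  ge <- concordance_metrics(rce$calls, rce$truth)
  expect_equal(ge$genotype_concordance, 1)
  expect_equal(ge$nr_discrepancy, 0)
  # truth het called hom-alt counts against concordance, not detection
  cm2 <- matrix(c(5L, 0L, 0L, 0L, 4L, 1L, 0L, 0L, 5L), 3, 3, byrow = TRUE)
  rc2 <- realise_confusion(cm2)
  g2 <- concordance_metrics(rc2$calls, rc2$truth)
  expect_equal(g2$nr_sensitivity, 9 / 10)
  expect_lt(g2$genotype_concordance, 1)
  expect_gt(g2$nr_discrepancy, 0)
  # random matrices against the oracle
  set.seed(92)
  for (i in 1:20) {
    m <- matrix(as.integer(sample(0:9, 9, replace = TRUE)), 3, 3)
    if (sum(m) == 0 || sum(m) == m[1, 1] || sum(m[2:3, ]) == 0 ||
        sum(m[, 2:3]) == 0) next
    rr <- realise_confusion(m)
    got <- concordance_metrics(rr$calls, rr$truth)
    want <- oracle_concordance(m)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]],
                                         info = paste("matrix", i, nm))
  }
  expect_error(concordance_metrics(tibble::tibble(id = "x", genotype = "0/1"),
                                   rc$truth, positions = character(0)),
               "empty")
})
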