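test_that("peak fold filter is strict and guards the score column", {
  pk <- data.frame(chrom = "c1", start = c(0, 100, 200),
                   end = c(50, 150, 250), score = c(4.0, 4.1, 12))
  out <- filter_peaks_by_fold(pk, 4)
  expect_equal(out$start, c(100, 200))
  expect_equal(nrow(filter_peaks_by_fold(pk, 50)), 0)
  pk$score <- NULL
  expect_error(filter_peaks_by_fold(pk), "score")
  expect_equal(filter_peaks_by_fold(pk, require_score = FALSE), pk)
})

test_that("exclusive open regions match the hand-segmented two-peak example", {
  sets <- list(A = data.frame(chrom = "c1", start = 0L, end = 500L),
               B = data.frame(chrom = "c1", start = 400L, end = 900L))
  ex <- exclusive_open_regions(sets, min_len = 100)
  expect_equal(ex$A, data.frame(chrom = "c1", start = 0L, end = 400L))
  expect_equal(ex$B, data.frame(chrom = "c1", start = 500L, end = 900L))

  ## short exclusive segment discarded
  sets2 <- list(A = data.frame(chrom = "c1", start = 0L, end = 480L),
                B = data.frame(chrom = "c1", start = 400L, end = 900L))
  ex2 <- exclusive_open_regions(sets2, min_len = 100)
  expect_equal(ex2$A, data.frame(chrom = "c1", start = 0L, end = 400L))
  ## identical peaks in all cell types leave nothing exclusive
  same <- data.frame(chrom = "c1", start = c(0L, 600L), end = c(500L, 700L))
  ex3 <- exclusive_open_regions(list(A = same, B = same, C = same))
  expect_true(all(vapply(ex3, nrow, 1L) == 0))
})

test_that("exclusive regions are pairwise disjoint and avoid other cell types' peaks", {
  toy <- toy_fixture()
  sim <- simulate_open_regions(toy, fold = 3, n_regions = 150, seed = 17)
  peaks <- lapply(sim$peak_sets, filter_peaks_by_fold, min_fold = 4)
  ex <- exclusive_open_regions(peaks, min_len = 100)
  expect_true(all(ex$cellA$end - ex$cellA$start >= 100))
  ab <- GenomicRanges::intersect(
    GenomicRanges::GRanges(ex$cellA$chrom,
                           IRanges::IRanges(ex$cellA$start + 1, ex$cellA$end)),
    GenomicRanges::GRanges(ex$cellB$chrom,
                           IRanges::IRanges(ex$cellB$start + 1, ex$cellB$end)))
  expect_equal(length(ab), 0L)
  ## A-exclusive regions never touch B's peaks
  hits <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(ex$cellA$chrom,
                           IRanges::IRanges(ex$cellA$start + 1, ex$cellA$end)),
    GenomicRanges::GRanges(peaks$cellB$chrom,
                           IRanges::IRanges(peaks$cellB$start + 1,
                                            peaks$cellB$end)))
  expect_true(all(hits == 0))
})

test_that("enrichment scores and binomial tails follow the stated formulas", {
  ## score arithmetic: observed 10, expected 2 -> log2(5)
  toy <- toy_fixture()
  part <- partition_fixture()
  sim <- simulate_open_regions(toy, fold = 5, n_regions = 150, seed = 23)
  enr <- te_subfamily_enrichment(filter_peaks_by_fold(sim$peak_sets$cellA, 4),
                                 toy$te_table, part, toy$chrom_sizes,
                                 n_shuffles = 50, seed = 31)
  expect_true(all(enr$expected >= 1))
  expect_equal(enr$score, log2(pmax(enr$observed, 1) / enr$expected))
  expect_true(all(is.finite(enr$score)))
  ## exact binomial tails against term-wise summation
  g <- enr$direction == "greater"
  p0 <- pmin(enr$expected / enr$total, 1)
  for (i in which(g)) {
    expect_equal(enr$p[i],
                 oracle_binom_upper(enr$observed[i], enr$total[i], p0[i]))
  }
  for (i in which(!g)) {
    expect_equal(enr$p[i],
                 oracle_binom_lower(enr$observed[i], enr$total[i], p0[i]))
  }
})

test_that("a 5x planted subfamily is top-scored; null data stays null", {
  toy <- toy_fixture()
  part <- partition_fixture()
  sim <- simulate_open_regions(toy, fold = 5, n_regions = 200, seed = 3)
  enr <- te_subfamily_enrichment(filter_peaks_by_fold(sim$peak_sets$cellA, 4),
                                 toy$te_table, part, toy$chrom_sizes,
                                 n_shuffles = 200, seed = 11)
  expect_equal(enr$subfamily[1], "LTR5S")
  expect_lt(enr$p[1], 0.01)

  null <- simulate_open_regions(toy, fold = 1, n_regions = 200, seed = 5)
  enr0 <- te_subfamily_enrichment(filter_peaks_by_fold(null$peak_sets$cellA, 4),
                                  toy$te_table, part, toy$chrom_sizes,
                                  n_shuffles = 200, seed = 12)
  expect_gte(mean(enr0$p > 0.05), 0.95)
})

test_that("interval RPM counts overlap-by-1bp reads and normalizes per library", {
  targets <- data.frame(chrom = "c1", start = c(100L, 1000L),
                        end = c(200L, 1100L))
  reads <- data.frame(chrom = "c1",
                      start = c(90L, 150L, 199L, 200L, 5000L),
                      end = c(110L, 160L, 210L, 250L, 5050L))
  sig <- interval_rpm_signal(list(s1 = reads), targets)
  expect_equal(sig[, "s1"], c(3, 0) / (5 / 1e6))
  ## duplicating reads doubles counts but RPM is unchanged
  sig2 <- interval_rpm_signal(list(s1 = rbind(reads, reads)), targets)
  expect_equal(sig2, sig)
})

test_that("Welch test matches stats::t.test and handles degenerate input", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- compare_groups_welch(a, b)
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$p, ref$p.value)
  expect_equal(w$df, unname(ref$parameter))
  ## swap negates t, preserves p
  w2 <- compare_groups_welch(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  ## identical constant groups
  expect_equal(compare_groups_welch(c(2, 2), c(2, 2))$p, 1)
  expect_equal(compare_groups_welch(c(2, 2), c(3, 3))$p, 0)
})

test_that("motif occurrence ratios use the pseudo-occurrence and rank by ratio", {
  q <- data.frame(chrom = "c1", start = seq(0, 2900, 100), end = seq(50, 2950, 100))
  ctrl <- data.frame(chrom = "c1", start = seq(10000, 12900, 100),
                     end = seq(10050, 12950, 100))
  site <- function(starts) data.frame(chrom = "c1", start = starts,
                                      end = starts + 10)
  motifs <- list(
    hot = site(c(seq(0, 2900, 100)[1:30], seq(10000, 12900, 100)[1:10])),
    none = site(seq(11000, 11800, 100)),
    both = site(c(0, 10000)))
  out <- motif_occurrence_enrichment(q, motifs, ctrl, top_k = 2)
  expect_equal(out$motif[1], "hot")
  expect_equal(out$ratio[1], 31 / 11)
  expect_equal(nrow(out), 2)
  ## identical query and control -> all ratios 1
  out2 <- motif_occurrence_enrichment(q, motifs, q)
  expect_true(all(out2$ratio == 1))
})
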