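test_that("toy genome generation is a pure function of (config, seed)", {
  cfg <- toy_genome_config(chrom_lengths = c(tc1 = 3e5, tc2 = 3e5),
                           n_genes = 30)
  cfg$roster$n_copies <- c(12L, 4L, 8L, 3L, 30L, 8L, 5L, 8L)
  cfg$roster$n_proviral <- c(4L, NA, 3L, NA, NA, NA, NA, NA)
  a <- build_toy_genome(cfg, seed = 5)
  b <- build_toy_genome(cfg, seed = 5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$te_table, b$te_table)
  expect_identical(a$genes$genes, b$genes$genes)
  c <- build_toy_genome(cfg, seed = 6)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
  ## truth bookkeeping equals config
  expect_equal(as.vector(table(a$te_table$subfamily)[cfg$roster$subfamily]),
               cfg$roster$n_copies)
})

test_that("planted elements do not overlap and genes sit in TE-free space", {
  toy <- toy_fixture()
  everything <- rbind(toy$te_table[, c("chrom", "start", "end")],
                      toy$genes$genes[, c("chrom", "start", "end")])
  gr <- GenomicRanges::GRanges(everything$chrom,
                               IRanges::IRanges(everything$start + 1,
                                                everything$end))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))
})

test_that("TE copies carry recognizable subfamily sequence identity", {
  toy <- toy_fixture()
  cons <- toy$truth$consensus
  copies <- toy$te_table[toy$te_table$subfamily == "LTR5S", ][1:5, ]
  seqs <- fetch_sequence(toy$genome, copies)
  for (s in seqs) {
    ident <- mean(strsplit(s, "")[[1]] == strsplit(cons[["LTR5S"]], "")[[1]])
    expect_gt(ident, 0.9)  # 5% divergence rate
  }
})

test_that("simulated counts honour the planted design and recover size factors", {
  design <- setNames(rep(c("ctrl", "trt"), each = 3), paste0("s", 1:6))
  sim <- simulate_counts(design, n_features = 1000, planted_fc = 8,
                         dispersion = 0.05, seed = 77)
  expect_identical(sim$counts, simulate_counts(design, n_features = 1000,
                                               planted_fc = 8,
                                               dispersion = 0.05,
                                               seed = 77)$counts)
  expect_equal(length(sim$truth$planted), 50)
  ## median-of-ratios recovers the simulated library-size factors within 5%
  sf <- size_factors(sim$counts)
  truth_sf <- sim$truth$sample_factors
  truth_sf <- truth_sf / exp(mean(log(truth_sf)))
  expect_true(all(abs(sf / truth_sf - 1) < 0.05))
  ## planted_fc = 1 plants nothing
  expect_equal(length(simulate_counts(design, n_features = 100,
                                      planted_fc = 1, seed = 1)$truth$planted), 0)
})

test_that("planted subfamily concentration puts differential copies where asked", {
  toy <- toy_fixture()
  design <- setNames(rep(c("es", "pgclc"), each = 3), paste0("s", 1:6))
  sim <- simulate_counts(design, te_table = toy$te_table, planted_fc = 8,
                         planted_frac = 0.05, planted_subfamily = "LTR5S",
                         seed = 15)
  planted_sub <- toy$te_table$subfamily[match(sim$truth$planted,
                                              te_copy_id(toy$te_table))]
  expect_true("LTR5S" %in% planted_sub)
  expect_equal(sum(planted_sub == "LTR5S"),
               min(sum(toy$te_table$subfamily == "LTR5S"),
                   length(sim$truth$planted)))
})

test_that("simulated methylomes place CG sites on genomic CG dinucleotides", {
  toy <- toy_fixture()
  meth <- simulate_methylomes(toy, coverage_mean = 30, seed = 3,
                              chroms = "chrTB")
  idx <- sample(nrow(meth$a), 50)
  dinucs <- fetch_sequence(toy$genome,
                           data.frame(chrom = meth$a$chrom[idx],
                                      start = meth$a$pos[idx],
                                      end = meth$a$pos[idx] + 2L))
  expect_true(all(dinucs == "CG"))
  expect_true(all(meth$a$count_m <= meth$a$count_total))
  ## planted drop shows up in condition B over the planted copies:
  ## mean level across copies tracks base_level - delta closely
  lvl_b <- region_methylation(meth$truth$planted,
                              filter_min_coverage(meth$b, 3))
  lvl_a <- region_methylation(meth$truth$planted,
                              filter_min_coverage(meth$a, 3))
  expect_lt(abs(mean(lvl_b, na.rm = TRUE) - 0.2), 0.03)
  expect_lt(abs(mean(lvl_a, na.rm = TRUE) - 0.8), 0.03)
})

test_that("null methylomes (delta = 0) yield essentially no DMR calls", {
  toy <- toy_fixture()
  meth <- simulate_methylomes(toy, delta = 0, coverage_mean = 30, seed = 8,
                              chroms = "chrTB")
  dmrs <- call_dmrs(meth$a, meth$b)
  n_tested <- nrow(attr(dmrs, "tested"))
  expect_gt(n_tested, 1000)
  ## BH at 0.05 with no signal: expected false calls near zero
  expect_lte(nrow(dmrs), max(3, 0.001 * n_tested))
})

test_that("guide planting writes exactly-k-mismatch variants on the requested strand", {
  toy <- toy_fixture()
  g <- ltr5hs_guides()
  pl <- plant_guide_sites(toy$genome, g$pattern[1], mismatches = c(0, 3),
                          strands = c("-", "-"), seed = 21)
  tr <- pl$truth
  expect_equal(tr$strand, c("-", "-"))
  for (i in 1:2) {
    written <- fetch_sequence(pl$genome, tr[i, c("chrom", "start", "end")])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tr$planted_seq[i])))
    expect_equal(written, rc)
    ## Hamming distance to the pattern at concrete positions is exactly k
    pat <- strsplit(g$pattern[1], "")[[1]]
    var <- strsplit(tr$planted_seq[i], "")[[1]]
    concrete <- pat %in% c("A", "C", "G", "T")
    expect_equal(sum(pat[concrete] != var[concrete]), tr$mismatches[i])
  }
})

test_that("simulated peak scores separate plantable and decoy peaks", {
  toy <- toy_fixture()
  sim <- simulate_open_regions(toy, fold = 5, n_regions = 100, seed = 41)
  pk <- sim$peak_sets$cellA
  expect_true(any(pk$score <= 4))
  kept <- filter_peaks_by_fold(pk, 4)
  expect_true(all(kept$score > 4))
  expect_true(all(pk$planted[pk$score > 4.5] %in% c(TRUE, FALSE)))
  ## zero regions -> only decoys, planted none
  sim0 <- simulate_open_regions(toy, fold = 5, n_regions = 0, decoy_frac = 0,
                                seed = 2)
  expect_equal(nrow(sim0$peak_sets$cellA), 0)
})
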