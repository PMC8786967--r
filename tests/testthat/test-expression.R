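design6 <- setNames(rep(c("ctrl", "trt"), each = 3), paste0("s", 1:6))

test_that("RPKM and RPM satisfy their unit cases and scaling laws", {
  counts <- matrix(c(10, 0, 5, 20), nrow = 2,
                   dimnames = list(c("f1", "f2"), c("a", "b")))
  r <- rpkm(counts, lengths = c(f1 = 1000, f2 = 2000),
            library_sizes = c(1e6, 1e6))
  expect_equal(r["f1", "a"], 10)
  expect_equal(r["f2", "a"], 0)
  r2 <- rpkm(counts, c(f1 = 1000, f2 = 2000), c(2e6, 2e6))
  expect_equal(r2, r / 2)
  expect_error(rpkm(counts, c(f1 = 1000, f2 = 2000), c(0, 1e6)), "> 0")

  m <- rpm(counts, c(1e6, 1e6))
  expect_equal(m["f1", "b"], 5)
  expect_equal(rpm(counts, c(2e6, 2e6)), m / 2)
})

test_that("expressed-feature filter keeps a feature iff a group mean exceeds 1 strictly", {
  rm <- rbind(kept = c(0.5, 0.5, 0.5, 1.2, 1.2, 1.2),
              dropped = c(0.5, 0.5, 0.5, 0.9, 0.9, 0.9),
              boundary = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0))
  colnames(rm) <- names(design6)
  expect_equal(filter_expressed(rm, design6), "kept")
})

test_that("size factors match the hand-computed median-of-ratios example", {
  counts <- matrix(c(10, 100, 20, 200), nrow = 2,
                   dimnames = list(c("f1", "f2"), c("a", "b")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  ## identical columns -> all factors 1
  eq <- matrix(c(5, 9, 5, 9), nrow = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(size_factors(eq)), c(1, 1))
  ## single sample -> 1
  expect_equal(unname(size_factors(matrix(1:3, ncol = 1,
                                          dimnames = list(NULL, "a")))), 1)
  ## no all-nonzero feature -> library-size fallback with warning
  z <- matrix(c(0, 4, 4, 0), nrow = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(sfz <- size_factors(z), "library-size")
  expect_equal(unname(sfz), c(1, 1))
})

test_that("NB test is null-centred on identical groups and label-symmetric", {
  counts <- matrix(rep(c(30L, 80L, 5L), 6), nrow = 3, byrow = FALSE,
                   dimnames = list(paste0("f", 1:3), names(design6)))
  res <- nb_differential(counts, design6)
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$p > 0.999))

  sim <- simulate_counts(design6, n_features = 300, planted_fc = 8,
                         planted_frac = 0.1, dispersion = 0.05, seed = 21)
  r1 <- nb_differential(sim$counts, design6)
  r2 <- nb_differential(sim$counts, design6, ref = "trt")
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p, r2$p)
})

test_that("planted strong fold changes are detected at the 4-fold/FDR 0.05 cut", {
  sim <- simulate_counts(design6, n_features = 500, planted_fc = 8,
                         planted_frac = 0.05, dispersion = 0.05, seed = 13)
  res <- call_differential(nb_differential(sim$counts, design6),
                           fold_threshold = 4, fdr_threshold = 0.05)
  called <- res$feature[res$call == "up"]
  expect_gte(mean(sim$truth$planted %in% called), 0.8)
  expect_lte(mean(!(called %in% sim$truth$planted)), 0.1)
})

test_that("differential calls apply thresholds exactly", {
  tab <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(2.1, 2.1, -0.6, 0.3),
                    padj = c(0.01, 0.06, 0.001, 0.001))
  expect_equal(call_differential(tab, 4, 0.05)$call, c("up", "ns", "ns", "ns"))
  expect_equal(call_differential(tab, 1.5, 0.05)$call,
               c("up", "ns", "down", "ns"))
  pr <- call_proportions(c("up", "down", "down", "ns", "down", "down"))
  expect_equal(pr$n, c(1L, 4L))
  expect_equal(pr$percent, c(20, 80))
})

test_that("BH adjustment agrees with brute-force step-up on random p-vectors", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      p <- runif(sample(1:100, 1))^2
      expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
    }
  })
})

test_that("subfamily ranking applies the 80-copy/8-DETE filters and proportions", {
  te <- data.frame(
    chrom = "c1",
    start = seq(0, by = 1000, length.out = 350),
    end = seq(0, by = 1000, length.out = 350) + 500,
    strand = "+",
    subfamily = rep(c("BIG", "SMALL", "FEWDETE"), c(100, 50, 200)),
    family = "F", class = "LTR", stringsAsFactors = FALSE)
  calls <- data.frame(feature = te_copy_id(te), call = "ns",
                      stringsAsFactors = FALSE)
  calls$call[1:20] <- "up"            # BIG: 20/100 up
  calls$call[101:120] <- "up"         # SMALL: 20/50 but only 50 copies
  calls$call[151:157] <- "up"         # FEWDETE: 7 DETEs only
  rk <- rank_subfamily_dete_proportion(calls, te, min_copies = 80,
                                       min_dete = 8, top_k = 10)
  expect_equal(rk$summary$subfamily, "BIG")
  expect_equal(rk$summary$prop_up, 0.2)
  expect_equal(rk$up$subfamily, "BIG")
})

test_that("top-variance selection picks highest-variance rows and z-scores them", {
  m <- rbind(flat = c(5, 5, 5),
             big = c(0, 10, 20),
             mid = c(1, 2, 3))
  colnames(m) <- c("x", "y", "z")
  z <- top_variance_subfamilies(m, k = 2)
  expect_equal(rownames(z), c("big", "mid"))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
  expect_warning(zz <- top_variance_subfamilies(m, k = 5), "keeping all")
  expect_equal(unname(zz["flat", ]), c(0, 0, 0))
})

test_that("subfamily aggregation conserves count mass", {
  toy <- toy_fixture()
  sim <- simulate_counts(design6, te_table = toy$te_table, planted_fc = 4,
                         seed = 3)
  agg <- aggregate_subfamily(sim$counts, toy$te_table)
  expect_equal(colSums(agg), colSums(sim$counts))
  expect_equal(nrow(agg), length(unique(toy$te_table$subfamily)))
  ## two named copies add up
  two <- sim$counts[1:2, , drop = FALSE]
  sub2 <- toy$te_table[match(rownames(two), te_copy_id(toy$te_table)), ]
  agg2 <- aggregate_subfamily(two, toy$te_table)
  for (s in unique(sub2$subfamily)) {
    expect_equal(agg2[s, ],
                 colSums(two[sub2$subfamily == s, , drop = FALSE]))
  }
  bad <- two
  rownames(bad)[1] <- "nonexistent"
  expect_error(aggregate_subfamily(bad, toy$te_table), "nonexistent")
})

test_that("solo/proviral classification reproduces the planted toy-genome roles", {
  toy <- toy_fixture()
  roles <- toy$truth$ltr_roles
  for (cfg in list(c(sub = "LTR5S", int = "ERVKI", d = 100),
                   c(sub = "LTR7S", int = "ERVHI", d = 10))) {
    ltr <- toy$te_table[toy$te_table$subfamily == cfg[["sub"]], ]
    int <- toy$te_table[toy$te_table$subfamily == cfg[["int"]], ]
    cls <- classify_solo_ltr(ltr, int, max_distance = as.numeric(cfg[["d"]]))
    truth <- roles[roles$subfamily == cfg[["sub"]], ]
    key <- paste(truth$chrom, truth$start)
    expect_equal(cls$ltr_class,
                 truth$role[match(paste(cls$chrom, cls$start), key)])
  }
})
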