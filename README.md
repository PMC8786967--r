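# teregkit

Toolkit for quantifying the regulatory activity of transposable-element
(TE) subfamilies between cell states — written for epigenomics and
regulatory-genomics analysts who work with RepeatMasker-style TE
annotations, peak sets, bisulfite count tables and copy-level count
matrices, and who need the bespoke statistics of TE biology rather than
generic genomics plumbing.

## What it computes

* **Copy-level differential TE expression.** Median-of-ratios
  normalization, an expressed-feature filter (mean RPKM > 1 in a group),
  and a self-contained negative-binomial Wald test; TE copies are called
  at ≥ 4-fold and FDR < 0.05 (genes at ≥ 1.5-fold). Subfamilies are
  ranked by the *proportion* of copies called differential
  (DETE/total), with minimum-copy and minimum-DETE filters, because
  absolute DETE counts just track subfamily size.
* **Solo vs proviral LTR classification.** An LTR copy is proviral when
  its distance to the nearest internal proviral sequence — overlap = 0,
  bookended = 1, else gap + 1 — is within a threshold (100 bp for
  LTR5Hs/HERVK, 10 bp for LTR7/HERVH).
* **TE enrichment in open chromatin with a distribution-matched null.**
  The genome is partitioned into 7 categories (promoter, TTS, exon,
  intron, ≤ 10 kb proximal, 10–100 kb distal, > 100 kb intergenic);
  observed regions are shuffled so each keeps its length, chromosome and
  midpoint category. Enrichment score = log2(observed/expected) with
  expected floored at 1; significance by one-sided exact binomial test
  over the subfamily's copies.
* **Fixed-bin DMR calling.** 200 bp bins, ≥ 4 CGs at ≥ 3 reads in both
  conditions, two-sided Fisher exact test on pooled counts, |Δ| ≥ 0.2
  and FDR < 0.05, same-direction merging within 100 bp; plus pooled
  region methylation and strand-aware scaled metaprofiles.
* **CRISPRi guide target scanning.** Both-strand, every-offset scanning
  of guide+PAM degenerate patterns with a Hamming mismatch budget
  (default ≤ 3), and single-category annotation by the priority
  promoter > exon > TE > intron > intergenic.
* **Region-associated DEG (RAD) analysis.** Upper-tail hypergeometric
  tests of DEG TSS concentration in regions extended by nested distances
  (0–1,000 kb), plus generic DEG-set overlap testing.
* **A seeded toy-genome simulator** that plants every effect above with
  a truth manifest, so the whole pipeline is testable offline.

## Worked example

```r
library(teregkit)

toy    <- build_toy_genome(seed = 1)                    # 3 x 2 Mb, planted TEs
design <- setNames(rep(c("hESC", "hPGCLC"), each = 3), paste0("s", 1:6))

## plant 8-fold up-regulation concentrated in the LTR5S subfamily
sim <- simulate_counts(design, te_table = toy$te_table, planted_fc = 8,
                       planted_frac = 0.09, planted_subfamily = "LTR5S",
                       dispersion = 0.05, seed = 2)
expressed <- filter_expressed(rpkm(sim$counts, sim$lengths), design)
dete <- call_differential(nb_differential(sim$counts[expressed, ], design),
                          fold_threshold = 4, fdr_threshold = 0.05)
call_proportions(dete)
#>   direction  n percent
#> 1        up 58     100
#> 2      down  0       0

rank_subfamily_dete_proportion(dete, toy$te_table,
                               min_copies = 50, min_dete = 8)$up
#>   subfamily total n_up prop_up
#> 1     LTR5S    55   55       1
```

All 58 differential copies are up-regulated, and the proportional ranking
puts the planted subfamily first with every one of its 55 copies called.
The same toy genome drives the chromatin side:

```r
part <- partition_genome(toy$genes, toy$chrom_sizes)
ors  <- simulate_open_regions(toy, fold = 5, n_regions = 200, seed = 3)
enr  <- te_subfamily_enrichment(filter_peaks_by_fold(ors$peak_sets$cellA, 4),
                                toy$te_table, part, toy$chrom_sizes,
                                n_shuffles = 200, seed = 4)
head(enr[, c("subfamily", "total", "observed", "expected", "score", "p")], 3)
#>   subfamily total observed expected     score            p
#> 1     LTR5S    55       15    2.850 2.3959287 8.538423e-08
#> 2     ERVHI    15        2    1.050 0.9296107 2.831530e-01
#> 3      SVAT    50        4    3.035 0.3983035 3.607860e-01
```

Fifteen of 55 LTR5S copies intersect the planted open regions against
2.85 expected under the stratified-shuffle null (score ≈ 2.4, i.e. about
5-fold enrichment; binomial p ≈ 9e-8), while background subfamilies stay
at their expectation. Finally, the planted proviral structure is
recovered exactly:

```r
ltr  <- subset(toy$te_table, subfamily == "LTR5S")
ervk <- subset(toy$te_table, subfamily == "ERVKI")
table(classify_solo_ltr(ltr, ervk, max_distance = 100)$ltr_class)
#> proviral     solo
#>       20       35
```

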