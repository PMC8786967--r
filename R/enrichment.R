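## Cell-type-exclusive open regions from peak sets, TE-subfamily enrichment
## against the stratified-shuffle null, interval signal quantification and
## motif-occurrence enrichment.

#' Filter peaks by fold enrichment
#'
#' Keeps peaks whose fold-enrichment score is strictly greater than
#' `min_fold` (the peak-caller output filter applied before deriving open
#' regions).
#'
#' @param peaks interval data.frame with a `score` column holding fold
#'   enrichment.
#' @param min_fold cutoff (strict `>`).
#' @param require_score error when the score column is absent (set FALSE to
#'   pass peaks through unfiltered).
#' @return filtered data.frame.
#' @export
filter_peaks_by_fold <- function(peaks, min_fold = 4, require_score = TRUE) {
  if (is.null(peaks$score) || anyNA(peaks$score)) {
    if (require_score) stop("peaks lack a usable fold-enrichment score column")
    return(peaks)
  }
  out <- peaks[peaks$score > min_fold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cell-type-exclusive open regions
#'
#' Segments the genome at all peak boundaries (a multi-intersection) and
#' assigns a segment to cell type T iff it is covered by T's peaks and by
#' no other cell type's. Adjacent same-type segments are merged and
#' segments shorter than `min_len` are discarded.
#'
#' @param peak_sets named list (>= 2 cell types) of interval data.frames.
#' @param min_len minimum region length in bp to keep.
#' @return named list of exclusive-region data.frames, one per cell type.
#' @export
exclusive_open_regions <- function(peak_sets, min_len = 100) {
  if (length(peak_sets) < 2) stop("need peak sets for >= 2 cell types")
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    stop("peak_sets must be a named list")
  }
  red <- lapply(peak_sets, function(p) GenomicRanges::reduce(.as_gr(p)))
  all_gr <- GenomicRanges::disjoin(do.call(c, unname(red)))
  cov <- vapply(red, function(r) {
    GenomicRanges::countOverlaps(all_gr, r, ignore.strand = TRUE) > 0L
  }, logical(length(all_gr)))
  cov <- matrix(cov, nrow = length(all_gr))
  excl <- rowSums(cov) == 1L
  out <- lapply(seq_along(peak_sets), function(j) {
    segs <- GenomicRanges::reduce(all_gr[excl & cov[, j]])
    segs <- segs[GenomicRanges::width(segs) >= min_len]
    .gr_to_df(segs)
  })
  names(out) <- names(peak_sets)
  out
}

#' TE-subfamily enrichment in a region set
#'
#' For every TE subfamily, compares the observed number of distinct copies
#' intersecting the query regions with the number expected under a
#' stratified-shuffle null that preserves each region's length, chromosome
#' and midpoint genomic category. The expectation is the mean intersected
#' count over `n_shuffles` shuffled sets, floored at 1; the enrichment
#' score is `log2(observed / expected)` (with observed floored at 1 for the
#' score only); the p-value is a one-sided exact binomial test treating
#' each copy of the subfamily as an independent trial of being hit, with
#' success probability `min(expected / total, 1)`.
#'
#' @param query_regions interval data.frame.
#' @param te_table TE annotation.
#' @param partition `category_partition` covering the genome.
#' @param chrom_sizes named chromosome lengths.
#' @param n_shuffles number of stratified shuffles for the null.
#' @param seed integer seed for the shuffles.
#' @return data.frame (subfamily, total, observed, expected, score, p,
#'   direction, observed_zero), sorted by decreasing score.
#' @export
te_subfamily_enrichment <- function(query_regions, te_table, partition,
                                    chrom_sizes, n_shuffles = 1000, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  te_gr <- .as_gr(te_table)
  subfam <- te_table$subfamily
  total <- table(subfam)
  count_hits <- function(region_gr) {
    hit <- GenomicRanges::countOverlaps(te_gr, region_gr,
                                        ignore.strand = TRUE) > 0L
    table(factor(subfam[hit], levels = names(total)))
  }
  observed <- count_hits(.as_gr(query_regions))
  shuf <- stratified_shuffle(query_regions, partition, chrom_sizes,
                             n_shuffles = n_shuffles, seed = seed)
  ## one overlap pass over all shuffles, then distinct copies per
  ## (subfamily, shuffle)
  shuf_gr <- .as_gr(shuf)
  hits <- GenomicRanges::findOverlaps(te_gr, shuf_gr, ignore.strand = TRUE)
  pair <- unique(data.frame(copy = S4Vectors::queryHits(hits),
                            shuffle = shuf$shuffle[S4Vectors::subjectHits(hits)]))
  exp_counts <- table(factor(subfam[pair$copy], levels = names(total)))
  expected_raw <- as.numeric(exp_counts) / n_shuffles
  expected <- pmax(expected_raw, 1)
  obs <- as.numeric(observed)
  tot <- as.numeric(total)
  score <- log2(pmax(obs, 1) / expected)
  p0 <- pmin(expected / tot, 1)
  greater <- obs >= expected
  p <- ifelse(greater,
              pbinom(obs - 1, size = tot, prob = p0, lower.tail = FALSE),
              pbinom(obs, size = tot, prob = p0))
  out <- data.frame(subfamily = names(total),
                    total = as.integer(tot),
                    observed = as.integer(obs),
                    expected_raw = expected_raw,
                    expected = expected,
                    score = score,
                    p = p,
                    direction = ifelse(greater, "greater", "less"),
                    observed_zero = obs == 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RPM-normalized interval signal
#'
#' Counts, per sample, the reads overlapping each target by at least 1 bp
#' and normalizes to reads per million, the library size being the
#' sample's total read count.
#'
#' @param read_sets named list (one per sample) of read interval
#'   data.frames.
#' @param targets interval data.frame.
#' @return matrix (targets x samples) of RPM values.
#' @export
interval_rpm_signal <- function(read_sets, targets) {
  tg <- .as_gr(targets)
  m <- vapply(read_sets, function(reads) {
    n <- GenomicRanges::countOverlaps(tg, .as_gr(reads), ignore.strand = TRUE)
    n / (nrow(reads) / 1e6)
  }, numeric(length(tg)))
  matrix(m, nrow = length(tg),
         dimnames = list(NULL, names(read_sets)))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided. Degenerate inputs (zero variance in both groups)
#' return p = 1 when the means are equal, p = 0 otherwise.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
compare_groups_welch <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(b) - mean(a)) * Inf, df = NA_real_, p = 0))
  }
  fit <- t.test(a, b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Motif-occurrence enrichment ratio
#'
#' Per motif, the ratio of occurrence counts in the query regions versus a
#' control region set, with a pseudo-occurrence added to both sides so
#' sparse controls cannot produce infinite ratios. An occurrence is a motif
#' site overlapping at least one region.
#'
#' @param query_regions,control_regions interval data.frames.
#' @param motif_sites named list of per-motif site interval data.frames.
#' @param pseudo pseudo-occurrence added to numerator and denominator.
#' @param top_k how many motifs to report (ranked by ratio, ties by name).
#' @return data.frame (motif, n_query, n_control, ratio), top_k rows.
#' @export
motif_occurrence_enrichment <- function(query_regions, motif_sites,
                                        control_regions, pseudo = 1,
                                        top_k = 50) {
  qg <- .as_gr(query_regions)
  cg <- .as_gr(control_regions)
  res <- lapply(names(motif_sites), function(m) {
    sg <- .as_gr(motif_sites[[m]])
    nq <- sum(GenomicRanges::countOverlaps(sg, qg, ignore.strand = TRUE) > 0)
    nc <- sum(GenomicRanges::countOverlaps(sg, cg, ignore.strand = TRUE) > 0)
    data.frame(motif = m, n_query = nq, n_control = nc,
               ratio = (nq + pseudo) / (nc + pseudo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$ratio, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}
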