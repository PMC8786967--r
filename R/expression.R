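## Copy-level TE expression: normalization, the expressed-feature filter,
## a self-contained negative-binomial Wald test, DETE/DEG calling,
## subfamily summaries and solo/proviral LTR classification.

#' RPKM normalization
#'
#' `count / (length/1e3) / (library_size/1e6)` — reads per kilobase of
#' feature per million mapped reads.
#'
#' @param counts matrix (features x samples).
#' @param lengths feature lengths in bp, recycled over columns; named
#'   vectors are matched to rownames.
#' @param library_sizes per-sample totals; defaults to column sums.
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts), all(lengths >= 1))
  if (any(library_sizes <= 0)) stop("library size must be > 0")
  sweep(counts / (lengths / 1e3), 2, library_sizes / 1e6, "/")
}

#' RPM normalization
#'
#' `count / (library_size/1e6)` — reads per million mapped reads, with no
#' length term.
#'
#' @inheritParams rpkm
#' @return numeric matrix of RPM values.
#' @export
rpm <- function(counts, library_sizes = colSums(counts)) {
  if (any(library_sizes <= 0)) stop("library size must be > 0")
  sweep(counts, 2, library_sizes / 1e6, "/")
}

#' Expressed-feature filter
#'
#' Keeps a feature iff its mean RPKM is strictly greater than `threshold`
#' in at least one of the two groups.
#'
#' @param rpkm_matrix RPKM matrix (features x samples).
#' @param design named character vector mapping sample id -> group label;
#'   exactly two groups.
#' @param threshold RPKM cutoff (strict `>`).
#' @return character vector of retained feature ids.
#' @export
filter_expressed <- function(rpkm_matrix, design, threshold = 1) {
  design <- .check_design(design, colnames(rpkm_matrix))
  groups <- levels(design)
  mA <- rowMeans(rpkm_matrix[, names(design)[design == groups[1]], drop = FALSE])
  mB <- rowMeans(rpkm_matrix[, names(design)[design == groups[2]], drop = FALSE])
  rownames(rpkm_matrix)[mA > threshold | mB > threshold]
}

.check_design <- function(design, samples) {
  if (is.null(names(design))) stop("design must be a named vector (sample -> group)")
  missing <- setdiff(names(design), samples)
  if (length(missing)) stop("design sample(s) absent from matrix: ",
                            paste(missing, collapse = ", "))
  f <- factor(design)
  if (nlevels(f) != 2) stop("design must have exactly two groups, got ",
                            nlevels(f))
  names(f) <- names(design)
  f
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over features with
#' nonzero counts in every sample, of the ratio of the sample's count to
#' the feature's geometric mean; factors are then rescaled to geometric
#' mean 1. When no feature is nonzero in all samples, library-size factors
#' are used instead (with a warning).
#'
#' @param counts matrix (features x samples).
#' @return numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to library-size factors")
    sf <- colSums(counts)
  } else {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(counts[allpos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - loggeo)))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Negative-binomial Wald differential test
#'
#' A self-contained two-group differential test on count data: counts are
#' normalized with median-of-ratios size factors; the per-feature log2 fold
#' change is `log2((meanB + c) / (meanA + c))` with pseudo-count `c`
#' (group B = second factor level over group A = first); dispersion is
#' estimated per feature by method of moments on normalized counts (pooled
#' within-group variance), floored at the across-feature median so noisy
#' per-feature estimates can only be inflated, never deflated; the Wald
#' statistic is the log2 fold change over its
#' delta-method standard error under the NB variance function
#' `var = mu + alpha * mu^2`, with a two-sided normal p-value and BH FDR.
#'
#' Features with zero counts in every sample are dropped before testing
#' (their fold change is undefined).
#'
#' @param counts integer matrix (features x samples).
#' @param design named sample -> group vector; exactly two groups, tested
#'   as second level over first (set the reference by `factor` level order
#'   or the `ref` argument).
#' @param ref optional group label to use as the denominator (group A).
#' @param pseudo pseudo-count `c` used in the fold change.
#' @param dispersion_floor lower bound on the dispersion estimate.
#' @return data.frame with feature, base_mean_a, base_mean_b, log2fc, se,
#'   p, padj.
#' @export
nb_differential <- function(counts, design, ref = NULL, pseudo = 0.5,
                            dispersion_floor = 1e-8) {
  design <- .check_design(design, colnames(counts))
  if (!is.null(ref)) design <- stats::relevel(design, ref = ref)
  groups <- levels(design)
  sA <- names(design)[design == groups[1]]
  sB <- names(design)[design == groups[2]]
  if (!length(sA) || !length(sB)) stop("each group needs >= 1 sample")
  keep <- rowSums(counts[, c(sA, sB), drop = FALSE]) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts[, c(sA, sB), drop = FALSE])
  norm <- sweep(counts[, c(sA, sB), drop = FALSE], 2, sf[c(sA, sB)], "/")
  A <- norm[, sA, drop = FALSE]
  B <- norm[, sB, drop = FALSE]
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  nA <- length(sA)
  nB <- length(sB)
  ## method-of-moments dispersion from pooled within-group variance,
  ## moderated toward the across-feature median to stabilise the tiny
  ## per-feature degrees of freedom
  dfA <- max(nA - 1, 0); dfB <- max(nB - 1, 0)
  if (dfA + dfB == 0) {
    v <- rep(NA_real_, nrow(norm))
  } else {
    vA <- if (dfA > 0) apply(A, 1, var) else 0
    vB <- if (dfB > 0) apply(B, 1, var) else 0
    v <- (dfA * vA + dfB * vB) / (dfA + dfB)
  }
  mu <- (mA + mB) / 2
  alpha_raw <- (v - mu) / mu^2
  alpha_raw[!is.finite(alpha_raw)] <- NA_real_
  trend <- median(pmax(alpha_raw, dispersion_floor), na.rm = TRUE)
  if (!is.finite(trend)) trend <- dispersion_floor
  ## conservative moderation: never let a feature drop below the
  ## across-feature trend (per-feature estimates at these sample sizes are
  ## far too noisy to trust on the low side)
  alpha <- pmax(alpha_raw, trend, dispersion_floor)
  alpha[is.na(alpha)] <- trend
  varA <- (mA + alpha * mA^2) / nA
  varB <- (mB + alpha * mB^2) / nB
  log2fc <- log2((mB + pseudo) / (mA + pseudo))
  se <- sqrt(varA / (mA + pseudo)^2 + varB / (mB + pseudo)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(feature = rownames(counts),
                    base_mean_a = mA, base_mean_b = mB,
                    log2fc = log2fc, se = se, p = p,
                    padj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = groups[1], b = groups[2])
  out
}

#' Call differential features at fold-change and FDR thresholds
#'
#' `up` iff `log2fc >= log2(fold_threshold)` and `padj < fdr_threshold`;
#' `down` symmetric; otherwise `ns`. The shipped defaults are the TE-copy
#' thresholds (4-fold, FDR 0.05); use `fold_threshold = 1.5` for genes.
#'
#' @param table output of [nb_differential()].
#' @param fold_threshold fold change cutoff (> 1).
#' @param fdr_threshold FDR cutoff in (0, 1).
#' @return `table` with an added `call` column.
#' @export
call_differential <- function(table, fold_threshold = 4, fdr_threshold = 0.05) {
  stopifnot(fold_threshold > 1, fdr_threshold > 0, fdr_threshold < 1)
  lfc <- log2(fold_threshold)
  call <- rep("ns", nrow(table))
  sig <- !is.na(table$padj) & table$padj < fdr_threshold
  call[sig & table$log2fc >= lfc] <- "up"
  call[sig & table$log2fc <= -lfc] <- "down"
  table$call <- call
  table
}

#' Direction proportions among differential calls
#'
#' The proportion of up- versus down-regulated features among all
#' differential calls (the pie-chart summary).
#'
#' @param calls character vector of calls (`up`/`down`/`ns`), or a table
#'   from [call_differential()].
#' @return data.frame with direction, n, percent.
#' @export
call_proportions <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$call
  n_up <- sum(calls == "up")
  n_down <- sum(calls == "down")
  tot <- n_up + n_down
  data.frame(direction = c("up", "down"),
             n = c(n_up, n_down),
             percent = if (tot > 0) 100 * c(n_up, n_down) / tot else c(NA, NA),
             stringsAsFactors = FALSE)
}

#' Rank TE subfamilies by DETE proportion
#'
#' Because subfamilies differ hugely in copy number, subfamilies are ranked
#' by the proportion of their copies called differential rather than the
#' absolute count. Subfamilies with fewer than `min_copies` total copies or
#' fewer than `min_dete` differential copies are excluded.
#'
#' @param table differential table with a `call` column; `feature` must be
#'   [te_copy_id()] values.
#' @param te_table TE annotation.
#' @param min_copies minimum total copies per subfamily.
#' @param min_dete minimum differential copies per subfamily.
#' @param top_k how many subfamilies to report per direction.
#' @return list with `summary` (all eligible subfamilies) and `up`/`down`
#'   (top_k by proportion, ties broken by name).
#' @export
rank_subfamily_dete_proportion <- function(table, te_table, min_copies = 80,
                                           min_dete = 8, top_k = 10) {
  ids <- te_copy_id(te_table)
  idx <- match(table$feature, ids)
  if (anyNA(idx)) {
    stop("feature(s) not in te_table, e.g. ", table$feature[which(is.na(idx))[1]])
  }
  sub <- te_table$subfamily[idx]
  total <- table(te_table$subfamily)
  n_up <- table(factor(sub[table$call == "up"], levels = names(total)))
  n_down <- table(factor(sub[table$call == "down"], levels = names(total)))
  s <- data.frame(subfamily = names(total),
                  total = as.integer(total),
                  n_up = as.integer(n_up),
                  n_down = as.integer(n_down),
                  stringsAsFactors = FALSE)
  s$n_dete <- s$n_up + s$n_down
  s$prop_up <- s$n_up / s$total
  s$prop_down <- s$n_down / s$total
  s <- s[s$total >= min_copies & s$n_dete >= min_dete, , drop = FALSE]
  rownames(s) <- NULL
  pick <- function(col) {
    o <- order(-s[[col]], s$subfamily)
    head(s[o, , drop = FALSE], top_k)
  }
  list(summary = s, up = pick("prop_up"), down = pick("prop_down"))
}

#' Top-variance subfamilies as a z-scored matrix
#'
#' Ranks subfamilies by cross-sample variance of their normalized (RPM)
#' expression and z-scores each retained row (mean 0, sd 1 across samples;
#' constant rows become all zeros). Variance ties are broken by subfamily
#' name for determinism.
#'
#' @param rpm_matrix subfamily x sample RPM matrix.
#' @param k number of subfamilies to keep (all, with a warning, if fewer
#'   exist).
#' @return z-scored matrix of the top-k subfamilies, highest variance
#'   first.
#' @export
top_variance_subfamilies <- function(rpm_matrix, k = 200) {
  v <- apply(rpm_matrix, 1, var)
  if (k > nrow(rpm_matrix)) {
    warning("k exceeds subfamily count; keeping all ", nrow(rpm_matrix))
    k <- nrow(rpm_matrix)
  }
  o <- order(-v, rownames(rpm_matrix))[seq_len(k)]
  m <- rpm_matrix[o, , drop = FALSE]
  t(apply(m, 1, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}

#' Aggregate copy-level counts to subfamilies
#'
#' Subfamily count = sum of its member copies' counts per sample; total
#' count mass is conserved.
#'
#' @param copy_counts matrix with [te_copy_id()] rownames.
#' @param te_table TE annotation.
#' @return subfamily x sample integer matrix.
#' @export
aggregate_subfamily <- function(copy_counts, te_table) {
  ids <- te_copy_id(te_table)
  idx <- match(rownames(copy_counts), ids)
  if (anyNA(idx)) {
    stop("copy missing from te_table: ",
         rownames(copy_counts)[which(is.na(idx))[1]])
  }
  rowsum(copy_counts, group = te_table$subfamily[idx])
}

#' Classify LTR copies as solo or proviral
#'
#' An LTR copy is `proviral` when its distance (under the [nearest_distance()]
#' convention: overlap = 0, bookended = 1) to the nearest internal proviral
#' copy is at most `max_distance`, else `solo`. Shipped defaults in the
#' human ERV system: 100 bp for LTR5Hs vs HERVK internal copies and 10 bp
#' for LTR7 vs HERVH.
#'
#' @param ltr_copies interval data.frame of LTR copies.
#' @param internal_copies interval data.frame of internal (coding) copies.
#' @param max_distance bp threshold (>= 0).
#' @return `ltr_copies` with added `distance` and `ltr_class` columns.
#' @export
classify_solo_ltr <- function(ltr_copies, internal_copies, max_distance = 100) {
  stopifnot(max_distance >= 0)
  d <- nearest_distance(ltr_copies, internal_copies)
  ltr_copies$distance <- d
  ltr_copies$ltr_class <- ifelse(d <= max_distance, "proviral", "solo")
  ltr_copies
}
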