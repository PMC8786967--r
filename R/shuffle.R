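## Region shuffling for null models. Two flavours: plain length-preserving
## same-chromosome shuffles, and stratified shuffles that additionally pin
## each region's midpoint to its source genomic category so the shuffled
## sets keep the genomic distribution of the originals.

#' Length-preserving random shuffle of regions
#'
#' Each region is re-placed uniformly on its own chromosome, keeping its
#' length. Deterministic for a given seed.
#'
#' @param regions interval data.frame.
#' @param chrom_sizes named chromosome lengths.
#' @param seed integer seed.
#' @param n_shuffles number of independent shuffled sets.
#' @return data.frame with the region columns plus `shuffle` (1..n) and
#'   `source` (input row index).
#' @export
shuffle_keep_length <- function(regions, chrom_sizes, seed = 1L, n_shuffles = 1L) {
  validate_intervals(regions, chrom_sizes, what = "region")
  len <- regions$end - regions$start
  maxstart <- unname(chrom_sizes[regions$chrom]) - len
  if (any(maxstart < 0)) {
    stop("region longer than its chromosome: row ", which(maxstart < 0)[1])
  }
  n <- nrow(regions)
  starts <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) floor(runif(n, 0, maxstart + 1)), numeric(n))
  })
  starts <- matrix(as.integer(starts), nrow = n)
  out <- data.frame(
    chrom = rep(regions$chrom, n_shuffles),
    start = as.vector(starts),
    end = as.vector(starts) + rep(len, n_shuffles),
    strand = if (is.null(regions$strand)) "." else rep(regions$strand, n_shuffles),
    shuffle = rep(seq_len(n_shuffles), each = n),
    source = rep(seq_len(n), n_shuffles),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stratified (category-matched) shuffle of regions
#'
#' Re-places each region uniformly among positions on its own chromosome
#' where the region's midpoint falls in a segment of the same genomic
#' category it came from, so every shuffled set preserves each region's
#' length, chromosome and midpoint category exactly. Only the midpoint is
#' constrained; the rest of the region may spill into neighbouring
#' categories, mirroring midpoint-based annotation. Shuffled regions may
#' overlap each other (no rejection).
#'
#' @param regions interval data.frame.
#' @param partition `category_partition` from [partition_genome()].
#' @param chrom_sizes named chromosome lengths.
#' @param n_shuffles number of shuffled sets (>= 1).
#' @param seed integer seed; the draw for region i, shuffle j is a fixed
#'   function of (seed, i, j).
#' @return data.frame as in [shuffle_keep_length()] plus `category`.
#' @export
stratified_shuffle <- function(regions, partition, chrom_sizes,
                               n_shuffles = 1L, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  validate_intervals(regions, chrom_sizes, what = "region")
  cat <- annotate_midpoint(regions, partition)
  len <- regions$end - regions$start
  moff <- len %/% 2L  # midpoint = start + moff
  ## per-region eligible midpoint segments
  pieces <- withr::with_seed(seed, lapply(seq_len(nrow(regions)), function(i) {
    segs <- partition[partition$chrom == regions$chrom[i] &
                        partition$category == cat[i], , drop = FALSE]
    lo <- pmax(segs$start, moff[i])
    hi <- pmin(segs$end,
               chrom_sizes[[regions$chrom[i]]] - len[i] + moff[i] + 1L)
    keep <- lo < hi
    lo <- lo[keep]; hi <- hi[keep]
    total <- sum(hi - lo)
    if (total <= 0) {
      stop(sprintf(
        "no eligible placement for region %d (%s, %s, length %d)",
        i, regions$chrom[i], cat[i], len[i]))
    }
    ## draw n_shuffles midpoints uniformly over the eligible bases
    u <- floor(runif(n_shuffles, 0, total))
    cum <- cumsum(hi - lo)
    seg_idx <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
    mids <- lo[seg_idx] + (u - c(0, cum)[seg_idx])
    data.frame(chrom = regions$chrom[i],
               start = as.integer(mids - moff[i]),
               end = as.integer(mids - moff[i] + len[i]),
               strand = if (is.null(regions$strand)) "." else regions$strand[i],
               category = cat[i],
               shuffle = seq_len(n_shuffles),
               source = i,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, pieces)
  out <- out[order(out$shuffle, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}
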