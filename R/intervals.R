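## Core interval plumbing. Intervals are plain data.frames with columns
## chrom, start, end (0-based half-open), plus optional strand/name/score.
## GenomicRanges does the heavy lifting behind these helpers; conversion to
## its 1-based closed convention is confined to .as_gr()/.gr_to_df().

#' Construct a genomic-interval table
#'
#' Builds the canonical interval data.frame used throughout the package:
#' 0-based half-open coordinates, one row per interval.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param name optional labels (recycled).
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   supplied every interval is bounds-checked against it.
#' @return data.frame with columns chrom, start, end, strand, name.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                              chrom_sizes = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  strand = rep_len(as.character(strand), length(chrom)),
                  name = rep_len(as.character(name), length(chrom)),
                  stringsAsFactors = FALSE)
  validate_intervals(x, chrom_sizes)
  x
}

#' Validate an interval table
#'
#' Checks the 0-based half-open invariants (`0 <= start < end`) and, when
#' `chrom_sizes` is given, that every interval lies within its chromosome.
#'
#' @param x interval data.frame.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("%s %d invalid: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop(sprintf("%s on unknown chromosome(s): %s", what,
                   paste(unknown, collapse = ", ")))
    }
    oob <- which(x$end > unname(chrom_sizes[x$chrom]))
    if (length(oob)) {
      stop(sprintf("%s %d out of bounds: %s:[%d,%d) exceeds length %d",
                   what, oob[1], x$chrom[oob[1]], x$start[oob[1]],
                   x$end[oob[1]], chrom_sizes[[x$chrom[oob[1]]]]))
    }
  }
  invisible(x)
}

## interval df (0-based half-open) -> GRanges (1-based closed), strand dropped
.as_gr <- function(x, chrom_sizes = NULL) {
  sl <- if (is.null(chrom_sizes)) NULL else chrom_sizes
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if (!is.null(sl)) GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr
}

.gr_to_df <- function(gr, extra = NULL) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Distance to the nearest subject interval
#'
#' For each query interval, the distance to the closest interval in
#' `subjects` on the same chromosome. Overlapping intervals are at distance
#' 0; non-overlapping intervals are at `gap + 1`, so bookended intervals
#' (e.g. `[100,200)` and `[200,300)`) are at distance 1, matching the
#' "closest"-style convention of standard interval toolkits. Queries with no
#' subject on their chromosome get `Inf`.
#'
#' @param query,subjects interval data.frames.
#' @return numeric vector, one distance per query row.
#' @examples
#' q <- genomic_intervals("chr1", 100, 200)
#' s <- genomic_intervals("chr1", 200, 300)
#' nearest_distance(q, s)  # 1
#' @export
nearest_distance <- function(query, subjects) {
  validate_intervals(query, what = "query")
  if (nrow(subjects) == 0L) return(rep(Inf, nrow(query)))
  validate_intervals(subjects, what = "subject")
  qg <- .as_gr(query)
  sg <- .as_gr(subjects)
  d <- rep(Inf, nrow(query))
  ## disjoint seqlevels between query and subjects are expected (-> Inf);
  ## silence the combine warning GenomicRanges emits for that situation
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(qg, sg, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hit)
  ## distanceToNearest: 0 for overlap AND for bookended; disambiguate with
  ## an explicit overlap test, then shift gaps by +1.
  dd <- S4Vectors::mcols(hit)$distance
  ov <- suppressWarnings(
    GenomicRanges::countOverlaps(qg[qi], sg, ignore.strand = TRUE)) > 0L
  d[qi] <- ifelse(ov, 0, dd + 1)
  d
}

#' Uniform random sample of TE copies
#'
#' Samples `n` rows without replacement, deterministically for a given
#' seed. Requests larger than the table return the whole table with a
#' warning. Output rows are in canonical (chrom, start) order.
#'
#' @param te_table TE annotation data.frame.
#' @param n number of copies to draw.
#' @param seed integer seed.
#' @return subset of `te_table`.
#' @export
sample_te_copies <- function(te_table, n, seed = 1L) {
  stopifnot(n >= 0)
  if (n >= nrow(te_table)) {
    if (n > nrow(te_table)) {
      warning(sprintf("requested %d copies but only %d available; returning all",
                      n, nrow(te_table)))
    }
    idx <- seq_len(nrow(te_table))
  } else {
    idx <- withr::with_seed(seed, sample.int(nrow(te_table), n))
  }
  out <- te_table[idx, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stable TE copy identifier
#'
#' A copy's identity is `(chrom, start, end, strand, subfamily)`; annotation
#' ids from upstream tools are not guaranteed unique. This id is the join
#' key between count matrices, differential tables and the TE annotation.
#'
#' @param te_table TE annotation data.frame.
#' @return character vector of ids, one per row.
#' @export
te_copy_id <- function(te_table) {
  paste0(te_table$chrom, ":", te_table$start, "-", te_table$end,
         "(", te_table$strand, "):", te_table$subfamily)
}
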