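## Readers/writers for every on-disk format the pipeline touches. All
## dialect conversion (1-based RepeatMasker starts, BED, TSVs) happens here
## and only here; everything downstream sees 0-based half-open coordinates.

TE_CLASSES <- c("LTR", "LINE", "SINE", "SVA", "DNA", "other")

#' Read a chromosome-sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "length"))
  if (anyDuplicated(x$chrom)) stop("duplicate chromosome names in ", path)
  if (any(x$length < 1)) stop("chromosome lengths must be >= 1 in ", path)
  setNames(as.integer(x$length), x$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named vector of lengths.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' BED3/BED6, tab-separated, 0-based half-open (the native BED convention,
#' kept as-is internally). Optional columns 4-6 (name, score, strand) are
#' preserved when present.
#'
#' @param path file path.
#' @param chrom_sizes optional named lengths for bounds checking.
#' @return interval data.frame (chrom, start, end, then name/score/strand
#'   when present in the file).
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("%s line %d: fewer than 3 tab-separated columns",
                 path, which(nf < 3)[1]))
  }
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  out <- data.frame(chrom = mat[, 1],
                    start = suppressWarnings(as.integer(mat[, 2])),
                    end = suppressWarnings(as.integer(mat[, 3])),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    stop(sprintf("%s line %d: non-numeric coordinates", path,
                 which(is.na(out$start) | is.na(out$end))[1]))
  }
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: invalid interval [%d,%d)", path, bad[1],
                 out$start[bad[1]], out$end[bad[1]]))
  }
  if (ncol_use >= 4) out$name <- mat[, 4]
  if (ncol_use >= 5) out$score <- suppressWarnings(as.numeric(mat[, 5]))
  if (ncol_use >= 6) out$strand <- mat[, 6]
  validate_intervals(out, chrom_sizes, what = paste0(path, " interval"))
  out
}

#' @rdname read_bed
#' @param x interval data.frame.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    cols <- c(cols, list(if (is.null(x$name)) "." else x$name))
  }
  if (!is.null(x$score) || !is.null(x$strand)) {
    cols <- c(cols, list(if (is.null(x$score)) 0 else x$score))
  }
  if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
  write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TE annotation table
#'
#' Seven-column TSV in RepeatMasker style: chrom, start, end, strand,
#' subfamily, family, class. `one_based` declares the coordinate dialect of
#' the *input*; internally coordinates are always 0-based half-open, so a
#' 1-based inclusive start `s` becomes `s - 1`.
#'
#' Unknown class labels are coerced to `"other"` with a warning; exact
#' duplicate rows are dropped (count reported via message).
#'
#' @param path file path.
#' @param chrom_sizes named lengths for bounds checking.
#' @param one_based logical; `TRUE` for 1-based inclusive starts.
#' @return TE table data.frame (chrom, start, end, strand, subfamily,
#'   family, class).
#' @export
read_te_table <- function(path, chrom_sizes = NULL, one_based = FALSE) {
  cols <- c("chrom", "start", "end", "strand", "subfamily", "family", "class")
  empty <- as.data.frame(setNames(
    list(character(), integer(), integer(), character(), character(),
         character(), character()), cols), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "integer",
                                 "character", "character", "character",
                                 "character"))
  if (!nrow(x)) return(empty)
  if (ncol(x) < 7) stop("TE table needs 7 columns, got ", ncol(x))
  names(x)[1:7] <- cols
  x <- x[, cols]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (one_based) x$start <- x$start - 1L
  if (any(!nzchar(x$subfamily))) stop("empty subfamily label in ", path)
  unknown <- !(x$class %in% TE_CLASSES)
  if (any(unknown)) {
    warning(sprintf("%d row(s) with unknown TE class (%s) set to 'other'",
                    sum(unknown),
                    paste(unique(x$class[unknown]), collapse = ", ")))
    x$class[unknown] <- "other"
  }
  dup <- duplicated(x)
  if (any(dup)) {
    message(sprintf("dropped %d duplicate TE row(s)", sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  validate_intervals(x, chrom_sizes, what = "TE copy")
  rownames(x) <- NULL
  x
}

#' @rdname read_te_table
#' @param te_table TE table data.frame.
#' @export
write_te_table <- function(te_table, path) {
  write.table(te_table[, c("chrom", "start", "end", "strand", "subfamily",
                           "family", "class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a per-cytosine methylation table
#'
#' TSV with columns chrom, pos (0-based), strand, context (CG/CHG/CHH),
#' count_methylated, count_total — the methratio-style per-site counts from
#' which methylation levels `#C/(#C+#T)` are computed downstream. Sites are
#' returned sorted by (chrom, pos). Rows with `count_methylated >
#' count_total` are a parse error; zero-coverage rows are retained (their
#' level stays undefined until the coverage filter).
#'
#' @param path file path.
#' @return data.frame (chrom, pos, strand, context, count_m, count_total).
#' @export
read_methylation_table <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "pos", "strand", "context",
                                "count_m", "count_total"),
                  colClasses = c("character", "integer", "character",
                                 "character", "integer", "integer"))
  x$pos <- as.integer(x$pos)
  x$count_m <- as.integer(x$count_m)
  x$count_total <- as.integer(x$count_total)
  bad <- which(x$count_m > x$count_total | x$count_m < 0)
  if (length(bad)) {
    stop(sprintf("%s row %d: count_methylated %d > count_total %d",
                 path, bad[1], x$count_m[bad[1]], x$count_total[bad[1]]))
  }
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @rdname read_methylation_table
#' @param sites methylation site data.frame.
#' @export
write_methylation_table <- function(sites, path) {
  write.table(sites[, c("chrom", "pos", "strand", "context", "count_m",
                        "count_total")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a count matrix with feature lengths
#'
#' TSV with header; first column `feature`, a `length` column (bp), and one
#' column of nonnegative integer counts per sample.
#'
#' @param path file path.
#' @return list with `counts` (integer matrix, features x samples) and
#'   `lengths` (named bp vector).
#' @export
read_count_matrix <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!"length" %in% names(x)) {
    stop("count matrix ", path, " lacks a 'length' column (RPKM impossible)")
  }
  ids <- as.character(x[[1]])
  dupes <- ids[duplicated(ids)]
  if (length(dupes)) stop("duplicated feature id(s): ",
                          paste(unique(dupes), collapse = ", "))
  lens <- x$length
  if (anyNA(lens)) stop("missing length for feature(s): ",
                        paste(ids[is.na(lens)], collapse = ", "))
  cnt <- x[, setdiff(names(x), c(names(x)[1], "length")), drop = FALSE]
  m <- as.matrix(cnt)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  list(counts = m, lengths = setNames(as.numeric(lens), ids))
}

#' @rdname read_count_matrix
#' @param counts integer matrix with feature rownames.
#' @param lengths named bp vector aligned to `counts` rows.
#' @export
write_count_matrix <- function(counts, lengths, path) {
  df <- data.frame(feature = rownames(counts),
                   length = unname(lengths[rownames(counts)]),
                   counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fetch genome sequence by interval
#'
#' Uppercase-normalized sequence extraction: softmasked lowercase is treated
#' as ordinary sequence because guide-scanning targets are repeats and must
#' not be skipped.
#'
#' @param genome `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param intervals interval data.frame (0-based half-open).
#' @return character vector of sequences.
#' @export
fetch_sequence <- function(genome, intervals) {
  genome <- load_genome(genome)
  validate_intervals(intervals,
                     setNames(Biostrings::width(genome), names(genome)))
  vapply(seq_len(nrow(intervals)), function(i) {
    as.character(Biostrings::subseq(genome[[intervals$chrom[i]]],
                                    start = intervals$start[i] + 1L,
                                    end = intervals$end[i]))
  }, character(1))
}

## accept a DNAStringSet or a FASTA path; always uppercase
load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  Biostrings::DNAStringSet(toupper(genome))
}
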