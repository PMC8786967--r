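## Mismatch-tolerant genome scanning for guide+PAM patterns on both
## strands, priority-ordered annotation of hits, and TE-targeting
## summaries.

#' CRISPRi guide patterns targeting LTR5Hs
#'
#' The two validated guide protospacers (20 nt) with their NGG PAM, as
#' degenerate 23-mer patterns.
#'
#' @return data.frame with `name` and `pattern`.
#' @export
ltr5hs_guides <- function() {
  data.frame(name = c("gRNA1", "gRNA2"),
             pattern = c("CTCCCTAATCTCAAGTACCCNGG",
                         "TGTTTCAGAGAGCACGGGGTNGG"),
             stringsAsFactors = FALSE)
}

#' Read a guide pattern file
#'
#' Two whitespace-separated columns: name, IUPAC pattern (protospacer
#' followed by PAM).
#'
#' @param path file path.
#' @return data.frame with `name` and `pattern`.
#' @export
read_guides <- function(path) {
  x <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("name", "pattern"),
                  colClasses = c("character", "character"))
  x$pattern <- toupper(x$pattern)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", x$pattern)
  if (any(bad)) stop("non-IUPAC letters in pattern ", x$name[which(bad)[1]])
  x
}

#' Scan a genome for guide+PAM matches
#'
#' Evaluates every offset on both strands of every chromosome and reports
#' hits whose Hamming distance over non-degenerate pattern positions is at
#' most `max_mismatches`. Degenerate IUPAC positions (e.g. the PAM's N)
#' match any base at zero cost; ambiguous genome bases count as mismatches
#' at non-degenerate pattern positions. Minus-strand hits are reported in
#' plus-strand coordinates with strand `"-"`. Sequence case is normalized,
#' so softmasked repeats are scanned like ordinary sequence.
#'
#' @param genome `Biostrings::DNAStringSet` or FASTA path.
#' @param patterns data.frame with `name` and `pattern` columns (see
#'   [ltr5hs_guides()]).
#' @param max_mismatches mismatch budget (applied uniformly over the full
#'   pattern, PAM included).
#' @return data.frame (chrom, start, end, strand, guide, mismatches, seq)
#'   with 0-based half-open coordinates, sorted canonically.
#' @export
scan_genome <- function(genome, patterns, max_mismatches = 3) {
  genome <- load_genome(genome)
  fixed <- c(pattern = FALSE, subject = TRUE)
  res <- list()
  for (k in seq_len(nrow(patterns))) {
    pat <- Biostrings::DNAString(patterns$pattern[k])
    rcpat <- Biostrings::reverseComplement(pat)
    for (chr in names(genome)) {
      subj <- genome[[chr]]
      if (length(pat) > length(subj)) {
        warning(sprintf("pattern %s longer than %s; chromosome skipped",
                        patterns$name[k], chr))
        next
      }
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else rcpat
        m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatches,
                                      with.indels = FALSE, fixed = fixed)
        ## drop partial matches hanging off the chromosome ends
        m <- m[IRanges::start(m) >= 1L & IRanges::end(m) <= length(subj)]
        if (!length(m)) next
        mm <- Biostrings::neditStartingAt(p, subj,
                                          starting.at = IRanges::start(m),
                                          fixed = fixed)
        res[[length(res) + 1L]] <- data.frame(
          chrom = chr,
          start = IRanges::start(m) - 1L,
          end = IRanges::end(m),
          strand = strand,
          guide = patterns$name[k],
          mismatches = as.integer(mm),
          seq = as.character(m),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), guide = character(),
                      mismatches = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand, out$guide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate guide matches with a single genomic category
#'
#' A match overlapping several feature types receives one category by the
#' priority order promoter > exon > TE > intron > intergenic (overlap of
#' at least 1 bp over the match's full interval). TE-category matches also
#' carry the subfamily of the overlapped copy, ties broken by largest
#' overlap.
#'
#' @param matches output of [scan_genome()].
#' @param genes `gene_models` object.
#' @param te_table TE annotation.
#' @param promoter_window bp half-width of the promoter window around the
#'   TSS.
#' @param chrom_sizes named chromosome lengths (for window clipping).
#' @return `matches` with added `category` and `subfamily` columns.
#' @export
annotate_matches <- function(matches, genes, te_table, promoter_window = 1000,
                             chrom_sizes = NULL) {
  mg <- .as_gr(matches)
  g <- genes$genes
  if (is.null(chrom_sizes)) {
    chrom_sizes <- setNames(rep(.Machine$integer.max %/% 2L, length(unique(g$chrom))),
                            unique(g$chrom))
  }
  prom <- .anchor_windows(g, "tss", promoter_window, chrom_sizes)
  ov <- function(df) {
    if (is.null(df) || !nrow(df)) return(rep(FALSE, nrow(matches)))
    GenomicRanges::countOverlaps(mg, .as_gr(df), ignore.strand = TRUE) > 0L
  }
  in_prom <- ov(prom)
  in_exon <- ov(genes$exons)
  in_te <- ov(te_table)
  in_gene <- ov(g)
  category <- rep("intergenic", nrow(matches))
  category[in_gene] <- "intron"
  category[in_te] <- "TE"
  category[in_exon] <- "exon"
  category[in_prom] <- "promoter"
  subfamily <- rep(NA_character_, nrow(matches))
  te_idx <- which(category == "TE")
  if (length(te_idx)) {
    hits <- GenomicRanges::findOverlaps(mg[te_idx], .as_gr(te_table),
                                        ignore.strand = TRUE)
    olap <- GenomicRanges::width(IRanges::pintersect(
      mg[te_idx][S4Vectors::queryHits(hits)],
      .as_gr(te_table)[S4Vectors::subjectHits(hits)]))
    o <- order(S4Vectors::queryHits(hits), -olap)
    first <- !duplicated(S4Vectors::queryHits(hits)[o])
    subfamily[te_idx[S4Vectors::queryHits(hits)[o][first]]] <-
      te_table$subfamily[S4Vectors::subjectHits(hits)[o][first]]
  }
  matches$category <- category
  matches$subfamily <- subfamily
  matches
}

#' Summarize guide targeting of a TE subfamily
#'
#' Site-level and copy-level summaries: the number of annotated matches in
#' the TE category carrying the subfamily, that number as a fraction of
#' all matches, and the fraction of the subfamily's copies overlapped by
#' at least one match.
#'
#' @param matches annotated matches from [annotate_matches()].
#' @param te_table TE annotation.
#' @param subfamily subfamily name.
#' @return list (sites_on_subfamily, fraction_of_sites,
#'   fraction_of_copies_hit).
#' @export
summarize_te_targeting <- function(matches, te_table, subfamily) {
  copies <- te_table[te_table$subfamily == subfamily, , drop = FALSE]
  if (!nrow(copies)) {
    warning("subfamily ", subfamily, " absent from te_table")
    return(list(sites_on_subfamily = 0L, fraction_of_sites = 0,
                fraction_of_copies_hit = 0))
  }
  if (!nrow(matches)) {
    return(list(sites_on_subfamily = 0L, fraction_of_sites = 0,
                fraction_of_copies_hit = 0))
  }
  n_sites <- sum(matches$category == "TE" &
                   !is.na(matches$subfamily) & matches$subfamily == subfamily)
  hit <- GenomicRanges::countOverlaps(.as_gr(copies), .as_gr(matches),
                                      ignore.strand = TRUE) > 0L
  list(sites_on_subfamily = as.integer(n_sites),
       fraction_of_sites = n_sites / nrow(matches),
       fraction_of_copies_hit = sum(hit) / nrow(copies))
}
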