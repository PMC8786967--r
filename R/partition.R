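## Gene models, the 7-category genome partition used for stratified
## shuffling, and midpoint annotation.

PARTITION_CATEGORIES <- c("promoter", "tts", "exon", "intron",
                          "proximal_10kb", "distal_10_100kb",
                          "intergenic_gt100kb")

#' Construct gene models
#'
#' A reduced gene table (no full GTF grammar): one row per gene plus an
#' exon table. The TSS is the strand-aware 5' base (`start` on `+`,
#' `end - 1` on `-`); the TES is the 3' base. Exons are merged per gene so
#' they are non-overlapping and within the gene body.
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @param exons data.frame with gene_id, chrom, start, end; defaults to one
#'   exon spanning each gene.
#' @param chrom_sizes optional named lengths for bounds checking.
#' @return list of class `gene_models` with elements `genes` (including
#'   tss/tes columns) and `exons`.
#' @export
gene_models <- function(genes, exons = NULL, chrom_sizes = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  validate_intervals(genes, chrom_sizes, what = "gene")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  } else {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
    validate_intervals(exons, chrom_sizes, what = "exon")
    key <- match(exons$gene_id, genes$gene_id)
    if (anyNA(key)) stop("exon with unknown gene_id: ",
                         exons$gene_id[which(is.na(key))[1]])
    inside <- exons$start >= genes$start[key] & exons$end <= genes$end[key]
    if (!all(inside)) stop("exon outside its gene body: row ",
                           which(!inside)[1])
    ## merge overlapping exons per gene
    sp <- split(seq_len(nrow(exons)), exons$gene_id)
    exons <- do.call(rbind, lapply(names(sp), function(g) {
      e <- exons[sp[[g]], , drop = FALSE]
      r <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
      data.frame(gene_id = g, chrom = e$chrom[1],
                 start = IRanges::start(r) - 1L, end = IRanges::end(r),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

## promoter/TTS windows as interval dfs: anchor base +/- window, clipped
.anchor_windows <- function(genes, anchor, window, chrom_sizes) {
  pos <- genes[[anchor]]
  data.frame(chrom = genes$chrom,
             start = pmax(0L, pos - as.integer(window)),
             end = pmin(unname(chrom_sizes[genes$chrom]),
                        pos + as.integer(window) + 1L),
             stringsAsFactors = FALSE)
}

#' Partition a genome into 7 regulatory categories
#'
#' Labels every base of every chromosome with exactly one of: promoter,
#' tts, exon, intron, proximal_10kb, distal_10_100kb, intergenic_gt100kb.
#' Overlaps are resolved by that priority order. Promoter and TTS windows
#' are anchor +/- `promoter_window`/`tts_window` bp; intergenic space is
#' shelled by distance to the nearest gene boundary (<=10 kb, (10,100] kb,
#' >100 kb).
#'
#' @param genes `gene_models` object (or NULL/empty for a gene-less genome,
#'   which is entirely `intergenic_gt100kb`).
#' @param chrom_sizes named chromosome lengths.
#' @param promoter_window,tts_window half-width in bp of the promoter/TTS
#'   windows around TSS/TES.
#' @param proximal_bp,distal_bp intergenic shell radii.
#' @return data.frame of class `category_partition` (chrom, start, end,
#'   category), sorted, disjoint, covering every base exactly once.
#' @export
partition_genome <- function(genes, chrom_sizes, promoter_window = 1000,
                             tts_window = 1000, proximal_bp = 10000,
                             distal_bp = 100000) {
  stopifnot(promoter_window >= 0, tts_window >= 0)
  gtab <- if (is.null(genes)) NULL else genes$genes
  out <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    full <- IRanges::IRanges(1L, L)
    g <- if (is.null(gtab)) NULL else gtab[gtab$chrom == chr, , drop = FALSE]
    clip <- function(df) {  # 0-based df -> 1-based IRanges, clipped
      if (is.null(df) || nrow(df) == 0) return(IRanges::IRanges())
      IRanges::reduce(IRanges::restrict(
        IRanges::IRanges(df$start + 1L, df$end), 1L, L))
    }
    if (is.null(g) || nrow(g) == 0) {
      layers <- list(promoter = IRanges::IRanges(), tts = IRanges::IRanges(),
                     exon = IRanges::IRanges(), intron = IRanges::IRanges(),
                     proximal_10kb = IRanges::IRanges(),
                     distal_10_100kb = IRanges::IRanges(),
                     intergenic_gt100kb = full)
    } else {
      ex <- if (is.null(genes$exons)) g else
        genes$exons[genes$exons$chrom == chr, , drop = FALSE]
      gene_ir <- clip(g)
      prox <- IRanges::reduce(IRanges::restrict(
        gene_ir + as.integer(proximal_bp), 1L, L))
      dist <- IRanges::reduce(IRanges::restrict(
        gene_ir + as.integer(distal_bp), 1L, L))
      layers <- list(
        promoter = clip(.anchor_windows(g, "tss", promoter_window, chrom_sizes)),
        tts = clip(.anchor_windows(g, "tes", tts_window, chrom_sizes)),
        exon = clip(ex),
        intron = IRanges::setdiff(gene_ir, clip(ex)),
        proximal_10kb = IRanges::setdiff(prox, gene_ir),
        distal_10_100kb = IRanges::setdiff(dist, prox),
        intergenic_gt100kb = IRanges::setdiff(full, dist)
      )
    }
    ## priority overlay
    taken <- IRanges::IRanges()
    segs <- lapply(PARTITION_CATEGORIES, function(cat) {
      r <- IRanges::setdiff(layers[[cat]], taken)
      taken <<- IRanges::reduce(c(taken, r))
      if (length(r) == 0) return(NULL)
      data.frame(chrom = chr, start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), category = cat,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, segs)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, names(chrom_sizes)), out$start), ]
  rownames(out) <- NULL
  class(out) <- c("category_partition", "data.frame")
  attr(out, "chrom_sizes") <- chrom_sizes
  out
}

#' Category at a region's midpoint
#'
#' The category of base `floor((start + end) / 2)` under a partition, the
#' convention used both to annotate open regions and to stratify shuffles.
#'
#' @param regions interval data.frame.
#' @param partition `category_partition` from [partition_genome()].
#' @return character vector of categories, one per region.
#' @export
annotate_midpoint <- function(regions, partition) {
  mid <- (regions$start + regions$end) %/% 2L
  pts <- GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  seg <- .as_gr(partition)
  hit <- GenomicRanges::findOverlaps(pts, seg, ignore.strand = TRUE)
  out <- rep(NA_character_, nrow(regions))
  out[S4Vectors::queryHits(hit)] <- partition$category[S4Vectors::subjectHits(hit)]
  if (anyNA(out)) {
    stop("midpoint not covered by partition (region row ",
         which(is.na(out))[1], ") - is the region on a partition chromosome?")
  }
  out
}
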