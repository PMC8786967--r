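## Region-associated DEG (RAD) analysis: do differential genes concentrate
## near a region set across nested extension distances? Plus a generic
## hypergeometric DEG-set overlap test.

#' Region-associated DEG analysis
#'
#' For each symmetric extension distance `d` and DEG direction, counts the
#' genes whose TSS falls within any region extended by `d` bp on both
#' sides and tests the DEG count against the universe with an upper-tail
#' hypergeometric test (population = universe, population successes =
#' universe genes in window, draws = DEG set, observed = DEGs in window).
#' Window counts are of distinct genes and are nested across extensions.
#'
#' @param regions interval data.frame (the genomic regions of interest).
#' @param deg_up,deg_down character vectors of gene ids; must be subsets
#'   of the universe.
#' @param universe data.frame with `gene_id`, `chrom` and `tss` (0-based
#'   base position) for every background gene (typically the
#'   expression-filtered gene set used for DEG calling).
#' @param extensions extension distances in bp.
#' @param chrom_sizes optional named lengths used to clip extended
#'   regions.
#' @return data.frame (extension_bp, direction, degs_in_window,
#'   degs_total, universe_in_window, universe_total, p).
#' @export
rad <- function(regions, deg_up, deg_down, universe,
                extensions = c(0, 2e5, 4e5, 6e5, 8e5, 1e6),
                chrom_sizes = NULL) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(universe)))
  for (set in list(up = deg_up, down = deg_down)) {
    missing <- setdiff(set, universe$gene_id)
    if (length(missing)) {
      stop("DEG not in universe: ", paste(head(missing, 5), collapse = ", "))
    }
  }
  pts <- GenomicRanges::GRanges(universe$chrom,
                                IRanges::IRanges(universe$tss + 1L,
                                                 universe$tss + 1L))
  N <- nrow(universe)
  rows <- list()
  for (d in sort(extensions)) {
    ext <- regions
    ext$start <- pmax(0L, regions$start - as.integer(d))
    ext$end <- regions$end + as.integer(d)
    if (!is.null(chrom_sizes)) {
      ext$end <- pmin(ext$end, unname(chrom_sizes[ext$chrom]))
    }
    inw <- GenomicRanges::countOverlaps(pts, .as_gr(ext),
                                        ignore.strand = TRUE) > 0L
    K <- sum(inw)
    genes_in <- universe$gene_id[inw]
    for (dir in c("up", "down")) {
      set <- if (dir == "up") deg_up else deg_down
      k <- length(intersect(set, genes_in))
      p <- phyper(k - 1, K, N - K, length(set), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        extension_bp = d, direction = dir,
        degs_in_window = k, degs_total = length(set),
        universe_in_window = K, universe_total = N, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap of two DEG sets
#'
#' Overlap size, overlap as a fraction of set A, and the upper-tail
#' hypergeometric p-value of drawing that many set-B members in |A| draws
#' from the universe.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe character vector of all background gene ids.
#' @return list (overlap, fraction_of_a, p).
#' @export
deg_set_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  for (nm in c("set_a", "set_b")) {
    missing <- setdiff(get(nm), universe)
    if (length(missing)) {
      stop(nm, " member(s) not in universe: ",
           paste(head(missing, 5), collapse = ", "))
    }
  }
  ov <- length(intersect(set_a, set_b))
  frac <- if (length(set_a)) ov / length(set_a) else NA_real_
  p <- phyper(ov - 1, length(set_b), length(universe) - length(set_b),
              length(set_a), lower.tail = FALSE)
  list(overlap = ov, fraction_of_a = frac, p = p)
}
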