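## CpG methylation: per-site and pooled region levels, coverage filtering,
## scaled metaprofiles over element sets, fixed-bin DMR calling with
## Fisher's exact test, and DMR-TE overlap summaries.

#' Per-site methylation level
#'
#' `#C / (#C + #T)`; `NA` where the site has no informative reads.
#'
#' @param sites methylation site data.frame.
#' @return numeric vector in `[0, 1]` (or NA).
#' @export
site_methylation <- function(sites) {
  ifelse(sites$count_total >= 1, sites$count_m / sites$count_total, NA_real_)
}

#' Minimum-coverage filter
#'
#' Retains sites covered by at least `k` reads.
#'
#' @param sites methylation site data.frame.
#' @param k minimum `count_total`.
#' @return filtered data.frame.
#' @export
filter_min_coverage <- function(sites, k = 3) {
  out <- sites[sites$count_total >= k, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## match site points (0-based pos) into intervals; returns Hits
.sites_in <- function(intervals, sites) {
  pts <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  GenomicRanges::findOverlaps(.as_gr(intervals), pts, ignore.strand = TRUE)
}

#' Pooled methylation level over regions
#'
#' For each region, `sum(count_m) / sum(count_total)` over the CG sites it
#' contains (read-pooled, not a mean of site levels), `NA` when a region
#' contains no site.
#'
#' @param regions interval data.frame.
#' @param sites methylation site data.frame (coverage-filter beforehand if
#'   desired).
#' @param context restrict to this context (default CG); NULL for all.
#' @return numeric vector, one level per region.
#' @export
region_methylation <- function(regions, sites, context = "CG") {
  if (!is.null(context)) sites <- sites[sites$context %in% context, , drop = FALSE]
  hit <- .sites_in(regions, sites)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  m <- tapply(sites$count_m[si], factor(qi, levels = seq_len(nrow(regions))),
              sum, default = NA_real_)
  tot <- tapply(sites$count_total[si], factor(qi, levels = seq_len(nrow(regions))),
                sum, default = NA_real_)
  as.numeric(ifelse(!is.na(tot) & tot > 0, m / tot, NA_real_))
}

#' Scaled metaprofile over an element set
#'
#' Aggregates methylation (pooled `sum m / sum total`) or coverage (mean
#' `count_total`) over all elements into a fixed-length bin curve: each
#' element's body is scaled to `body_bins` bins and each flank of
#' `flank_bp` to `flank_bins` bins. Minus-strand elements are
#' orientation-flipped so bin 1 is always the 5' upstream edge.
#'
#' @param intervals strand-annotated interval data.frame.
#' @param sites methylation site data.frame.
#' @param flank_bp flank width in bp.
#' @param body_bins,flank_bins bin counts.
#' @param value `"methylation"` or `"coverage"`.
#' @param context site context filter (default CG).
#' @return data.frame (bin, zone, value, n_sites); bins run 5' flank,
#'   body, 3' flank.
#' @export
metaprofile <- function(intervals, sites, flank_bp = 2000, body_bins = 50,
                        flank_bins = 20, value = c("methylation", "coverage"),
                        context = "CG") {
  value <- match.arg(value)
  if (!is.null(context)) sites <- sites[sites$context %in% context, , drop = FALSE]
  stopifnot(all(intervals$strand %in% c("+", "-")))
  nbins <- 2L * flank_bins + body_bins
  win <- intervals
  win$start <- pmax(0L, intervals$start - as.integer(flank_bp))
  win$end <- intervals$end + as.integer(flank_bp)
  hit <- .sites_in(win, sites)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  pos <- sites$pos[si]
  s <- intervals$start[qi]; e <- intervals$end[qi]
  len <- e - s
  bin <- integer(length(qi))
  up <- pos < s        # upstream flank (plus orientation)
  dn <- pos >= e       # downstream flank
  body <- !up & !dn
  bin[up] <- flank_bins - floor((s[up] - 1 - pos[up]) / flank_bp * flank_bins)
  bin[body] <- flank_bins + 1L + floor((pos[body] - s[body]) / len[body] * body_bins)
  bin[dn] <- flank_bins + body_bins +
    1L + floor((pos[dn] - e[dn]) / flank_bp * flank_bins)
  bin <- pmin(pmax(bin, 1L), nbins)
  neg <- intervals$strand[qi] == "-"
  bin[neg] <- nbins + 1L - bin[neg]
  f <- factor(bin, levels = seq_len(nbins))
  val <- if (value == "methylation") {
    as.numeric(tapply(sites$count_m[si], f, sum, default = NA_real_) /
                 tapply(sites$count_total[si], f, sum, default = NA_real_))
  } else {
    as.numeric(tapply(sites$count_total[si], f, mean, default = NA_real_))
  }
  zone <- rep("body", nbins)
  zone[seq_len(flank_bins)] <- "flank_5p"
  zone[flank_bins + body_bins + seq_len(flank_bins)] <- "flank_3p"
  data.frame(bin = seq_len(nbins), zone = zone, value = val,
             n_sites = as.integer(table(f)), stringsAsFactors = FALSE)
}

#' Call differentially methylated regions in fixed bins
#'
#' Tiles the genome in fixed-phase `bin_size` bins anchored at coordinate
#' 0 and, in each bin, compares pooled CG counts between two conditions
#' with a two-sided Fisher exact test. A bin is tested only if it holds at
#' least `min_cg` CG sites that are covered by at least `min_cov` reads in
#' both conditions. DMRs are tested bins with
#' `|pooled level B - pooled level A| >= min_diff` and BH FDR below `fdr`;
#' same-direction DMRs within `merge_gap` bp are merged (coordinates
#' unioned, counts pooled, worst FDR kept). Direction is relative to
#' condition B: `hypo` means B is less methylated.
#'
#' @param sites_a,sites_b methylation site data.frames for conditions A
#'   and B on the same genome.
#' @param bin_size bin width in bp.
#' @param min_cg minimum qualifying CG sites per tested bin.
#' @param min_cov minimum reads per site, enforced in both conditions.
#' @param min_diff minimum absolute pooled methylation difference.
#' @param fdr BH FDR cutoff.
#' @param merge_gap maximum gap in bp for merging same-direction DMRs.
#' @return data.frame (chrom, start, end, mean_a, mean_b, diff, fdr,
#'   direction, n_bins); attribute `"tested"` holds the per-bin test table.
#' @export
call_dmrs <- function(sites_a, sites_b, bin_size = 200, min_cg = 4,
                      min_cov = 3, min_diff = 0.2, fdr = 0.05,
                      merge_gap = 100) {
  if (!nrow(sites_a) || !nrow(sites_b)) stop("empty methylome")
  a <- sites_a[sites_a$context == "CG", , drop = FALSE]
  b <- sites_b[sites_b$context == "CG", , drop = FALSE]
  key_a <- paste(a$chrom, a$pos, a$strand)
  key_b <- paste(b$chrom, b$pos, b$strand)
  idx <- match(key_a, key_b)
  shared <- !is.na(idx)
  a <- a[shared, , drop = FALSE]
  b <- b[idx[shared], , drop = FALSE]
  ok <- a$count_total >= min_cov & b$count_total >= min_cov
  a <- a[ok, , drop = FALSE]
  b <- b[ok, , drop = FALSE]
  if (!nrow(a)) stop("no shared CG sites passing the coverage filter")
  bin <- a$pos %/% as.integer(bin_size)
  grp <- paste(a$chrom, bin)
  agg <- function(x) as.numeric(tapply(x, grp, sum))
  tab <- data.frame(chrom = tapply(a$chrom, grp, `[`, 1),
                    bin = as.integer(tapply(bin, grp, `[`, 1)),
                    n_cg = as.integer(tapply(a$pos, grp, length)),
                    m_a = agg(a$count_m), t_a = agg(a$count_total),
                    m_b = agg(b$count_m), t_b = agg(b$count_total),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$n_cg >= min_cg, , drop = FALSE]
  if (!nrow(tab)) {
    return(structure(data.frame(chrom = character(), start = integer(),
                                end = integer(), mean_a = numeric(),
                                mean_b = numeric(), diff = numeric(),
                                fdr = numeric(), direction = character(),
                                n_bins = integer()),
                     tested = tab))
  }
  tab$start <- tab$bin * as.integer(bin_size)
  tab$end <- tab$start + as.integer(bin_size)
  tab$mean_a <- tab$m_a / tab$t_a
  tab$mean_b <- tab$m_b / tab$t_b
  tab$diff <- tab$mean_b - tab$mean_a
  tab$p <- vapply(seq_len(nrow(tab)), function(i) {
    fisher.test(matrix(c(tab$m_a[i], tab$t_a[i] - tab$m_a[i],
                         tab$m_b[i], tab$t_b[i] - tab$m_b[i]),
                       nrow = 2))$p.value
  }, numeric(1))
  tab$fdr <- p.adjust(tab$p, method = "BH")
  sig <- tab[abs(tab$diff) >= min_diff & tab$fdr < fdr, , drop = FALSE]
  sig$direction <- ifelse(sig$diff < 0, "hypo", "hyper")
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  ## merge same-direction runs within merge_gap
  merged <- list()
  if (nrow(sig)) {
    run <- cumsum(c(TRUE, !(sig$chrom[-1] == sig$chrom[-nrow(sig)] &
                              sig$direction[-1] == sig$direction[-nrow(sig)] &
                              sig$start[-1] - sig$end[-nrow(sig)] <= merge_gap)))
    merged <- lapply(split(seq_len(nrow(sig)), run), function(ii) {
      s <- sig[ii, , drop = FALSE]
      data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
                 mean_a = sum(s$m_a) / sum(s$t_a),
                 mean_b = sum(s$m_b) / sum(s$t_b),
                 diff = sum(s$m_b) / sum(s$t_b) - sum(s$m_a) / sum(s$t_a),
                 fdr = max(s$fdr), direction = s$direction[1],
                 n_bins = nrow(s), stringsAsFactors = FALSE)
    })
  }
  out <- if (length(merged)) do.call(rbind, merged) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               mean_a = numeric(), mean_b = numeric(), diff = numeric(),
               fdr = numeric(), direction = character(), n_bins = integer())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  keep <- c("chrom", "bin", "start", "end", "n_cg", "m_a", "t_a", "m_b",
            "t_b", "mean_a", "mean_b", "diff", "p", "fdr")
  structure(out, tested = tab[, keep])
}

#' TE-subfamily overlap with DMRs
#'
#' Per subfamily and DMR direction, the proportion of copies overlapping
#' at least one DMR. A copy overlapping both a hypo- and a hyper-DMR
#' counts once in each direction.
#'
#' @param dmrs output of [call_dmrs()] (or any interval data.frame with a
#'   `direction` column).
#' @param te_table TE annotation.
#' @return data.frame (subfamily, total, n_hypo, prop_hypo, n_hyper,
#'   prop_hyper).
#' @export
dmr_subfamily_overlap <- function(dmrs, te_table) {
  total <- table(te_table$subfamily)
  te_gr <- .as_gr(te_table)
  count_dir <- function(dir) {
    d <- dmrs[dmrs$direction == dir, , drop = FALSE]
    if (!nrow(d)) return(setNames(rep(0L, length(total)), names(total)))
    hit <- GenomicRanges::countOverlaps(te_gr, .as_gr(d),
                                        ignore.strand = TRUE) > 0L
    tab <- table(factor(te_table$subfamily[hit], levels = names(total)))
    setNames(as.integer(tab), names(total))
  }
  hypo <- count_dir("hypo")
  hyper <- count_dir("hyper")
  data.frame(subfamily = names(total), total = as.integer(total),
             n_hypo = as.integer(hypo),
             prop_hypo = as.integer(hypo) / as.integer(total),
             n_hyper = as.integer(hyper),
             prop_hyper = as.integer(hyper) / as.integer(total),
             stringsAsFactors = FALSE)
}
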