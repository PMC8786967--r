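## Toy-genome simulator. Generates, from a single seed, a small
## multi-chromosome genome with TE subfamilies (including LTR-like
## subfamilies in solo and proviral form), gene models, peak sets with a
## planted enriched subfamily, two-condition methylomes with planted
## hypomethylated copies, negative-binomial count matrices with planted
## differential copies, and planted guide target sites — each with a truth
## manifest so recovery can be scored exactly.

#' Default toy-genome configuration
#'
#' Three 2-Mb chromosomes; a subfamily roster with two LTR-like
#' subfamilies that occur both solo and as proviral units next to an
#' internal subfamily (gap bounded so the shipped solo/proviral
#' classification thresholds separate them exactly), plus background
#' SINE/LINE/SVA/LTR subfamilies; ~300 genes placed in TE-free space.
#'
#' @param chrom_lengths named chromosome lengths in bp.
#' @param n_genes number of genes.
#' @param divergence per-base substitution rate of copies from their
#'   subfamily consensus.
#' @param min_separation minimum bp between placed elements (keeps solo
#'   LTRs unambiguously far from internal copies).
#' @return configuration list.
#' @export
toy_genome_config <- function(chrom_lengths = c(chrTA = 2e6, chrTB = 2e6,
                                                chrTC = 2e6),
                              n_genes = 300, divergence = 0.05,
                              min_separation = 300) {
  roster <- data.frame(
    subfamily = c("LTR5S", "ERVKI", "LTR7S", "ERVHI",
                  "ALUY2", "L1T", "SVAT", "MER41T"),
    family = c("ERVK", "ERVK", "ERVH", "ERVH", "Alu", "L1", "SVA", "ERV1"),
    class = c("LTR", "LTR", "LTR", "LTR", "SINE", "LINE", "SVA", "LTR"),
    length = c(970L, 2000L, 450L, 1800L, 300L, 1500L, 1300L, 600L),
    n_copies = c(55L, 20L, 40L, 15L, 300L, 80L, 50L, 80L),
    role = c("ltr", "internal", "ltr", "internal",
             "background", "background", "background", "background"),
    partner = c("ERVKI", NA, "ERVHI", NA, NA, NA, NA, NA),
    n_proviral = c(20L, NA, 15L, NA, NA, NA, NA, NA),
    proviral_gap_max = c(99L, NA, 9L, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  list(chrom_lengths = chrom_lengths, roster = roster, n_genes = n_genes,
       gene_length_range = c(2000, 10000), max_exons = 4,
       divergence = divergence, min_separation = min_separation)
}

## place n non-overlapping spans of given widths; occupied is a per-chrom
## list of IRanges; returns df(chrom, start) and updates occupied by ref
.place_spans <- function(widths, chrom_lengths, occupied, margin,
                         label = "element") {
  chroms <- names(chrom_lengths)
  pr <- chrom_lengths / sum(chrom_lengths)
  out_chrom <- character(length(widths))
  out_start <- integer(length(widths))
  for (i in seq_along(widths)) {
    placed <- FALSE
    for (attempt in 1:2000) {
      chr <- sample(chroms, 1, prob = pr)
      L <- chrom_lengths[[chr]]
      if (widths[i] + 2 * margin >= L) next
      s <- floor(runif(1, margin, L - widths[i] - margin))
      cand <- IRanges::IRanges(s + 1L - margin, s + widths[i] + margin)
      if (!IRanges::countOverlaps(cand, occupied[[chr]])) {
        occupied[[chr]] <- c(occupied[[chr]],
                             IRanges::IRanges(s + 1L, s + widths[i]))
        out_chrom[i] <- chr
        out_start[i] <- as.integer(s)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place ", label, " ", i,
                      ": requested elements do not fit")
  }
  list(df = data.frame(chrom = out_chrom, start = out_start,
                       stringsAsFactors = FALSE),
       occupied = occupied)
}

## mutate a consensus sequence at a per-base substitution rate
.mutate_seq <- function(consensus, rate) {
  ch <- strsplit(consensus, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (j in hit) {
    ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
  }
  paste(ch, collapse = "")
}

#' Build the toy genome
#'
#' Generates the genome sequence, chromosome sizes, TE annotation, gene
#' models and a truth manifest, all as a pure function of
#' `(config, seed)`.
#'
#' @param config from [toy_genome_config()].
#' @param seed integer seed.
#' @return list with `genome` (DNAStringSet), `chrom_sizes`, `te_table`,
#'   `genes` (`gene_models`), and `truth` (planted layout: per-copy
#'   solo/proviral role, proviral gaps, consensus sequences, seed,
#'   config).
#' @export
build_toy_genome <- function(config = toy_genome_config(), seed = 1L) {
  withr::with_seed(seed, {
    cl <- config$chrom_lengths
    roster <- config$roster
    bases <- c("A", "C", "G", "T")
    raws <- charToRaw("ACGT")
    genome_raw <- lapply(cl, function(L) raws[sample.int(4, L, replace = TRUE)])
    consensus <- setNames(
      vapply(roster$length,
             function(w) paste(sample(bases, w, replace = TRUE), collapse = ""),
             character(1)),
      roster$subfamily)
    occupied <- setNames(lapply(cl, function(L) IRanges::IRanges()), names(cl))
    margin <- config$min_separation

    te_rows <- list()
    add_te <- function(chrom, start, len, sub) {
      r <- roster[roster$subfamily == sub, ]
      te_rows[[length(te_rows) + 1L]] <<- data.frame(
        chrom = chrom, start = as.integer(start),
        end = as.integer(start + len),
        strand = sample(c("+", "-"), 1),
        subfamily = sub, family = r$family, class = r$class,
        stringsAsFactors = FALSE)
    }
    write_seq <- function(chrom, start, seq) {
      genome_raw[[chrom]][(start + 1):(start + nchar(seq))] <<- charToRaw(seq)
    }

    truth_roles <- list()
    ## proviral units first (LTR + bounded gap + internal copy)
    for (k in which(roster$role == "ltr")) {
      sub <- roster$subfamily[k]
      partner <- roster$partner[k]
      np <- roster$n_proviral[k]
      gaps <- sample.int(roster$proviral_gap_max[k] + 1L, np, replace = TRUE) - 1L
      ltr_len <- roster$length[k]
      int_len <- roster$length[roster$subfamily == partner]
      widths <- ltr_len + gaps + int_len
      pl <- .place_spans(widths, cl, occupied, margin, paste0(sub, " provirus"))
      occupied <- pl$occupied
      for (i in seq_len(np)) {
        chr <- pl$df$chrom[i]; s <- pl$df$start[i]
        write_seq(chr, s, .mutate_seq(consensus[[sub]], config$divergence))
        add_te(chr, s, ltr_len, sub)
        s_int <- s + ltr_len + gaps[i]
        write_seq(chr, s_int, .mutate_seq(consensus[[partner]], config$divergence))
        add_te(chr, s_int, int_len, partner)
        truth_roles[[length(truth_roles) + 1L]] <- data.frame(
          subfamily = sub, chrom = chr, start = s, role = "proviral",
          gap = gaps[i], stringsAsFactors = FALSE)
      }
      ## solo copies
      ns <- roster$n_copies[k] - np
      pl <- .place_spans(rep(ltr_len, ns), cl, occupied, margin,
                         paste0(sub, " solo"))
      occupied <- pl$occupied
      for (i in seq_len(ns)) {
        chr <- pl$df$chrom[i]; s <- pl$df$start[i]
        write_seq(chr, s, .mutate_seq(consensus[[sub]], config$divergence))
        add_te(chr, s, ltr_len, sub)
        truth_roles[[length(truth_roles) + 1L]] <- data.frame(
          subfamily = sub, chrom = chr, start = s, role = "solo",
          gap = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    ## background subfamilies
    for (k in which(roster$role == "background")) {
      sub <- roster$subfamily[k]
      n <- roster$n_copies[k]
      pl <- .place_spans(rep(roster$length[k], n), cl, occupied, margin, sub)
      occupied <- pl$occupied
      for (i in seq_len(n)) {
        chr <- pl$df$chrom[i]; s <- pl$df$start[i]
        write_seq(chr, s, .mutate_seq(consensus[[sub]], config$divergence))
        add_te(chr, s, roster$length[k], sub)
      }
    }
    te_table <- do.call(rbind, te_rows)
    te_table <- te_table[order(te_table$chrom, te_table$start), ]
    rownames(te_table) <- NULL

    ## genes in the remaining (TE-free) space
    glen <- floor(runif(config$n_genes, config$gene_length_range[1],
                        config$gene_length_range[2] + 1))
    pl <- .place_spans(glen, cl, occupied, margin, "gene")
    occupied <- pl$occupied
    genes <- data.frame(gene_id = sprintf("gene_%03d", seq_len(config$n_genes)),
                        chrom = pl$df$chrom, start = pl$df$start,
                        end = pl$df$start + as.integer(glen),
                        strand = sample(c("+", "-"), config$n_genes,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
      k <- sample.int(config$max_exons, 1)
      if (k == 1) {
        return(data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                          start = genes$start[i], end = genes$end[i],
                          stringsAsFactors = FALSE))
      }
      cuts <- sort(sample((genes$start[i] + 1):(genes$end[i] - 1), 2 * k - 2))
      edges <- c(genes$start[i], cuts, genes$end[i])
      idx <- seq(1, 2 * k - 1, by = 2)
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = edges[idx], end = edges[idx + 1],
                 stringsAsFactors = FALSE)
    }))
    chrom_sizes <- setNames(as.integer(cl), names(cl))
    gm <- gene_models(genes, exons, chrom_sizes)
    genome <- Biostrings::DNAStringSet(
      vapply(genome_raw, rawToChar, character(1)))
    names(genome) <- names(cl)
    list(genome = genome,
         chrom_sizes = chrom_sizes,
         te_table = te_table,
         genes = gm,
         truth = list(seed = seed, config = config, consensus = consensus,
                      ltr_roles = do.call(rbind, truth_roles)))
  })
}

#' Simulate per-cell-type peak sets with a planted enriched subfamily
#'
#' For each cell type, a fraction of regions is placed over copies of that
#' cell type's planted subfamily so the subfamily is hit at `fold` times
#' the rate expected for a uniformly placed region of the same length; the
#' remaining regions are uniform. `fold <= 1` yields fully uniform (null)
#' regions. Peaks carry a fold-enrichment score; a small decoy fraction
#' gets sub-threshold scores to exercise the peak filter.
#'
#' @param toy output of [build_toy_genome()].
#' @param enriched named character vector: cell type -> planted subfamily
#'   (subfamilies should be disjoint between cell types).
#' @param fold planted enrichment factor.
#' @param n_regions regions per cell type.
#' @param region_len_range min/max region length in bp.
#' @param decoy_frac fraction of extra low-score decoy peaks.
#' @param seed integer seed.
#' @return list with `peak_sets` (named list of interval data.frames with
#'   a `score` column) and `truth`.
#' @export
simulate_open_regions <- function(toy, enriched = c(cellA = "LTR5S",
                                                    cellB = "ALUY2"),
                                  fold = 5, n_regions = 200,
                                  region_len_range = c(300, 600),
                                  decoy_frac = 0.1, seed = 1L) {
  te <- toy$te_table
  cl <- toy$chrom_sizes
  withr::with_seed(seed, {
    sets <- lapply(names(enriched), function(ct) {
      sub <- enriched[[ct]]
      copies <- te[te$subfamily == sub, , drop = FALSE]
      if (!nrow(copies)) stop("planted subfamily absent: ", sub)
      if (n_regions == 0) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), score = numeric(),
                          planted = logical(), stringsAsFactors = FALSE))
      }
      lens <- floor(runif(n_regions, region_len_range[1],
                          region_len_range[2] + 1))
      ## chance that a uniform region of mean length overlaps >= 1 copy
      p0 <- sum(copies$end - copies$start + mean(lens) - 1) / sum(cl)
      n_hit <- if (fold <= 1) 0L else
        min(n_regions, max(0L, round(fold * p0 * n_regions)))
      idx <- sample.int(nrow(copies), n_hit, replace = n_hit > nrow(copies))
      rows <- lapply(seq_len(n_regions), function(i) {
        if (i <= n_hit) {
          cp <- copies[idx[i], ]
          mid <- (cp$start + cp$end) %/% 2
          s <- mid - lens[i] %/% 2 + sample(-50:50, 1)
          chr <- cp$chrom
        } else {
          chr <- sample(names(cl), 1, prob = cl / sum(cl))
          s <- floor(runif(1, 0, cl[[chr]] - lens[i]))
        }
        s <- max(0, min(s, cl[[chr]] - lens[i]))
        data.frame(chrom = chr, start = as.integer(s),
                   end = as.integer(s + lens[i]),
                   score = round(runif(1, 4.5, 25), 2),
                   planted = i <= n_hit, stringsAsFactors = FALSE)
      })
      peaks <- do.call(rbind, rows)
      n_decoy <- round(decoy_frac * n_regions)
      if (n_decoy > 0) {
        dl <- floor(runif(n_decoy, region_len_range[1],
                          region_len_range[2] + 1))
        dchr <- sample(names(cl), n_decoy, replace = TRUE, prob = cl / sum(cl))
        ds <- floor(runif(n_decoy, 0, unname(cl[dchr]) - dl))
        peaks <- rbind(peaks, data.frame(
          chrom = dchr, start = as.integer(ds), end = as.integer(ds + dl),
          score = round(runif(n_decoy, 1, 4), 2), planted = FALSE,
          stringsAsFactors = FALSE))
      }
      peaks <- peaks[order(peaks$chrom, peaks$start), ]
      rownames(peaks) <- NULL
      peaks
    })
    names(sets) <- names(enriched)
    list(peak_sets = sets,
         truth = list(enriched = enriched, fold = fold,
                      n_regions = n_regions, seed = seed))
  })
}

#' Simulate two-condition methylomes with planted hypomethylation
#'
#' One CG site per CG dinucleotide of the toy genome. Per site,
#' `count_total ~ Poisson(coverage_mean)` and
#' `count_m ~ Binomial(count_total, level)`; the level is `base_level`
#' everywhere except over copies of `dmr_subfamily` in condition B, where
#' it is lowered by `delta`.
#'
#' @param toy output of [build_toy_genome()].
#' @param base_level background methylation level.
#' @param dmr_subfamily subfamily whose copies are demethylated in B.
#' @param delta methylation drop over planted copies.
#' @param coverage_mean mean per-site read coverage.
#' @param seed integer seed.
#' @param chroms optional subset of chromosomes to simulate.
#' @return list with `a`, `b` (site data.frames) and `truth` (planted
#'   intervals).
#' @export
simulate_methylomes <- function(toy, base_level = 0.8,
                                dmr_subfamily = "LTR5S", delta = 0.6,
                                coverage_mean = 30, seed = 1L,
                                chroms = NULL) {
  if (is.null(chroms)) chroms <- names(toy$chrom_sizes)
  planted <- toy$te_table[toy$te_table$subfamily == dmr_subfamily &
                            toy$te_table$chrom %in% chroms, , drop = FALSE]
  withr::with_seed(seed, {
    sites <- do.call(rbind, lapply(chroms, function(chr) {
      pos <- IRanges::start(Biostrings::matchPattern("CG", toy$genome[[chr]])) - 1L
      data.frame(chrom = chr, pos = pos, strand = "+", context = "CG",
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(sites)
    in_planted <- rep(FALSE, n)
    if (nrow(planted)) {
      pts <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L,
                                                     sites$pos + 1L))
      in_planted <- GenomicRanges::countOverlaps(
        pts, .as_gr(planted), ignore.strand = TRUE) > 0L
    }
    lv_a <- rep(base_level, n)
    lv_b <- ifelse(in_planted, pmax(0, base_level - delta), base_level)
    draw <- function(level) {
      tot <- rpois(n, coverage_mean)
      m <- rbinom(n, tot, level)
      cbind(m = m, tot = tot)
    }
    da <- draw(lv_a)
    db <- draw(lv_b)
    a <- cbind(sites, count_m = da[, "m"], count_total = da[, "tot"])
    b <- cbind(sites, count_m = db[, "m"], count_total = db[, "tot"])
    list(a = a, b = b,
         truth = list(planted = planted, delta = delta,
                      base_level = base_level, seed = seed))
  })
}

#' Simulate copy-level count matrices with planted differential copies
#'
#' Negative-binomial counts for a two-group design. Planted features get
#' their group-B mean multiplied by `planted_fc`; when `planted_subfamily`
#' is given (and `te_table` features are used) the planted set is
#' concentrated there first, spilling over to random other copies.
#' Per-sample library-size factors vary uniformly by `+/- libsize_cv`.
#'
#' @param design named sample -> group vector (two groups; B = second
#'   level is the perturbed group).
#' @param te_table optional TE annotation supplying features (ids from
#'   [te_copy_id()], lengths from the spans).
#' @param n_features feature count when no `te_table` is given.
#' @param planted_fc fold change applied to planted features in group B.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param planted_frac fraction of features planted.
#' @param planted_subfamily optional subfamily to concentrate planted
#'   copies in.
#' @param libsize_cv half-range of the uniform library-size factor.
#' @param seed integer seed.
#' @return list with `counts`, `lengths`, `design` and `truth` (planted
#'   ids, sample factors).
#' @export
simulate_counts <- function(design, te_table = NULL, n_features = 2000,
                            planted_fc = 8, dispersion = 0.05,
                            planted_frac = 0.05, planted_subfamily = NULL,
                            libsize_cv = 0.3, seed = 1L) {
  f <- factor(design)
  stopifnot(nlevels(f) == 2)
  withr::with_seed(seed, {
    if (!is.null(te_table)) {
      ids <- te_copy_id(te_table)
      lengths <- setNames(as.numeric(te_table$end - te_table$start), ids)
    } else {
      ids <- sprintf("feat_%05d", seq_len(n_features))
      lengths <- setNames(floor(runif(n_features, 300, 3000)), ids)
    }
    n <- length(ids)
    n_planted <- round(planted_frac * n)
    if (planted_fc == 1) n_planted <- 0L
    planted <- character(0)
    if (n_planted > 0) {
      if (!is.null(planted_subfamily) && !is.null(te_table)) {
        first <- ids[te_table$subfamily == planted_subfamily]
        planted <- head(first, n_planted)
        rest <- setdiff(ids, first)
        if (length(planted) < n_planted) {
          planted <- c(planted,
                       sample(rest, n_planted - length(planted)))
        }
      } else {
        planted <- sample(ids, n_planted)
      }
    }
    base <- setNames(10^runif(n, log10(20), log10(500)), ids)
    fc <- setNames(rep(1, n), ids)
    fc[planted] <- planted_fc
    sfac <- setNames(runif(length(design), 1 - libsize_cv, 1 + libsize_cv),
                     names(design))
    groupB <- levels(f)[2]
    counts <- vapply(names(design), function(s) {
      mu <- base * (if (design[[s]] == groupB) fc else 1) * sfac[[s]]
      if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
      else rpois(n, mu)
    }, numeric(n))
    counts <- matrix(as.integer(counts), nrow = n,
                     dimnames = list(ids, names(design)))
    list(counts = counts, lengths = lengths, design = design,
         truth = list(planted = planted, planted_fc = planted_fc,
                      dispersion = dispersion, sample_factors = sfac,
                      base_means = base, seed = seed))
  })
}

#' Plant guide target sites at known mismatch counts
#'
#' Writes, for each requested mismatch count `k`, a variant of the pattern
#' with exactly `k` substitutions at non-degenerate positions (degenerate
#' positions are filled with a random concrete base at zero cost) into the
#' genome at a random free locus, on the requested strand (minus-strand
#' plants are written reverse-complemented).
#'
#' @param genome `Biostrings::DNAStringSet`.
#' @param pattern IUPAC pattern string (e.g. a guide + PAM 23-mer).
#' @param mismatches integer vector, one planted site per entry.
#' @param strands strand per site (recycled; default alternating).
#' @param avoid optional interval data.frame of regions not to write into.
#' @param margin bp kept clear around avoided regions and other plants.
#' @param seed integer seed.
#' @return list with `genome` (modified) and `truth`
#'   (chrom, start, end, strand, mismatches, planted_seq).
#' @export
plant_guide_sites <- function(genome, pattern, mismatches = 0:4,
                              strands = NULL, avoid = NULL, margin = 50,
                              seed = 1L) {
  pattern <- toupper(pattern)
  ch <- strsplit(pattern, "")[[1]]
  concrete <- ch %in% c("A", "C", "G", "T")
  if (is.null(strands)) {
    strands <- rep(c("+", "-"), length.out = length(mismatches))
  }
  strands <- rep_len(strands, length(mismatches))
  cl <- setNames(Biostrings::width(genome), names(genome))
  withr::with_seed(seed, {
    occupied <- setNames(lapply(cl, function(L) IRanges::IRanges()),
                         names(cl))
    if (!is.null(avoid)) {
      for (chr in unique(avoid$chrom)) {
        av <- avoid[avoid$chrom == chr, ]
        occupied[[chr]] <- IRanges::reduce(
          IRanges::IRanges(av$start + 1L, av$end))
      }
    }
    truth <- list()
    for (i in seq_along(mismatches)) {
      k <- mismatches[i]
      stopifnot(k <= sum(concrete))
      v <- ch
      v[!concrete] <- sample(c("A", "C", "G", "T"), sum(!concrete),
                             replace = TRUE)
      flip <- sample(which(concrete), k)
      for (j in flip) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
      variant <- paste(v, collapse = "")
      insert <- if (strands[i] == "+") variant else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(variant)))
      pl <- .place_spans(nchar(insert), cl, occupied, margin, "guide site")
      occupied <- pl$occupied
      chr <- pl$df$chrom[1]; s <- pl$df$start[1]
      gseq <- genome[[chr]]
      Biostrings::subseq(gseq, s + 1L, s + nchar(insert)) <-
        Biostrings::DNAString(insert)
      genome[[chr]] <- gseq
      truth[[i]] <- data.frame(chrom = chr, start = s,
                               end = s + nchar(insert), strand = strands[i],
                               mismatches = as.integer(k),
                               planted_seq = variant,
                               stringsAsFactors = FALSE)
    }
    list(genome = genome, truth = do.call(rbind, truth))
  })
}
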