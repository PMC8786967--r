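## Shared fixtures and independent oracles. The toy genome is expensive to
## build, so it is constructed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixture_env$toy)) {
    .fixture_env$toy <- build_toy_genome(seed = 1)
  }
  .fixture_env$toy
}

partition_fixture <- function() {
  if (is.null(.fixture_env$partition)) {
    toy <- toy_fixture()
    .fixture_env$partition <- partition_genome(toy$genes, toy$chrom_sizes)
  }
  .fixture_env$partition
}

## ---- independent oracles -------------------------------------------------

## brute-force BH step-up adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## exact binomial upper/lower tail by term-wise summation
oracle_binom_upper <- function(k, n, p) sum(dbinom(k:n, n, p))
oracle_binom_lower <- function(k, n, p) sum(dbinom(0:k, n, p))

## exact hypergeometric upper tail by enumeration
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## all-pairs nearest distance under the gap+1 convention
oracle_nearest <- function(query, subjects) {
  vapply(seq_len(nrow(query)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(subjects))) {
      if (query$chrom[i] != subjects$chrom[j]) next
      if (query$start[i] < subjects$end[j] &&
            subjects$start[j] < query$end[i]) return(0)
      gap <- max(subjects$start[j] - query$end[i],
                 query$start[i] - subjects$end[j])
      best <- min(best, gap + 1)
    }
    best
  }, numeric(1))
}

## naive per-offset Hamming scan of a genome for an IUPAC pattern
oracle_guide_scan <- function(genome, pattern, name, max_mm) {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  res <- list()
  for (chr in names(genome)) {
    bytes <- charToRaw(as.character(genome[[chr]]))
    L <- length(bytes)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pattern else revcomp(pattern)
      ch <- strsplit(pat, "")[[1]]
      P <- length(ch)
      if (P > L) next
      n_off <- L - P + 1L
      mm <- integer(n_off)
      for (j in seq_len(P)) {
        if (!(ch[j] %in% c("A", "C", "G", "T"))) next
        mm <- mm + (bytes[j:(j + n_off - 1L)] != charToRaw(ch[j]))
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = chr, start = hit - 1L, end = hit - 1L + P,
          strand = strand, guide = name, mismatches = mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      guide = character(), mismatches = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start, out$strand), ]
}

## small deterministic interval set generator for property tests
random_intervals <- function(n, chrom_sizes, max_len = 500) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, unname(chrom_sizes[chrom]) - len))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), stringsAsFactors = FALSE)
}
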