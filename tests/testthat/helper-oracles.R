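# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities by enumeration / dense arrays rather than calling the
# package's own algorithms.

# Per-base representation of an interval: set of "chrom:pos" strings.
base_set <- function(chrom, start, end) {
  if (end <= start) return(character(0))
  paste0(chrom, ":", start:(end - 1))
}

random_interval <- function(chroms = c("chr1", "chr2"), max_pos = 200) {
  s <- sample.int(max_pos, 1) - 1L
  e <- s + sample.int(30, 1)
  genomic_intervals(sample(chroms, 1), s, e,
                    strand = sample(c("+", "-", "."), 1))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(m+n, m) group assignments of the pooled ranks.
wilcoxon_enum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  W_null <- apply(combos, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(W_null <= W_obs), mean(W_null >= W_obs)))
}

# Max contiguous complementary run over all antiparallel offsets, written
# independently of the package scanner.
kissing_enum_max <- function(a_str, b_str, allow_wobble = TRUE) {
  a <- strsplit(toupper(a_str), "")[[1]]
  b <- strsplit(toupper(b_str), "")[[1]]
  rb <- rev(b)
  comp <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AU", "UA", "GC", "CG") || (allow_wobble && p %in% c("GU", "UG"))
  }
  best <- 0L
  for (off in -(length(b) - 1):(length(a) - 1)) {
    run <- 0L
    for (i in seq_along(a)) {
      j <- i - off
      if (j >= 1 && j <= length(rb) && comp(a[i], rb[j])) {
        run <- run + 1L
        best <- max(best, run)
      } else {
        run <- 0L
      }
    }
  }
  best
}

# Sliding-window both-strand motif count with position dedup.
motif_window_count <- function(seq, motif) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  k <- nchar(motif)
  n <- nchar(seq)
  if (n < k) return(0L)
  hits <- vapply(1:(n - k + 1), function(i) {
    w <- substr(seq, i, i + k - 1)
    w == motif || w == revcomp(motif)
  }, logical(1))
  sum(hits)
}

random_dna_string <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

tiny_cohort <- function(n = 80, seed = 11, ...) {
  generate_cohort(cohort_params(n_tl = n, seed = seed, ...))
}

features_of <- function(co, ...) {
  build_feature_table(co$tls, promoters = co$promoters, splice3 = co$splice3,
                      cage_peaks = co$cage_peaks, rnaseq = co$rnaseq, ...)
}
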