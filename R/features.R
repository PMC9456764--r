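#' GC content of a DNA sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator
#' and denominator. High GC is a hallmark of promoter regions, and
#' reporter-active TLs tend to be GC-richer than inactive ones.
#'
#' @param sequence Character vector of DNA sequences over `A,C,G,T,N`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_content(c("ACGT", "GGGG", "GCAN"))
#' @export
gc_content <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    counts <- table(strsplit(s, "")[[1]])
    acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
    if (acgt == 0) abort("gc_content: sequence empty or all-N")
    gc <- sum(counts[intersect(names(counts), c("G", "C"))])
    gc / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count motif occurrences on both strands
#'
#' Number of distinct start positions at which `motif` or its reverse
#' complement matches exactly. For palindromic motifs (such as the E-box
#' core `CACGTG`) both strands give the same positions, which are counted
#' once. Overlapping occurrences count separately. `N` in the sequence never
#' matches.
#'
#' @param sequence Character vector of DNA sequences.
#' @param motif Single motif over `A,C,G,T`, e.g. `"CACGTG"`.
#' @return Integer vector of counts.
#' @examples
#' count_motif("GACACGTGAC", "CACGTG") # 1
#' count_motif("GACACTATAC", "CACGTG") # 0
#' @export
count_motif <- function(sequence, motif) {
  stopifnot(length(motif) == 1, grepl("^[ACGT]+$", motif))
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  vapply(toupper(sequence), function(s) {
    subj <- Biostrings::DNAString(s)
    starts <- Biostrings::start(Biostrings::matchPattern(fwd, subj, fixed = TRUE))
    starts <- union(starts,
                    Biostrings::start(Biostrings::matchPattern(rev, subj, fixed = TRUE)))
    length(starts)
  }, integer(1), USE.NAMES = FALSE)
}

#' Promoter overlap and containment counts for a TL
#'
#' `any_count` is the number of promoter annotations sharing at least one
#' base with the TL; `full_count` the number lying entirely inside it (a
#' fully contained promoter is direct evidence for an internal transcription
#' unit). Also reports the fraction of TL bases covered by the promoter
#' union, an alternative encoding of promoter load.
#'
#' @param tl Single-row interval tibble for the TL.
#' @param promoters Interval tibble of promoter/enhancer annotations.
#' @return A one-row tibble with `promoter_any_count`, `promoter_full_count`,
#'   `promoter_coverage_fraction`.
#' @export
promoter_features <- function(tl, promoters) {
  validate_intervals(tl); stopifnot(nrow(tl) == 1)
  if (is.null(promoters) || nrow(promoters) == 0) {
    return(tibble(promoter_any_count = 0L, promoter_full_count = 0L,
                  promoter_coverage_fraction = 0))
  }
  tl_rep <- tl[rep(1, nrow(promoters)), ]
  any_hit <- interval_overlaps(tl_rep, promoters)
  full_hit <- interval_contains(tl_rep, promoters)
  tibble(
    promoter_any_count = sum(any_hit),
    promoter_full_count = sum(full_hit),
    promoter_coverage_fraction =
      union_covered_length(promoters, tl) / (tl$end - tl$start)
  )
}

#' 3' splice sites inside a TL
#'
#' Counts annotated 3' splice sites (1-bp intron acceptor-end points) lying
#' within the TL but excluding its 5'-most base: an acceptor coinciding with
#' the annotated transcription start cannot splice the reporter internally.
#'
#' @param tl Single-row interval tibble.
#' @param splice3_sites Interval tibble of 1-bp points.
#' @param exclude_5prime_base Drop sites at the TL's strand-aware 5'-most
#'   base (default TRUE).
#' @return One-row tibble with `splice3_count` and `has_splice3`.
#' @export
splice3_features <- function(tl, splice3_sites, exclude_5prime_base = TRUE) {
  validate_intervals(tl); stopifnot(nrow(tl) == 1)
  if (is.null(splice3_sites) || nrow(splice3_sites) == 0) {
    return(tibble(splice3_count = 0L, has_splice3 = FALSE))
  }
  validate_intervals(splice3_sites)
  pos <- splice3_sites$start
  inside <- splice3_sites$chrom == tl$chrom & pos >= tl$start & pos < tl$end
  if (exclude_5prime_base) {
    inside <- inside & pos != five_prime_end(tl)
  }
  tibble(splice3_count = sum(inside), has_splice3 = any(inside))
}

#' CAGE TSS-peak features for a TL
#'
#' Each peak overlapping the TL is classified by the distance from its
#' summit to the TL's strand-aware 5' end: within `window_nt` bases it is
#' "5'-proximal" (supports the annotated start), otherwise "internal"
#' (supports internal transcription initiation, the signature of a cryptic
#' promoter). Returns the fraction of CAGE reads in 5'-proximal peaks, the
#' reads in internal peaks, and whether the strongest (max-read) peak is
#' internal. With no overlapping peaks all three are `NA` (missing, not
#' zero: absence of CAGE data is not evidence).
#'
#' @param tl Single-row interval tibble.
#' @param peaks Peak tibble: interval columns plus `summit` (0-based
#'   position; defaults to the interval midpoint when absent/NA) and
#'   `read_count`.
#' @param window_nt 5'-proximity window in nucleotides (default 10).
#' @return One-row tibble with `cage_5prime_fraction`, `cage_internal_reads`,
#'   `strongest_peak_internal`.
#' @export
cage_features <- function(tl, peaks, window_nt = 10) {
  validate_intervals(tl); stopifnot(nrow(tl) == 1)
  if (window_nt < 0) abort("cage_features: window_nt must be >= 0")
  empty <- tibble(cage_5prime_fraction = NA_real_,
                  cage_internal_reads = NA_real_,
                  strongest_peak_internal = NA)
  if (is.null(peaks) || nrow(peaks) == 0) return(empty)
  validate_intervals(peaks, "peak set")
  if (!"read_count" %in% names(peaks)) abort("cage_features: peaks need read_count")
  summit <- if ("summit" %in% names(peaks)) peaks$summit else rep(NA_real_, nrow(peaks))
  summit <- ifelse(is.na(summit), floor((peaks$start + peaks$end - 1) / 2), summit)
  hit <- interval_overlaps(tl[rep(1, nrow(peaks)), ], peaks)
  if (!any(hit)) return(empty)
  summit <- summit[hit]
  reads <- peaks$read_count[hit]
  dist5 <- abs(summit - five_prime_end(tl))
  proximal <- dist5 <= window_nt
  total <- sum(reads)
  tibble(
    cage_5prime_fraction = if (total > 0) sum(reads[proximal]) / total else NA_real_,
    cage_internal_reads = sum(reads[!proximal]),
    strongest_peak_internal = !proximal[which.max(reads)]
  )
}

#' RNA-seq 5'/3' half coverage ratio
#'
#' Splits the TL into a strand-aware 5' half (the first `ceiling(L/2)` nt)
#' and 3' half, and returns `(sum5 + pseudocount) / (sum3 + pseudocount)`.
#' Full-length transcription gives a ratio near 1; internal initiation
#' depletes the 5' half and drives the ratio toward 0.
#'
#' @param tl Single-row interval tibble, length >= 2.
#' @param coverage Signal-track tibble (aggregate across datasets first via
#'   [merge_tracks()]).
#' @param pseudocount Added to both halves to keep the ratio finite
#'   (default 1).
#' @return A single positive number.
#' @export
rnaseq_bias <- function(tl, coverage, pseudocount = 1) {
  validate_intervals(tl); stopifnot(nrow(tl) == 1)
  L <- tl$end - tl$start
  if (L < 2) abort("rnaseq_bias: TL shorter than 2 nt")
  half5_len <- ceiling(L / 2)
  strand <- if ("strand" %in% names(tl)) tl$strand else "."
  if (strand == "-") {
    half5 <- genomic_intervals(tl$chrom, tl$end - half5_len, tl$end, strand)
    half3 <- genomic_intervals(tl$chrom, tl$start, tl$end - half5_len, strand)
  } else {
    half5 <- genomic_intervals(tl$chrom, tl$start, tl$start + half5_len, strand)
    half3 <- genomic_intervals(tl$chrom, tl$start + half5_len, tl$end, strand)
  }
  (track_sum(coverage, half5) + pseudocount) /
    (track_sum(coverage, half3) + pseudocount)
}

#' Fraction of TL bases covered by annotated CDS
#'
#' CDS overlap from alternative isoforms is an alternative explanation for
#' TL hyperconservation. Union coverage: overlapping CDS intervals are not
#' double counted.
#'
#' @param tl Single-row interval tibble.
#' @param cds_intervals Interval tibble of CDS annotations.
#' @return Fraction in `[0, 1]`.
#' @export
cds_overlap_fraction <- function(tl, cds_intervals) {
  validate_intervals(tl); stopifnot(nrow(tl) == 1)
  union_covered_length(cds_intervals, tl) / (tl$end - tl$start)
}

ebox_core <- "CACGTG"
ebox_extended <- "GACACGTGAC"

#' Assemble the per-TL feature table
#'
#' Runs the whole feature battery over a TL cohort: sequence features (length,
#' GC content, E-box core `CACGTG` and extended `GACACGTGAC` counts),
#' annotation features (promoter overlap/containment, 3' splice sites, CDS
#' coverage), CAGE TSS features, and the RNA-seq 5'/3' bias. CAGE-derived
#' cells are `NA` for TLs with no overlapping peaks. Label and
#' hyperconserved columns of `tls` are carried through.
#'
#' @param tls TL tibble: columns `tl_id`, `chrom`, `start`, `end`, `strand`,
#'   `sequence`, optionally `label`, `hyperconserved`.
#' @param promoters,splice3,cds Interval tibbles (or NULL).
#' @param cage_peaks Peak tibble with `summit`, `read_count` (or NULL: CAGE
#'   features missing).
#' @param rnaseq Signal-track tibble of aggregate coverage (or NULL: bias
#'   computed on zero coverage, i.e. 1 by pseudocounting).
#' @param window_nt,pseudocount See [cage_features()], [rnaseq_bias()].
#' @return A feature-table tibble, one row per TL, deterministic in its
#'   inputs.
#' @export
build_feature_table <- function(tls, promoters = NULL, splice3 = NULL,
                                cds = NULL, cage_peaks = NULL, rnaseq = NULL,
                                window_nt = 10, pseudocount = 1) {
  stopifnot(is.data.frame(tls), all(c("tl_id", "sequence") %in% names(tls)))
  validate_intervals(tls, "TL set")
  if (anyDuplicated(tls$tl_id)) {
    abort(sprintf("build_feature_table: duplicate TL id '%s'",
                  tls$tl_id[duplicated(tls$tl_id)][1]))
  }
  if (is.null(rnaseq)) rnaseq <- signal_track()
  rows <- lapply(seq_len(nrow(tls)), function(i) {
    tl <- tls[i, ]
    bind_cols(
      tibble(tl_id = tl$tl_id,
             length = tl$end - tl$start,
             gc_content = gc_content(tl$sequence),
             ebox_core_count = count_motif(tl$sequence, ebox_core),
             ebox_extended_count = count_motif(tl$sequence, ebox_extended)),
      promoter_features(tl, promoters),
      splice3_features(tl, splice3),
      cage_features(tl, cage_peaks, window_nt = window_nt),
      tibble(rnaseq_bias = rnaseq_bias(tl, rnaseq, pseudocount = pseudocount),
             cds_overlap_fraction = cds_overlap_fraction(tl, cds))
    )
  })
  out <- list_rbind(rows)
  if ("label" %in% names(tls)) out$label <- tls$label
  if ("hyperconserved" %in% names(tls)) out$hyperconserved <- tls$hyperconserved
  out
}
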