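#' Genomic intervals as tibbles
#'
#' All coordinates in tlaudit use the BED convention: 0-based, half-open
#' `[start, end)`. An interval tibble has columns `chrom` (character),
#' `start`, `end` (integers, `start < end`), `strand` (one of `"+"`, `"-"`,
#' `"."`), and optionally `name` and `score`. `genomic_intervals()` builds
#' and validates such a tibble; most other functions accept any data frame
#' with these columns.
#'
#' @param chrom Character vector of chromosome (or contig) names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Strand, `"+"`, `"-"` or `"."` (recycled).
#' @param name Optional feature label (recycled).
#' @param score Optional numeric score (recycled).
#' @return A tibble with one row per interval.
#' @examples
#' genomic_intervals("chr1", c(0L, 50L), c(100L, 150L), strand = "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                              score = NA_real_) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    name = as.character(name),
    score = as.numeric(score)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (anyNA(x$start) || anyNA(x$end) || any(x$start < 0)) {
      abort(paste0(what, ": starts must be non-negative integers"))
    }
    bad <- which(x$start >= x$end)
    if (length(bad) > 0) {
      abort(sprintf("%s: start >= end at row %d (%s:%d-%d)", what, bad[1],
                    x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
    }
    if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
      abort(paste0(what, ": strand must be one of '+', '-', '.'"))
    }
  }
  invisible(x)
}

#' Strand-aware 5' end of an interval
#'
#' The 5'-most base of the interval: `start` on the `+` strand, `end - 1` on
#' the `-` strand. Unstranded (`"."`) intervals are treated as `+` with a
#' one-time warning.
#'
#' @param intervals Interval tibble (see [genomic_intervals()]).
#' @return Integer vector of 0-based positions.
#' @export
five_prime_end <- function(intervals) {
  validate_intervals(intervals)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", nrow(intervals))
  if (any(strand == ".")) {
    warn("unstranded interval(s): treating '.' as '+' for 5'-end arithmetic",
         .frequency = "once", .frequency_id = "tlaudit_unstranded")
  }
  ifelse(strand == "-", intervals$end - 1L, intervals$start)
}

#' Pairwise interval overlap and containment
#'
#' `interval_overlaps()` is TRUE where intervals share a chromosome and at
#' least one base (half-open: abutting intervals do not overlap).
#' `interval_contains()` is TRUE where `inner` lies entirely within `outer`.
#' Both are strand-blind and vectorized row-wise with recycling.
#'
#' @param a,b,outer,inner Interval tibbles (rows recycled to a common length).
#' @return Logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 0, 100)
#' b <- genomic_intervals("chr1", c(50, 100), c(150, 200))
#' interval_overlaps(a, b) # TRUE FALSE
#' @export
interval_overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' @rdname interval_overlaps
#' @export
interval_contains <- function(outer, inner) {
  validate_intervals(outer); validate_intervals(inner)
  outer$chrom == inner$chrom & outer$start <= inner$start & inner$end <= outer$end
}

#' Bases of a window covered by a union of intervals
#'
#' Length of the intersection between `within` and the union of `intervals`,
#' counting each base once regardless of how many intervals cover it.
#'
#' @param intervals Interval tibble (may be empty).
#' @param within A single-row interval tibble.
#' @return Integer number of covered bases, in `[0, end - start]`.
#' @examples
#' w <- genomic_intervals("chr1", 0, 100)
#' s <- genomic_intervals("chr1", c(10, 40), c(60, 90))
#' union_covered_length(s, w) # 80
#' @export
union_covered_length <- function(intervals, within) {
  validate_intervals(within)
  stopifnot(nrow(within) == 1)
  if (is.null(intervals) || nrow(intervals) == 0) return(0L)
  validate_intervals(intervals)
  x <- intervals[intervals$chrom == within$chrom, , drop = FALSE]
  if (nrow(x) == 0) return(0L)
  s <- pmax(x$start, within$start)
  e <- pmin(x$end, within$end)
  keep <- s < e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  covered <- 0L
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  as.integer(covered + (cur_e - cur_s))
}

#' Signal tracks as sparse per-base tibbles
#'
#' A signal track is a tibble with columns `chrom`, `pos` (0-based base
#' position) and `count` (non-negative); absent positions are zero. This is
#' the in-memory form of a bedGraph (see [read_bedgraph()]) and carries CAGE
#' 5'-end counts or RNA-seq coverage.
#'
#' @param chrom,pos,count Parallel vectors.
#' @return A signal-track tibble with duplicated positions summed.
#' @export
signal_track <- function(chrom = character(), pos = integer(), count = numeric()) {
  x <- tibble(chrom = as.character(chrom), pos = as.integer(pos),
              count = as.numeric(count))
  validate_track(x)
  x |>
    group_by(.data$chrom, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

validate_track <- function(x, what = "signal track") {
  need <- c("chrom", "pos", "count")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(paste0(what, " must have columns chrom, pos, count"))
  }
  if (nrow(x) > 0 && any(x$count < 0)) abort(paste0(what, ": negative counts"))
  invisible(x)
}

#' Total track signal over a region
#'
#' Sums the track values at positions in `[start, end)` of `region`.
#'
#' @param track Signal-track tibble ([signal_track()]).
#' @param region Single-row interval tibble.
#' @return A single number (0 for empty overlap).
#' @export
track_sum <- function(track, region) {
  validate_track(track)
  validate_intervals(region)
  stopifnot(nrow(region) == 1)
  sel <- track$chrom == region$chrom & track$pos >= region$start & track$pos < region$end
  sum(track$count[sel])
}

#' Total mass of a signal track
#' @param track Signal-track tibble.
#' @return Sum of all counts.
#' @export
track_mass <- function(track) {
  validate_track(track)
  sum(track$count)
}
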