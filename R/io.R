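#' Read and write BED intervals
#'
#' `read_bed()` parses BED3-BED6 (tab-separated; `track`, `browser` and `#`
#' lines are skipped) into an interval tibble. Column 5 is kept as `score`
#' (used for CAGE TSS-peak read counts) and column 6 as `strand`. Malformed
#' lines are rejected with the offending line number; records with
#' `start >= end` are errors, not silently repaired.
#'
#' @param path File path.
#' @return An interval tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    abort(sprintf("%s line %d: expected >= 3 tab-separated fields, got %d",
                  path, lineno[i], nf[i]))
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("%s line %d: non-integer start/end", path, lineno[i]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid interval [%d, %d)", path,
                  lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  score_chr <- get(5, NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA, score_chr)))
  strand <- get(6, ".")
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  genomic_intervals(get(1, NA_character_), start, end, strand = strand,
                    name = get(4, NA_character_), score = score)
}

#' @rdname read_bed
#' @param intervals Interval tibble to write.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else NA_character_
  score <- if ("score" %in% names(intervals)) intervals$score else NA_real_
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$chrom, intervals$start, intervals$end,
                   ifelse(is.na(name), ".", name),
                   ifelse(is.na(score), ".", format(score, trim = TRUE, scientific = FALSE)),
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a signal track
#'
#' Four-column bedGraph (`chrom start end value`); each record contributes
#' `value` at every base of `[start, end)`, and overlapping records sum.
#' Negative values are rejected.
#'
#' @param path File path.
#' @return A signal-track tibble (see [signal_track()]).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(signal_track())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    i <- which(nf != 4)[1]
    abort(sprintf("%s line %d: bedGraph needs exactly 4 fields, got %d",
                  path, lineno[i], nf[i]))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(start) || anyNA(end) || anyNA(value)) {
    i <- which(is.na(start) | is.na(end) | is.na(value))[1]
    abort(sprintf("%s line %d: non-numeric record", path, lineno[i]))
  }
  if (any(value < 0)) {
    i <- which(value < 0)[1]
    abort(sprintf("%s line %d: negative bedGraph value %g", path, lineno[i], value[i]))
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    abort(sprintf("%s line %d: invalid span [%d, %d)", path, lineno[i], start[i], end[i]))
  }
  span <- end - start
  signal_track(
    chrom = rep(m[, 1], span),
    pos = unlist(Map(function(s, e) s:(e - 1L), start, end)),
    count = rep(value, span)
  )
}

#' @rdname read_bedgraph
#' @param track Signal-track tibble to write; consecutive equal-valued
#'   positions are collapsed into spans.
#' @export
write_bedgraph <- function(track, path) {
  validate_track(track)
  x <- track |>
    filter(.data$count != 0) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$pos[-1] != x$pos[-nrow(x)] + 1L |
                 x$count[-1] != x$count[-nrow(x)])
  run <- cumsum(new_run)
  spans <- x |>
    mutate(run = run) |>
    group_by(run) |>
    summarise(chrom = first(.data$chrom), start = min(.data$pos),
              end = max(.data$pos) + 1L, value = first(.data$count),
              .groups = "drop")
  writeLines(sprintf("%s\t%d\t%d\t%s", spans$chrom, spans$start, spans$end,
                     format(spans$value, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings. Names are truncated at the first
#' whitespace, sequences upper-cased; duplicated names are an error.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("%s: duplicated sequence name '%s'", path,
                  names(seqs)[duplicated(names(seqs))][1]))
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

label_vocabulary <- c("active", "nonactive", "unlabeled")

#' Read and write per-TL feature tables
#'
#' A feature table is a tibble with one row per TL id, a `label` column over
#' `active` / `nonactive` / `unlabeled`, an optional logical `hyperconserved`
#' column, and numeric or logical feature columns. Empty cells are missing
#' (`NA`) — missingness is meaningful (e.g. TLs without CAGE data) and is
#' never silently zero-filled.
#'
#' @param path TSV (or CSV, by extension) file with a header.
#' @param column_map Optional named character vector renaming file columns to
#'   canonical names, e.g. `c(label = "activity_class")` (supports
#'   supplementary tables whose schema differs).
#' @return A tibble.
#' @export
read_feature_table <- function(path, column_map = NULL) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      if (column_map[[canonical]] %in% names(x)) {
        names(x)[names(x) == column_map[[canonical]]] <- canonical
      }
    }
  }
  if (!"label" %in% names(x)) abort(sprintf("%s: no 'label' column", path))
  bad <- setdiff(unique(x$label[!is.na(x$label)]), label_vocabulary)
  if (length(bad) > 0) {
    abort(sprintf("%s: label value(s) outside {active, nonactive, unlabeled}: %s",
                  path, paste(bad, collapse = ", ")))
  }
  if ("hyperconserved" %in% names(x)) x$hyperconserved <- as.logical(x$hyperconserved)
  as_tibble(x)
}

#' @rdname read_feature_table
#' @param table Feature-table tibble to write.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(table, path, na = "")
  invisible(path)
}

#' Sum a list of signal tracks position-wise
#'
#' Mirrors aggregating many coverage tracks (bedGraph union semantics): the
#' result's value at each base is the sum over all inputs, so total mass is
#' additive.
#'
#' @param tracks List of signal-track tibbles.
#' @return One signal-track tibble.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(is.list(tracks))
  if (length(tracks) == 0) return(signal_track())
  lapply(tracks, validate_track)
  bind_rows(tracks) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop")
}
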