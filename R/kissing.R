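# Nearest-neighbor stacking free energies (kcal/mol, 37 C), Turner-2004-style.
# Key "XY/ZW": top strand 5'-XY-3', bottom strand 3'-ZW-5', X pairs Z and Y
# pairs W. Watson-Crick magnitudes follow the standard table; G.U wobble
# terms are approximate. Because this scanner scores a register, not an
# oriented helix, the shipped table is orientation-averaged: each stack is
# assigned the mean over its symmetry orbit (reading the stack from the
# other strand, WZ/YX, and traversing the run in the opposite direction,
# YX/WZ), so the score of a duplex does not depend on which loop is called
# A or on the scan direction. It is a stability score, not a duplex free
# energy.
nn_stack_primary <- c(
  # Watson-Crick / Watson-Crick
  "AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
  "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
  "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26, "GC/CG" = -3.42,
  # stacks with one or two G.U wobble pairs (approximate)
  "GA/UU" = -1.27, "GU/UA" = -1.36, "GC/UG" = -2.51, "GG/UC" = -2.11,
  "GG/UU" = -0.50, "GU/UG" = 1.29, "UG/GU" = -0.50, "UA/GU" = -1.00,
  "UU/GA" = -0.55, "UC/GG" = -1.53, "UG/GC" = -1.41
)

build_stack_table <- function() {
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  keys <- c(outer(pairs, pairs, function(p, q) {
    paste0(substr(p, 1, 1), substr(q, 1, 1), "/", substr(p, 2, 2), substr(q, 2, 2))
  }))
  strand_swap <- function(k) {
    a <- strsplit(substr(k, 1, 2), "")[[1]]
    b <- strsplit(substr(k, 4, 5), "")[[1]]
    paste0(b[2], b[1], "/", a[2], a[1])
  }
  order_rev <- function(k) {
    a <- strsplit(substr(k, 1, 2), "")[[1]]
    b <- strsplit(substr(k, 4, 5), "")[[1]]
    paste0(a[2], a[1], "/", b[2], b[1])
  }
  tab <- setNames(numeric(length(keys)), keys)
  for (k in keys) {
    orbit <- unique(c(k, strand_swap(k), order_rev(k), strand_swap(order_rev(k))))
    vals <- nn_stack_primary[orbit[orbit %in% names(nn_stack_primary)]]
    if (length(vals) == 0) {
      abort(sprintf("stack table: no primary value for orbit of %s", k))
    }
    tab[k] <- mean(vals)
  }
  tab
}
nn_stack_table <- build_stack_table()

pair_type <- function(a, b, allow_wobble = TRUE) {
  key <- paste0(a, b)
  wc <- c(AU = "AU", UA = "AU", GC = "GC", CG = "GC")
  if (key %in% names(wc)) return(unname(wc[key]))
  if (allow_wobble && key %in% c("GU", "UG")) return("GU")
  NA_character_
}

check_rna <- function(x, what) {
  s <- toupper(gsub("T", "U", toupper(x)))
  if (!grepl("^[ACGU]+$", s)) abort(sprintf("%s must be an RNA sequence over A,C,G,U", what))
  if (nchar(s) < 3) abort(sprintf("%s must be at least 3 nt", what))
  strsplit(s, "")[[1]]
}

#' Best loop-loop (kissing) hybridization register
#'
#' Scans all alignment offsets of two hairpin loop sequences (loop B read
#' antiparallel) and returns the contiguous complementary run — Watson-Crick
#' pairs plus G.U wobble when enabled — with the most base pairs. Ties break
#' toward the lower (more negative) nearest-neighbor stack energy, then the
#' smaller offset. This is a pure sequence-complementarity scan: loop
#' topology constraints and full secondary-structure thermodynamics are out
#' of scope.
#'
#' @param loopA,loopB RNA sequences (length >= 3; T is read as U).
#' @param allow_wobble Allow G.U pairs (default TRUE).
#' @return An object of class `kissing_duplex`: `offset`, a `pairs` tibble
#'   (1-based positions `pos_a` in loop A 5'->3' and `pos_b` in loop B
#'   5'->3', plus pair type), counts `n_pairs`, `n_gc`, `n_au`, `n_gu`, and
#'   `energy` (kcal/mol, see [stack_energy()]). Zero pairs is a valid
#'   result, not an error.
#' @examples
#' best_kissing_register("GGGGGGGGG", "CCCCCCCCC")
#' @export
best_kissing_register <- function(loopA, loopB, allow_wobble = TRUE) {
  a <- check_rna(loopA, "loopA")
  b <- check_rna(loopB, "loopB")
  nA <- length(a); nB <- length(b)
  rb <- rev(b) # antiparallel: align A 5'->3' against B 3'->5'
  best <- NULL
  for (off in -(nB - 1):(nA - 1)) {
    i <- max(1, 1 + off):min(nA, nB + off)
    j <- i - off
    ok <- mapply(function(x, y) !is.na(pair_type(x, y, allow_wobble)),
                 a[i], rb[j])
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run_i <- i[starts[k]:ends[k]]
      run_j <- run_i - off
      cand <- make_kissing_duplex(a, rb, run_i, run_j, off, nB, allow_wobble)
      if (is.null(best) ||
          cand$n_pairs > best$n_pairs ||
          (cand$n_pairs == best$n_pairs && cand$energy < best$energy - 1e-12) ||
          (cand$n_pairs == best$n_pairs && abs(cand$energy - best$energy) <= 1e-12 &&
             cand$offset < best$offset)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    best <- structure(list(offset = 0L, pairs = tibble(
      pos_a = integer(), pos_b = integer(), base_a = character(),
      base_b = character(), type = character()),
      n_pairs = 0L, n_gc = 0L, n_au = 0L, n_gu = 0L, energy = 0,
      allow_wobble = allow_wobble), class = "kissing_duplex")
  }
  best
}

make_kissing_duplex <- function(a, rb, run_i, run_j, off, nB, allow_wobble) {
  types <- mapply(pair_type, a[run_i], rb[run_j],
                  MoreArgs = list(allow_wobble = allow_wobble))
  d <- structure(list(
    offset = as.integer(off),
    pairs = tibble(pos_a = as.integer(run_i),
                   pos_b = as.integer(nB + 1 - run_j),
                   base_a = a[run_i], base_b = rb[run_j],
                   type = unname(types)),
    n_pairs = length(run_i),
    n_gc = sum(types == "GC"), n_au = sum(types == "AU"),
    n_gu = sum(types == "GU"),
    energy = 0, allow_wobble = allow_wobble
  ), class = "kissing_duplex")
  d$energy <- stack_energy(d)
  d
}

#' Nearest-neighbor stack energy of a kissing duplex
#'
#' Sums the embedded nearest-neighbor stacking parameters (see the
#' documented constant `nn_stack_table` in the package source) over the
#' adjacent pair steps of the duplex's contiguous run. Fewer than two pairs
#' contribute nothing. This is a simplified stability score, not a full
#' duplex free energy (no initiation, dangles or loop terms).
#'
#' @param duplex A `kissing_duplex` from [best_kissing_register()].
#' @return Energy in kcal/mol (0 for 0 or 1 pairs; more negative = more
#'   stable).
#' @export
stack_energy <- function(duplex) {
  stopifnot(inherits(duplex, "kissing_duplex"))
  p <- duplex$pairs
  if (nrow(p) < 2) return(0)
  e <- 0
  for (k in seq_len(nrow(p) - 1)) {
    key <- paste0(p$base_a[k], p$base_a[k + 1], "/", p$base_b[k], p$base_b[k + 1])
    if (!key %in% names(nn_stack_table)) {
      abort(sprintf("stack_energy: no parameter for stack %s", key))
    }
    e <- e + nn_stack_table[[key]]
  }
  e
}

#' @export
print.kissing_duplex <- function(x, ...) {
  cat(sprintf("Kissing duplex: %d pairs (%d G-C, %d A-U, %d G-U), offset %d, %.2f kcal/mol\n",
              x$n_pairs, x$n_gc, x$n_au, x$n_gu, x$offset, x$energy))
  invisible(x)
}

#' @export
tidy.kissing_duplex <- function(x, ...) x$pairs

#' @export
glance.kissing_duplex <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_gc = x$n_gc, n_au = x$n_au, n_gu = x$n_gu,
         offset = x$offset, energy = x$energy)
}
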