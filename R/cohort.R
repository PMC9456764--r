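#' Parameters for the synthetic TL cohort generator
#'
#' The generator emulates the statistical structure the audit assumes: a
#' cohort of transcript leaders in which a planted internal promoter
#' (localized internal CAGE mass, locally elevated GC, an E-box) and/or a
#' planted 3' splice site raise the probability that the TL scores "active"
#' in a bicistronic reporter, via a logistic label model
#' `logit P(active) = b0 + beta_p * promoter + beta_s * splice + beta_g * gc_z`
#' with `b0` calibrated so the cohort prevalence matches `target_prevalence`
#' (0.40, the share of active TLs among the 223 assayed hyperconserved TLs).
#'
#' @param n_tl Number of TLs (each on its own contig).
#' @param length_meanlog,length_sdlog Log-normal TL length distribution
#'   (median ~400 nt); lengths are clipped to at least 120 nt.
#' @param base_gc Background GC fraction of the i.i.d. sequence (0.45).
#' @param pi_promoter Probability a TL carries an internal promoter.
#' @param promoter_gc_boost Added GC fraction in the ~60-nt promoter window.
#' @param p_ebox Probability a planted promoter carries an E-box
#'   (`GACACGTGAC` inserted ~45 nt upstream of the internal TSS).
#' @param cage_weight Fraction of a planted TL's CAGE mass at the internal
#'   TSS (0.7); the rest maps to the annotated 5' end.
#' @param cage_concentration Beta-concentration of the per-TL noise around
#'   `cage_weight`.
#' @param pi_splice Probability of a planted 3' splice site.
#' @param beta Planted log-odds for (internal promoter, splice site,
#'   standardized GC).
#' @param target_prevalence Cohort fraction of active labels targeted when
#'   calibrating the intercept.
#' @param cage_mean,cage_size Negative-binomial CAGE reads per TL
#'   (mean 100).
#' @param rnaseq_depth Mean per-base RNA-seq coverage; per-TL track mass is
#'   exactly `rnaseq_depth * length`.
#' @param frac_hyperconserved Probability a TL is flagged hyperconserved.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the parameters.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_tl = 400, length_meanlog = log(400),
                          length_sdlog = 0.35, base_gc = 0.45,
                          pi_promoter = 0.45, promoter_gc_boost = 0.15,
                          p_ebox = 0.8, cage_weight = 0.7,
                          cage_concentration = 100, pi_splice = 0.25,
                          beta = c(internal_promoter = 1.5, splice3 = 1.2,
                                   gc_z = 0.5),
                          target_prevalence = 0.40, cage_mean = 100,
                          cage_size = 5, rnaseq_depth = 5,
                          frac_hyperconserved = 1, seed = 1L) {
  p <- list(n_tl = n_tl, length_meanlog = length_meanlog,
            length_sdlog = length_sdlog, base_gc = base_gc,
            pi_promoter = pi_promoter, promoter_gc_boost = promoter_gc_boost,
            p_ebox = p_ebox, cage_weight = cage_weight,
            cage_concentration = cage_concentration, pi_splice = pi_splice,
            beta = beta, target_prevalence = target_prevalence,
            cage_mean = cage_mean, cage_size = cage_size,
            rnaseq_depth = rnaseq_depth,
            frac_hyperconserved = frac_hyperconserved, seed = as.integer(seed))
  probs <- c(p$pi_promoter, p$p_ebox, p$pi_splice, p$target_prevalence,
             p$frac_hyperconserved, p$cage_weight)
  if (any(probs < 0 | probs > 1)) abort("cohort_params: probabilities must be in [0, 1]")
  if (n_tl < 2) abort("cohort_params: n_tl must be >= 2")
  if (p$base_gc + p$promoter_gc_boost > 1) abort("cohort_params: GC boost exceeds 1")
  structure(p, class = "cohort_params")
}

random_dna <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# Destroy chance E-box core matches outside the allowed footprints by
# mutating one base, so planted counts are exact by construction.
scrub_motif <- function(chars, allowed = integer(0)) {
  repeat {
    s <- paste(chars, collapse = "")
    hits <- Biostrings::start(Biostrings::matchPattern(ebox_core,
                                                       Biostrings::DNAString(s)))
    hits <- hits[!hits %in% allowed]
    if (length(hits) == 0) return(chars)
    chars[hits[1] + 3L] <- "A" # CACGTG -> CACATG
  }
}

#' Generate a synthetic labeled TL cohort with planted features
#'
#' Draws TL lengths, i.i.d. sequences at the background GC, and plants per
#' TL (with the configured probabilities) an internal promoter — a
#' GC-boosted window around an internal TSS in the middle 60% of the TL,
#' usually carrying one inserted `GACACGTGAC` E-box — and/or one 3' splice
#' site. Chance E-box core matches elsewhere are scrubbed, so planted motif
#' counts are exact ground truth. CAGE reads (negative binomial per TL) are
#' split between the annotated 5' peak and the internal TSS peak with a
#' beta-noised weight for planted TLs, and all map to the 5' peak
#' otherwise. RNA-seq coverage is a mixture of a uniform full-length
#' component and an internal-start component covering only bases 3' of the
#' internal TSS, with the internal weight tied to the CAGE weight. Labels
#' are drawn from the logistic model described in [cohort_params()]. Each TL
#' occupies `[0, L)` of its own contig with a random strand; all evidence
#' layers are emitted in genomic coordinates.
#'
#' @param params A [cohort_params()].
#' @return A list of class `tl_cohort`: `tls` (TL tibble with sequences and
#'   labels), `promoters`, `splice3`, `cage_peaks`, `rnaseq`
#'   (signal track), and `truth` (planted ground truth per TL).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_tl
  L <- pmax(120L, as.integer(round(rlnorm(n, params$length_meanlog,
                                          params$length_sdlog))))
  tl_id <- sprintf("tl%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  planted_p <- runif(n) < params$pi_promoter
  planted_s <- runif(n) < params$pi_splice
  has_ebox <- planted_p & (runif(n) < params$p_ebox)
  # internal TSS offset from the TL 5' end, uniform over the middle 60%
  d5 <- ifelse(planted_p,
               floor(runif(n, 0.2 * L, 0.8 * L)), NA_real_)
  splice_off <- ifelse(planted_s, pmax(1, floor(runif(n, 0.1 * L, 0.9 * L))),
                       NA_real_)

  to_genomic <- function(i, off) {
    if (strand[i] == "-") L[i] - 1L - as.integer(off) else as.integer(off)
  }

  seqs <- character(n)
  ebox_off <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    chars <- random_dna(L[i], params$base_gc)
    if (planted_p[i]) {
      w0 <- max(0L, as.integer(d5[i]) - 50L)
      w1 <- min(L[i], as.integer(d5[i]) + 10L)
      chars[(w0 + 1):w1] <- random_dna(w1 - w0,
                                       params$base_gc + params$promoter_gc_boost)
    }
    allowed <- integer(0)
    if (has_ebox[i]) {
      off <- max(0L, as.integer(d5[i]) - 45L)
      chars[(off + 1):(off + 10)] <- strsplit(ebox_extended, "")[[1]]
      ebox_off[i] <- off
      allowed <- off + 3L # 1-based core start within the planted motif
    }
    chars <- scrub_motif(chars, allowed)
    seqs[i] <- paste(chars, collapse = "")
  }

  # promoter annotation intervals (genomic coords) for planted promoters
  promoters <- list_rbind(lapply(which(planted_p), function(i) {
    off0 <- max(0L, as.integer(d5[i]) - 50L)
    off1 <- min(L[i], as.integer(d5[i]) + 10L)
    g <- sort(c(to_genomic(i, off0), to_genomic(i, off1 - 1L)))
    tibble(chrom = tl_id[i], start = g[1], end = g[2] + 1L,
           strand = strand[i], name = paste0(tl_id[i], "_prom"),
           score = NA_real_)
  }))
  if (is.null(promoters) || nrow(promoters) == 0) {
    promoters <- genomic_intervals(character(), integer(), integer())
  }

  splice3 <- list_rbind(lapply(which(planted_s), function(i) {
    g <- to_genomic(i, splice_off[i])
    tibble(chrom = tl_id[i], start = g, end = g + 1L, strand = strand[i],
           name = paste0(tl_id[i], "_3ss"), score = NA_real_)
  }))
  if (is.null(splice3) || nrow(splice3) == 0) {
    splice3 <- genomic_intervals(character(), integer(), integer())
  }

  cage_total <- rnbinom(n, mu = params$cage_mean, size = params$cage_size)
  internal_reads <- integer(n)
  for (i in seq_len(n)) {
    if (planted_p[i] && cage_total[i] > 0) {
      w <- rbeta(1, params$cage_concentration * params$cage_weight,
                 params$cage_concentration * (1 - params$cage_weight))
      internal_reads[i] <- rbinom(1, cage_total[i], w)
    }
  }
  peak_row <- function(i, summit_off, reads, tag) {
    summit <- to_genomic(i, summit_off)
    tibble(chrom = tl_id[i], start = max(0L, summit - 5L),
           end = min(L[i], summit + 6L), strand = strand[i],
           name = paste0(tl_id[i], tag), score = NA_real_,
           summit = summit, read_count = as.numeric(reads))
  }
  cage_peaks <- list_rbind(lapply(seq_len(n), function(i) {
    rows <- list()
    r5 <- cage_total[i] - internal_reads[i]
    if (r5 > 0) rows <- c(rows, list(peak_row(i, 0L, r5, "_tss5")))
    if (internal_reads[i] > 0) {
      rows <- c(rows, list(peak_row(i, as.integer(d5[i]), internal_reads[i],
                                    "_tssint")))
    }
    if (length(rows) == 0) NULL else list_rbind(rows)
  }))

  rnaseq <- list_rbind(lapply(seq_len(n), function(i) {
    M <- params$rnaseq_depth * L[i]
    w <- if (planted_p[i]) params$cage_weight else 0
    cov <- rep((1 - w) * M / L[i], L[i])
    if (w > 0) {
      int_len <- L[i] - as.integer(d5[i])
      cov[(as.integer(d5[i]) + 1):L[i]] <- cov[(as.integer(d5[i]) + 1):L[i]] +
        w * M / int_len
    }
    offs <- 0:(L[i] - 1L)
    tibble(chrom = tl_id[i],
           pos = vapply(offs, function(o) to_genomic(i, o), integer(1)),
           count = cov)
  }))

  gc_realized <- gc_content(seqs)
  gc_z <- if (sd(gc_realized) > 0) (gc_realized - mean(gc_realized)) / sd(gc_realized) else rep(0, n)
  lin <- params$beta[["internal_promoter"]] * planted_p +
    params$beta[["splice3"]] * planted_s +
    params$beta[["gc_z"]] * gc_z
  b0 <- if (diff(range(lin)) == 0) {
    stats::qlogis(params$target_prevalence) - lin[1]
  } else {
    uniroot(function(b) mean(plogis(b + lin)) - params$target_prevalence,
            c(-30, 30))$root
  }
  true_prob <- plogis(b0 + lin)
  label <- ifelse(rbinom(n, 1, true_prob) == 1, "active", "nonactive")
  hyperconserved <- runif(n) < params$frac_hyperconserved

  tls <- tibble(tl_id = tl_id, gene = tl_id, chrom = tl_id, start = 0L,
                end = L, strand = strand, sequence = seqs, label = label,
                hyperconserved = hyperconserved)
  truth <- tibble(tl_id = tl_id,
                  has_internal_promoter = planted_p,
                  promoter_tss_offset = as.integer(d5),
                  n_ebox_planted = as.integer(has_ebox),
                  has_splice3_planted = planted_s,
                  splice_offset = as.integer(splice_off),
                  cage_total = cage_total,
                  cage_internal_reads = internal_reads,
                  intercept = b0,
                  true_prob = true_prob,
                  label = label)
  structure(list(tls = tls, promoters = promoters, splice3 = splice3,
                 cage_peaks = cage_peaks, rnaseq = rnaseq, truth = truth,
                 params = params),
            class = "tl_cohort")
}

#' @export
print.tl_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TL cohort: %d TLs (%d active), %d planted promoters, %d splice sites\n",
              nrow(x$tls), sum(x$tls$label == "active"),
              sum(x$truth$has_internal_promoter),
              sum(x$truth$has_splice3_planted)))
  invisible(x)
}

#' Write a synthetic cohort to disk in pipeline formats
#'
#' Emits exactly the files the real pipeline consumes: TL intervals (BED),
#' sequences (FASTA), promoter and 3'-splice-site annotations (BED), CAGE
#' TSS peaks (BED with read counts in the score column), aggregate RNA-seq
#' coverage (bedGraph), labels (TSV) and the planted truth (TSV).
#'
#' @param cohort A `tl_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_bed(cohort$tls |> mutate(name = .data$tl_id, score = NA_real_),
            fp("tls.bed"))
  write_fasta(setNames(cohort$tls$sequence, cohort$tls$tl_id), fp("tls.fasta"))
  write_bed(cohort$promoters, fp("promoters.bed"))
  write_bed(cohort$splice3, fp("splice3.bed"))
  if (!is.null(cohort$cage_peaks) && nrow(cohort$cage_peaks) > 0) {
    write_bed(cohort$cage_peaks |> mutate(score = .data$read_count),
              fp("cage_peaks.bed"))
  }
  write_bedgraph(cohort$rnaseq, fp("rnaseq.bedGraph"))
  readr::write_tsv(cohort$tls |> select("tl_id", "label", "hyperconserved"),
                   fp("labels.tsv"))
  readr::write_tsv(cohort$truth, fp("truth.tsv"))
  invisible(dir)
}

#' Audit extracted features against planted ground truth
#'
#' The end-to-end recovery check: run a generated cohort through
#' [build_feature_table()] and compare with the generator's truth table.
#' E-box counts and splice-site flags are planted exactly and must agree
#' exactly; CAGE-based internal-promoter calls are stochastic (multinomial
#' read sampling), so their agreement is reported as rates. A TL counts as
#' an internal-promoter detection when any internal CAGE reads were
#' extracted (threshold 0: non-planted TLs receive no internal CAGE mass).
#'
#' @param features Feature table from [build_feature_table()].
#' @param truth Truth tibble from a `tl_cohort`.
#' @return One-row tibble of agreement metrics.
#' @export
truth_audit <- function(features, truth) {
  if (!setequal(features$tl_id, truth$tl_id)) {
    abort("truth_audit: feature table and truth disagree on TL ids")
  }
  x <- inner_join(features, truth, by = "tl_id",
                  suffix = c("", ".truth"))
  planted <- x$has_internal_promoter & !is.na(x$strongest_peak_internal)
  cage_present <- !is.na(x$cage_internal_reads)
  tibble(
    n_tl = nrow(x),
    ebox_agreement = mean(x$ebox_core_count == x$n_ebox_planted),
    splice_agreement = mean(x$has_splice3 == x$has_splice3_planted),
    strongest_internal_rate =
      if (any(planted)) mean(x$strongest_peak_internal[planted]) else NA_real_,
    internal_reads_sensitivity =
      if (any(planted)) mean(x$cage_internal_reads[planted] > 0) else NA_real_,
    internal_reads_specificity =
      if (any(!x$has_internal_promoter & cage_present)) {
        mean(x$cage_internal_reads[!x$has_internal_promoter & cage_present] == 0)
      } else NA_real_
  )
}
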