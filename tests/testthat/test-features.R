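test_that("gc_content excludes N and rejects empty input", {
  expect_equal(gc_content(c("ACGT", "GGGG", "GCAN")), c(0.5, 1, 2 / 3))
  expect_error(gc_content("NNN"), "all-N")
})

test_that("E-box scanning counts both strands without double counting palindromes", {
  expect_equal(count_motif("GACACGTGAC", "CACGTG"), 1L)
  expect_equal(count_motif("GACACTATAC", "CACGTG"), 0L)
  expect_equal(count_motif("CACGTGCACGTG", "CACGTG"), 2L)
  expect_equal(count_motif("GACACGTGAC", "GACACGTGAC"), 1L)
  # non-palindromic motif: reverse-complement occurrences count too
  expect_equal(count_motif("TTGACAAA", "TGTCAA"), 1L)
})

test_that("motif counting agrees with a sliding-window dual-strand oracle", {
  set.seed(21)
  for (i in 1:150) {
    s <- random_dna_string(sample(20:60, 1), letters = c("A", "C", "G", "T"))
    motif <- random_dna_string(sample(3:5, 1))
    expect_equal(count_motif(s, motif), motif_window_count(s, motif),
                 info = paste(s, motif))
  }
})

test_that("promoter features count overlap and containment correctly", {
  tl <- genomic_intervals("chr1", 0, 100)
  proms <- genomic_intervals("chr1", c(10, 90), c(20, 110))
  pf <- promoter_features(tl, proms)
  expect_equal(pf$promoter_any_count, 2L)
  expect_equal(pf$promoter_full_count, 1L)
  expect_equal(pf$promoter_coverage_fraction, 0.2)
  empty <- promoter_features(tl, NULL)
  expect_equal(unlist(empty), c(promoter_any_count = 0, promoter_full_count = 0,
                                promoter_coverage_fraction = 0))
  # full_count <= any_count over random sets
  set.seed(22)
  for (i in 1:100) {
    tlr <- random_interval(chroms = "chr1")
    pr <- do.call(rbind, lapply(1:4, function(j) random_interval(chroms = "chr1")))
    pf <- promoter_features(tlr, pr)
    expect_lte(pf$promoter_full_count, pf$promoter_any_count)
  }
})

test_that("3' splice-site counting excludes the TL 5'-most base", {
  tl <- genomic_intervals("chr1", 0, 100, "+")
  expect_equal(splice3_features(tl, genomic_intervals("chr1", 50, 51))$splice3_count, 1L)
  expect_false(splice3_features(tl, genomic_intervals("chr1", 0, 1))$has_splice3)
  # on the minus strand the 5'-most base is end-1
  tlm <- genomic_intervals("chr1", 0, 100, "-")
  expect_false(splice3_features(tlm, genomic_intervals("chr1", 99, 100))$has_splice3)
  expect_true(splice3_features(tlm, genomic_intervals("chr1", 0, 1))$has_splice3)
  # brute-force membership oracle
  set.seed(23)
  for (i in 1:100) {
    pos <- sample.int(120, 1) - 1L
    res <- splice3_features(tl, genomic_intervals("chr1", pos, pos + 1))
    expect_equal(res$splice3_count, as.integer(pos >= 1 && pos < 100))
  }
})

test_that("CAGE features classify peaks by summit distance to the strand-aware 5' end", {
  tl <- genomic_intervals("chr1", 0, 100, "+")
  peaks <- tibble::tibble(chrom = "chr1", start = c(0, 55), end = c(5, 65),
                          strand = "+", summit = c(2, 60), read_count = c(30, 70))
  cf <- cage_features(tl, peaks, window_nt = 10)
  expect_equal(cf$cage_5prime_fraction, 0.3)
  expect_equal(cf$cage_internal_reads, 70)
  expect_true(cf$strongest_peak_internal)

  one <- cage_features(tl, peaks[1, ] |> dplyr::mutate(summit = 5, read_count = 100))
  expect_equal(one$cage_5prime_fraction, 1)
  expect_equal(one$cage_internal_reads, 0)
  expect_false(one$strongest_peak_internal)

  # minus strand: 5' end is position 99
  tlm <- genomic_intervals("chr1", 0, 100, "-")
  pk <- tibble::tibble(chrom = "chr1", start = 92, end = 100, strand = "-",
                       summit = 97, read_count = 10)
  expect_equal(cage_features(tlm, pk)$cage_5prime_fraction, 1)

  # no peaks -> all three missing
  none <- cage_features(tl, peaks |> dplyr::mutate(chrom = "chr9"))
  expect_true(is.na(none$cage_5prime_fraction))
  expect_true(is.na(none$strongest_peak_internal))
  expect_error(cage_features(tl, peaks, window_nt = -1), "window")
})

test_that("cage fraction and internal reads partition the total", {
  set.seed(24)
  tl <- genomic_intervals("chr1", 0, 200, "+")
  for (i in 1:50) {
    k <- sample(1:4, 1)
    summits <- sample.int(200, k) - 1L
    peaks <- tibble::tibble(chrom = "chr1", start = pmax(0L, summits - 2L),
                            end = summits + 3L, strand = "+", summit = summits,
                            read_count = sample(1:100, k))
    cf <- cage_features(tl, peaks)
    expect_equal(cf$cage_5prime_fraction + cf$cage_internal_reads / sum(peaks$read_count), 1)
  }
})

test_that("RNA-seq bias splits halves strand-awarely and pseudocounts", {
  tl <- genomic_intervals("chr1", 0, 100, "+")
  uniform <- signal_track("chr1", 0:99, rep(1, 100))
  expect_equal(rnaseq_bias(tl, uniform), 1)
  skewed <- signal_track("chr1", 50:99, rep(10, 50))
  expect_equal(rnaseq_bias(tl, skewed), 1 / 501)
  tlm <- genomic_intervals("chr1", 0, 100, "-")
  expect_equal(rnaseq_bias(tlm, skewed), 501)
  expect_error(rnaseq_bias(genomic_intervals("chr1", 0, 1), uniform), "shorter")
  # odd length: 5' half gets the extra base
  tl5 <- genomic_intervals("chr1", 0, 5, "+")
  tr <- signal_track("chr1", 0:4, c(1, 1, 1, 0, 0))
  expect_equal(rnaseq_bias(tl5, tr, pseudocount = 1), 4 / 1)
})

test_that("CDS overlap fraction uses union coverage", {
  tl <- genomic_intervals("chr1", 0, 100)
  expect_equal(cds_overlap_fraction(tl, genomic_intervals("chr1", 50, 150)), 0.5)
  expect_equal(cds_overlap_fraction(tl, genomic_intervals("chr1", c(10, 40), c(60, 90))), 0.8)
  expect_equal(cds_overlap_fraction(tl, NULL), 0)
})

test_that("build_feature_table is deterministic, masks missing CAGE, rejects duplicate ids", {
  co <- tiny_cohort(n = 30, seed = 5)
  ft1 <- features_of(co)
  ft2 <- features_of(co)
  expect_identical(ft1, ft2)
  expect_true(all(ft1$promoter_full_count <= ft1$promoter_any_count))

  # empty annotations: counts zero, fractions defined, CAGE missing
  bare <- build_feature_table(co$tls)
  expect_true(all(bare$promoter_any_count == 0))
  expect_true(all(is.na(bare$cage_5prime_fraction)))
  expect_true(all(bare$rnaseq_bias == 1)) # zero coverage, pseudocounted

  dup <- co$tls[c(1, 1), ]
  expect_error(build_feature_table(dup), "duplicate")
})

test_that("planted internal promoters shift CAGE features in the expected direction", {
  co <- tiny_cohort(n = 200, seed = 6, pi_promoter = 0.5)
  ft <- features_of(co) |>
    dplyr::inner_join(co$truth |> dplyr::select("tl_id", "has_internal_promoter"),
                      by = "tl_id")
  grp <- split(ft, ft$has_internal_promoter)
  w <- wilcoxon_rank_sum(grp[["TRUE"]]$cage_internal_reads,
                         grp[["FALSE"]]$cage_internal_reads)
  expect_lt(w$p_value, 0.01)
  expect_gt(median(grp[["TRUE"]]$cage_internal_reads, na.rm = TRUE),
            median(grp[["FALSE"]]$cage_internal_reads, na.rm = TRUE))
  w2 <- wilcoxon_rank_sum(grp[["TRUE"]]$cage_5prime_fraction,
                          grp[["FALSE"]]$cage_5prime_fraction)
  expect_lt(w2$p_value, 0.01)
})
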