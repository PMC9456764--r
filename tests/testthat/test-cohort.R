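test_that("cohort generation is a deterministic function of its parameters", {
  co1 <- generate_cohort(cohort_params(n_tl = 40, seed = 17))
  co2 <- generate_cohort(cohort_params(n_tl = 40, seed = 17))
  expect_identical(co1$tls, co2$tls)
  expect_identical(co1$cage_peaks, co2$cage_peaks)
  expect_identical(co1$rnaseq, co2$rnaseq)
  co3 <- generate_cohort(cohort_params(n_tl = 40, seed = 18))
  expect_false(identical(co1$tls$sequence, co3$tls$sequence))
})

test_that("written cohort files are byte-identical across same-seed runs and round-trip", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cohort_params(n_tl = 25, seed = 3)), d1)
  write_cohort(generate_cohort(cohort_params(n_tl = 25, seed = 3)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  co <- generate_cohort(cohort_params(n_tl = 25, seed = 3))
  seqs <- read_fasta(file.path(d1, "tls.fasta"))
  expect_equal(unname(seqs[co$tls$tl_id]), co$tls$sequence)
  tr <- read_bedgraph(file.path(d1, "rnaseq.bedGraph"))
  expect_equal(track_mass(tr), track_mass(co$rnaseq), tolerance = 1e-6)
})

test_that("degenerate parameters give an unplanted cohort at the target prevalence", {
  p <- cohort_params(n_tl = 400, pi_promoter = 0, pi_splice = 0,
                     beta = c(internal_promoter = 0, splice3 = 0, gc_z = 0),
                     seed = 19)
  co <- generate_cohort(p)
  expect_equal(sum(co$truth$has_internal_promoter), 0)
  expect_equal(nrow(co$promoters), 0)
  ft <- features_of(co)
  expect_gte(mean(ft$cage_5prime_fraction, na.rm = TRUE), 0.9)
  prev <- mean(co$tls$label == "active")
  se <- sqrt(0.4 * 0.6 / 400)
  expect_lt(abs(prev - plogis(co$truth$intercept[1])), 3 * se)
})

test_that("planted effects reproduce the logistic label model", {
  co <- generate_cohort(cohort_params(n_tl = 400, seed = 20))
  tr <- co$truth
  p_with <- mean(tr$label[tr$has_internal_promoter] == "active")
  p_without <- mean(tr$label[!tr$has_internal_promoter] == "active")
  # labels are Bernoulli draws from the closed-form logistic probabilities
  implied <- mean(tr$true_prob[tr$has_internal_promoter]) -
    mean(tr$true_prob[!tr$has_internal_promoter])
  n1 <- sum(tr$has_internal_promoter); n0 <- sum(!tr$has_internal_promoter)
  se <- sqrt(0.25 / n1 + 0.25 / n0)
  expect_lt(abs((p_with - p_without) - implied), 3 * se)
  expect_gt(implied, 0.2) # the planted log-odds of 1.5 is a real effect
})

test_that("RNA-seq track mass matches the configured depth and evidence lies inside TLs", {
  p <- cohort_params(n_tl = 50, seed = 21)
  co <- generate_cohort(p)
  expect_equal(track_mass(co$rnaseq),
               p$rnaseq_depth * sum(co$tls$end - co$tls$start),
               tolerance = 1e-8)
  # planted elements are inside their TL
  for (layer in list(co$promoters, co$splice3, co$cage_peaks)) {
    if (nrow(layer) == 0) next
    tl <- co$tls[match(layer$chrom, co$tls$chrom), ]
    expect_true(all(layer$start >= tl$start & layer$end <= tl$end))
  }
})

test_that("planted E-box, splice and internal-promoter signals are recovered end to end", {
  co <- tiny_cohort(n = 150, seed = 22)
  ft <- features_of(co)
  audit <- truth_audit(ft, co$truth)
  expect_equal(audit$ebox_agreement, 1)
  expect_equal(audit$splice_agreement, 1)
  expect_gte(audit$strongest_internal_rate, 0.95)
  expect_equal(audit$internal_reads_specificity, 1)
  expect_error(truth_audit(ft[-1, ], co$truth), "ids")
})

test_that("infeasible parameters are rejected", {
  expect_error(cohort_params(pi_promoter = 1.2), "probabilities")
  expect_error(cohort_params(n_tl = 1), "n_tl")
  expect_error(cohort_params(base_gc = 0.8, promoter_gc_boost = 0.4), "boost")
})
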