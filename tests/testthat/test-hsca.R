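make_peaks <- function(acc1, tot1, acc2, tot2, hcn1 = 1, hcn2 = 1,
                       somatic = 0L, germ = 0L, imprinted = FALSE) {
  n <- length(acc1)
  data.frame(contig = "c", start = seq_len(n) * 1000,
             end = seq_len(n) * 1000 + 200,
             acc_hap1 = acc1, total_hap1 = rep_len(tot1, n),
             acc_hap2 = acc2, total_hap2 = rep_len(tot2, n),
             hcn_hap1 = rep_len(hcn1, n), hcn_hap2 = rep_len(hcn2, n),
             n_somatic_variants = rep_len(somatic, n),
             n_germline_hets = rep_len(germ, n),
             imprinted = rep_len(imprinted, n), stringsAsFactors = FALSE)
}

test_that("haplotype selectivity testing uses Fisher + BH", {
  pk <- make_peaks(acc1 = c(50, 90, 10), tot1 = 100,
                   acc2 = c(50, 10, 50), tot2 = 100)
  r <- test_haplotype_selectivity(pk)
  expect_equal(r$p[1], 1)
  expect_false(r$selective[1])
  expect_true(r$selective[2])
  expect_true(r$selective[3])
  # Fisher p agrees with the hypergeometric enumeration oracle
  expect_equal(r$p[2], fisher_p_oracle(90, 10, 10, 90), tolerance = 1e-9)

  # no-contrast peaks are excluded with a warning
  pk0 <- make_peaks(acc1 = c(0, 30), tot1 = c(0, 60),
                    acc2 = c(5, 30), tot2 = c(10, 60))
  expect_warning(r0 <- test_haplotype_selectivity(pk0), "contrast")
  expect_false(r0$tested[1])
  expect_true(is.na(r0$q[1]))
  # LOH loci (one haplotype absent) are excluded too
  pkl <- make_peaks(acc1 = 30, tot1 = 60, acc2 = 3, tot2 = 60, hcn1 = 0)
  expect_warning(rl <- test_haplotype_selectivity(pkl), "contrast")
  expect_false(rl$tested[1])
})

test_that("the selective set grows monotonically with the FDR threshold", {
  set.seed(19)
  n <- 60
  shift <- runif(n) < 0.4
  rate1 <- ifelse(shift, 0.15, 0.5)
  pk <- make_peaks(acc1 = rbinom(n, 80, rate1), tot1 = 80,
                   acc2 = rbinom(n, 80, 0.5), tot2 = 80)
  sel <- lapply(c(0.01, 0.05, 0.2), function(f) {
    which(test_haplotype_selectivity(pk, fdr = f)$selective)
  })
  expect_true(all(sel[[1]] %in% sel[[2]]))
  expect_true(all(sel[[2]] %in% sel[[3]]))
})

test_that("selective peaks partition by explanation priority", {
  pk <- make_peaks(acc1 = rep(95, 5), tot1 = 100, acc2 = rep(5, 5),
                   tot2 = 100)
  pk$n_somatic_variants <- c(1L, 1L, 0L, 0L, 0L)
  pk$n_germline_hets <- c(1L, 0L, 1L, 0L, 0L)
  pk$imprinted <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  r <- partition_selective(test_haplotype_selectivity(pk))
  expect_equal(as.numeric(r$counts),
               c(2, 1, 1, 1))  # variant > germline > imprinted > unexplained
  expect_equal(r$peaks$explanation[5], "unexplained")
  # non-selective peaks are excluded
  pk2 <- make_peaks(acc1 = 50, tot1 = 100, acc2 = 50, tot2 = 100)
  r2 <- partition_selective(test_haplotype_selectivity(pk2))
  expect_equal(nrow(r2$peaks), 0)
})

test_that("additive copy-number expectation matches observed dosage", {
  pk <- make_peaks(acc1 = 60, tot1 = 120, acc2 = 30, tot2 = 60,
                   hcn1 = 2, hcn2 = 1)
  r <- additive_expectation(pk)
  expect_equal(r$peaks$expected_hap1, 60)
  expect_equal(r$peaks$observed_ratio, r$peaks$expected_ratio)
  # an inverted peak is a non-additive outlier
  pk2 <- make_peaks(acc1 = 30, tot1 = 120, acc2 = 60, tot2 = 60,
                    hcn1 = 2, hcn2 = 1)
  r2 <- additive_expectation(pk2)
  expect_gt(abs(r2$peaks$observed_ratio - r2$peaks$expected_ratio), 0.3)
  expect_error(additive_expectation(make_peaks(1, 2, 1, 2, hcn1 = 0,
                                               hcn2 = 0)), "copy number")

  # simulated additive cohort: high observed/expected correlation,
  # approaching 1 as fiber counts grow
  segs <- make_segments(c("1", "2", "3", "2", "4"), width = 2e6)
  cfg <- sim_config(seed = 2)
  pks <- simulate_peaks(segs, cfg, n_peaks = 300, n_selective = 0)
  expect_gte(additive_expectation(pks)$correlation, 0.9)
  pks_big <- simulate_peaks(segs, cfg, n_peaks = 300, n_selective = 0,
                            fibers_per_copy = 2000)
  expect_gte(additive_expectation(pks_big)$correlation, 0.99)
})

test_that("boundary-distance curves expose positional enrichment", {
  segs <- make_segments(c("1", "2", "1", "3", "1"), width = 1e7)
  near <- make_peaks(acc1 = rep(1, 40), tot1 = 2, acc2 = 1, tot2 = 2)
  near$start <- rep(c(1e7, 2e7, 3e7, 4e7), 10) +
    runif(40, -2e6, 2e6)
  near$end <- near$start + 200
  set.seed(7)
  bg <- near
  bg$start <- runif(40, 0, 5e7); bg$end <- bg$start + 200
  curves <- boundary_distance_enrichment(near, bg, segs, n_boot = 200,
                                         seed = 5)
  expect_true(all(diff(curves$frac_unexplained) >= 0))  # cumulative
  expect_gt(curves$difference[curves$distance_mb == 2], 0)
  expect_equal(max(curves$frac_unexplained), 1)

  # peaks sitting on boundaries start the curve at 1
  on_b <- near[1:4, ]
  on_b$start <- c(1e7, 2e7, 3e7, 4e7) - 100; on_b$end <- on_b$start + 200
  c2 <- boundary_distance_enrichment(on_b, bg, segs, n_boot = 50, seed = 5)
  expect_equal(c2$frac_unexplained[1], 1)

  # difference is centred on zero when both sets share the distribution
  c3 <- boundary_distance_enrichment(bg, bg, segs, n_boot = 50, seed = 5)
  expect_true(all(c3$difference == 0))
  expect_error(boundary_distance_enrichment(near, bg,
                                            make_segments(character(0))),
               "no segments")
  expect_error(boundary_distance_enrichment(near, bg,
                                            make_segments(c("1", "1"))),
               "state changes")
})
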