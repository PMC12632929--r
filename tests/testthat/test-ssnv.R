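test_that("replicate intersection is keyed on contig, pos, ref, alt", {
  a <- make_calls(c(10, 20, 30), alt = c("T", "T", "A"))
  b <- make_calls(c(20, 30, 40), alt = c("T", "G", "T"))
  expect_equal(intersect_replicates(a, b)$pos, 20)  # same site, diff alt out
  expect_equal(nrow(intersect_replicates(a, make_calls(c(50, 60)))), 0)
  same <- intersect_replicates(a, a)
  expect_equal(same$pos, a$pos)
  expect_true(all(c("depth_tumor_rep_b", "alt_depth_tumor_rep_b") %in%
                    names(same)))
})

test_that("normal-evidence filter tolerates one alt read and no more", {
  calls <- make_calls(c(10, 20, 30), alt_depth_normal = c(0L, 1L, 2L))
  kept <- normal_evidence_filter(calls)
  expect_equal(kept$pos, c(10, 20))
  pile <- data.frame(contig = "sim1", pos = c(10, 20, 30),
                     alt_depth_normal = c(2L, 0L, 0L))
  expect_equal(normal_evidence_filter(calls, pile)$pos, c(20, 30))
})

test_that("calls in deleted segments are removed", {
  segs <- make_segments(c("DEL", "2"))
  calls <- make_calls(c(5e5, 1.5e6))
  calls$contig <- "c"
  expect_equal(remove_deleted_segments(calls, segs)$pos, 1.5e6)
  out <- make_calls(5e6); out$contig <- "c"
  expect_warning(kept <- remove_deleted_segments(out, segs), "outside")
  expect_equal(nrow(kept), 1)
})

test_that("cross-haplotype resolution follows the two-tier Fisher scheme", {
  pc <- data.frame(alt1 = c(30, 5), ref1 = c(0, 5),
                   alt2 = c(0, 5), ref2 = c(30, 5))
  r <- cross_haplotype_resolve(pc)
  expect_lt(r$p_tier1[1], 0.01)
  expect_equal(r$assigned_hap[1], 1L)
  expect_equal(r$p_tier1[2], 1)          # symmetric table
  expect_true(r$ambiguous[2])

  pc2 <- data.frame(alt1 = 5, ref1 = 5, alt2 = 5, ref2 = 5,
                    alt1_t2 = 40, ref1_t2 = 2, alt2_t2 = 3, ref2_t2 = 41)
  r2 <- cross_haplotype_resolve(pc2)
  expect_false(r2$ambiguous)
  expect_equal(r2$assigned_hap, 1L)
  expect_lt(r2$p_tier2, 0.01)

  r0 <- cross_haplotype_resolve(data.frame(alt1 = 0, ref1 = 0, alt2 = 0,
                                           ref2 = 0))
  expect_true(r0$ambiguous)
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  set.seed(8)
  for (i in 1:200) {
    n <- sample(4:100, 1)
    a <- sample(0:n, 1); r1 <- sample(0:(n - a), 1)
    b <- sample(0:(n - a - r1), 1); r2 <- n - a - r1 - b
    got <- cross_haplotype_resolve(
      data.frame(alt1 = a, ref1 = r1, alt2 = b, ref2 = r2))$p_tier1
    if (a + r1 + b + r2 == 0) next
    expect_equal(got, fisher_p_oracle(a, r1, b, r2), tolerance = 1e-9)
  }
})

test_that("density filter applies the VAF and depth rules independently", {
  # rule (a): >= 3 low-VAF calls in one window
  low <- make_calls(c(1100, 1400, 1700), alt_depth_tumor = c(30, 36, 42))
  expect_equal(nrow(density_filter(low)), 0)
  # neither rule fires: high VAF, healthy depth
  hi <- make_calls(c(1100, 1400, 1700), depth_tumor = c(58, 60, 64))
  expect_equal(nrow(density_filter(hi)), 3)
  # rule (b): median depth below 61.5 - 3 * sqrt(61.5) ~ 37.97
  shallow <- make_calls(c(1100, 1400, 1700), depth_tumor = 30L)
  expect_equal(nrow(density_filter(shallow)), 0)
  expect_equal(nrow(attr(density_filter(shallow), "removed")), 3)
  # threshold arithmetic is exact at the boundary
  at <- make_calls(c(1100, 1400, 1700), depth_tumor = 38L)
  expect_equal(nrow(density_filter(at)), 3)  # 38 > 37.97 retained
  # sparse calls never trigger
  sparse <- make_calls(c(1000, 5000, 9000), alt_depth_tumor = 30L,
                       depth_tumor = 60L)
  expect_equal(nrow(density_filter(sparse)), 3)
})

test_that("density filter removes planted artifact clusters, not clonal calls", {
  set.seed(31)
  true_pos <- seq(10000, by = 2000, length.out = 200)
  true_calls <- make_calls(true_pos, depth_tumor = rpois(200, 61.5) + 1L)
  art <- list()
  for (k in 1:20) {
    base <- 5e5 + k * 10000
    art[[k]] <- make_calls(base + c(0, 150, 300, 450),
                           depth_tumor = 60L,
                           alt_depth_tumor = as.integer(
                             round(60 * runif(4, 0.3, 0.6))))
  }
  all_calls <- rbind(true_calls, do.call(rbind, art))
  kept <- density_filter(all_calls)
  art_pos <- do.call(rbind, art)$pos
  expect_gte(mean(!art_pos %in% kept$pos), 0.95)
  expect_lt(mean(!true_pos %in% kept$pos), 0.01)
})

test_that("DNV calling merges fixed same-haplotype adjacent pairs only", {
  pair <- make_calls(c(100, 101), ref = c("C", "C"), alt = c("T", "T"))
  r <- call_dnvs(pair)
  expect_equal(nrow(r$dnvs), 1)
  expect_equal(r$dnvs$ref, "CC")
  expect_equal(r$dnvs$alt, "TT")
  expect_equal(nrow(r$snvs), 0)

  # different phase sets, not fixed: stays two SNVs
  het <- make_calls(c(100, 101), alt_depth_tumor = 30L,
                    phase_set = c(1L, 2L))
  r2 <- call_dnvs(het)
  expect_equal(nrow(r2$dnvs), 0)
  expect_equal(nrow(r2$snvs), 2)

  # same phase set on the same haplotype merges even at het VAF
  phased <- make_calls(c(100, 101), alt_depth_tumor = 30L,
                       phase_set = c(9L, 9L))
  expect_equal(nrow(call_dnvs(phased)$dnvs), 1)

  # odd cluster: flagged, no DNV
  odd <- make_calls(c(100, 101, 102))
  r3 <- call_dnvs(odd)
  expect_equal(nrow(r3$dnvs), 0)
  expect_equal(length(r3$flagged_clusters), 1)

  # different haplotypes never merge
  xh <- make_calls(c(100, 101), haplotype = c(1L, 2L))
  expect_equal(nrow(call_dnvs(xh)$dnvs), 0)
})

test_that("orthogonal validation fraction matches the planted dropout", {
  calls <- make_calls(seq_len(5000) * 10)
  set.seed(4)
  support <- rbinom(5000, 1, 0.998) * 5L
  orth <- data.frame(contig = "sim1", pos = calls$pos, alt_depth = support)
  expect_equal(validate_against(calls, orth), mean(support >= 1))
  expect_lt(abs(validate_against(calls, orth) - 0.998),
            3 * sqrt(0.998 * 0.002 / 5000))
  orth$alt_depth <- 0L
  expect_equal(validate_against(calls, orth), 0)
  orth$alt_depth <- 1L
  expect_equal(validate_against(calls, orth), 1)
})

test_that("hVAF definitions behave as documented", {
  calls <- make_calls(1:2, depth_tumor = 100L, alt_depth_tumor = 50L)
  calls$hap_depth <- c(50L, 100L)
  calls$alt_hap_depth <- c(50L, 50L)
  expect_equal(hvaf(calls), c(1, 0.5))
  expect_equal(hvaf(calls, "vaf_times_hcn", hcn = c(2, 1)), c(1, 0.5))
  expect_error(hvaf(calls, "vaf_times_hcn"))
})
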