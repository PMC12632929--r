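test_that("generate_genome keeps fraction bookkeeping and validates config", {
  cfg <- sim_config(seed = 1, genome_length_bp = 1e6,
                    class_fractions = c("HSat2" = 0.1),
                    class_rates = c("HSat2" = 0, "non-repeat" = 0))
  g <- generate_genome(cfg)
  ann <- g$annotations
  hs <- ann[ann$class == "HSat2", ]
  expect_equal(sum(hs$end - hs$start), 1e5)
  expect_equal(sum(ann$end - ann$start), 1e6)
  expect_equal(nchar(g$contigs[[1]]), 1e6)

  expect_error(sim_config(class_fractions = c("SINE" = 0.7, "LINE" = 0.5)),
               "configuration error")
  expect_error(sim_config(class_rates = c("non-repeat" = 1.5)),
               "configuration error")
  expect_error(sim_config(genome_length_bp = 5000), "10 kb")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, genome_length_bp = 5e4,
                    telomere_spec = default_telomere_spec(1))
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1$contigs, f1); write_fasta(g2$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_ssnvs(g1, cfg), simulate_ssnvs(g2, cfg))
  expect_identical(simulate_telomeres(cfg), simulate_telomeres(cfg))
  expect_identical(simulate_coverage(g1, cfg), simulate_coverage(g1, cfg))
})

test_that("simulated mutation counts follow the binomial at the class rate", {
  cfg <- sim_config(seed = 7, genome_length_bp = 1e6,
                    class_fractions = c("non-repeat" = 1),
                    class_rates = c("non-repeat" = 1e-4))
  g <- generate_genome(cfg)
  sim <- simulate_ssnvs(g, cfg)
  n <- nrow(sim$calls)
  expect_gt(n, 100 - 4 * 10)  # 4 sigma of Binomial(1e6, 1e-4)
  expect_lt(n, 100 + 4 * 10)
  expect_true(all(sim$calls$ref != sim$calls$alt))
  expect_true(all(sim$calls$vaf == 1))  # clonal default

  cfg0 <- sim_config(seed = 7, genome_length_bp = 1e6,
                     class_fractions = c("non-repeat" = 1),
                     class_rates = c("non-repeat" = 0))
  expect_equal(nrow(simulate_ssnvs(g, cfg0)$calls), 0)
})

test_that("planted normal contamination is removed by the normal-evidence filter", {
  cfg <- sim_config(seed = 3, genome_length_bp = 5e5,
                    class_fractions = c("non-repeat" = 1),
                    class_rates = c("non-repeat" = 2e-4),
                    contamination_fraction = 0.5,
                    contamination_alt_depth = 2L)
  g <- generate_genome(cfg)
  calls <- simulate_ssnvs(g, cfg)$calls
  contaminated <- calls$alt_depth_normal >= 2
  expect_gt(sum(contaminated), 10)
  kept <- normal_evidence_filter(calls)
  expect_equal(sort(kept$pos), sort(calls$pos[!contaminated]))
})

test_that("simulated coverage is bimodal for a mixed karyotype and degenerates sanely", {
  kar <- data.frame(start = c(0, 3.5e6), end = c(3.5e6, 1e7),
                    state = c("1", "2"))
  cfg <- sim_config(seed = 9, genome_length_bp = 1e7,
                    class_fractions = c("non-repeat" = 1),
                    class_rates = c("non-repeat" = 0), karyotype = kar)
  g <- generate_genome(cfg)
  cov <- simulate_coverage(g, cfg)
  m <- find_coverage_modes(cov$tumor$depth, binwidth = 5)
  expect_lt(abs(m$primary - 123), 10)   # 2 x 61.5
  expect_lt(abs(m$haploid - 61.5), 10)
  mn <- find_coverage_modes(cov$normal$depth, binwidth = 5)
  expect_equal(mn$primary, mn$haploid)  # unimodal normal
  expect_lt(abs(mn$primary - 176), 10)

  kar1 <- data.frame(start = 0, end = 1e7, state = "1")
  cfg1 <- sim_config(seed = 9, genome_length_bp = 1e7,
                     class_fractions = c("non-repeat" = 1),
                     class_rates = c("non-repeat" = 0), karyotype = kar1,
                     depth_1n_tumor = 0)
  expect_true(all(simulate_coverage(g, cfg1)$tumor$depth == 0))
})

test_that("single-molecule methylation averages to the bulk track", {
  cfg <- sim_config(seed = 21, genome_length_bp = 6e5,
                    class_fractions = c("alpha-satellite" = 0.8),
                    class_rates = c("alpha-satellite" = 0,
                                    "non-repeat" = 0),
                    molecule_coverage = 30)
  g <- generate_genome(cfg)
  meth <- simulate_methylation(g, cfg)
  expect_gt(nrow(meth$bulk), 100)
  # molecule mean in dip vs baseline regions matches planted means
  sp <- somaT2T:::default_cdr_spec(g)[[1]]
  dip <- sp$dips[[1]]
  mol <- meth$molecules
  in_dip <- mol$pos >= dip[1] & mol$pos < dip[2]
  expect_lt(abs(mean(mol$meth[in_dip]) - cfg$meth_dip_level), 0.03)
  expect_lt(abs(mean(mol$meth[!in_dip]) - cfg$meth_baseline), 0.03)
  # law of large numbers: per-bin molecule means track the bulk values
  bin <- floor(mol$pos / 1000)
  mm <- tapply(mol$meth, bin, mean)
  bulk_at <- meth$bulk$value[match(as.numeric(names(mm)) * 1000,
                                   meth$bulk$start)]
  ok <- !is.na(bulk_at)
  expect_gt(cor(as.numeric(mm)[ok], bulk_at[ok]), 0.6)
})
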