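test_that("strand assignment counts canonical hexamers", {
  expect_equal(assign_strand(strrep("TTAGGG", 10)), "TTAGGG")
  expect_equal(assign_strand(strrep("CCCTAA", 10)), "CCCTAA")
  expect_true(is.na(assign_strand(paste0(strrep("TTAGGG", 3),
                                         strrep("CCCTAA", 3)))))
})

test_that("TVR parsing tiles the telomere and matches the exhaustive oracle", {
  pure <- strrep("TTAGGG", 20)
  p <- parse_tvrs(pure, 0)
  expect_equal(nrow(p$tvr), 0)
  expect_equal(p$canonical$end - p$canonical$start, 120)

  # (TTAGGG)10 TTGGGG (TTAGGG)10 -> one 6 bp TVR at offset 60
  mid <- paste0(strrep("TTAGGG", 10), "TTGGGG", strrep("TTAGGG", 10))
  p2 <- parse_tvrs(mid, 0)
  expect_equal(p2$tvr, data.frame(start = 60L, end = 66L))

  empty <- parse_tvrs("ACGTACGT", 8)  # no telomeric portion
  expect_equal(nrow(empty$canonical), 0)
  expect_equal(nrow(empty$tvr), 0)

  # partition + oracle properties over randomized telomeres
  set.seed(23)
  for (i in 1:15) {
    n_units <- sample(20:60, 1)
    units <- ifelse(runif(n_units) < 0.15,
                    c("TTGGGG", "TCAGGG", "ACGTAC")[sample.int(3, n_units,
                                                    replace = TRUE)],
                    "TTAGGG")
    telo <- paste(units, collapse = "")
    pp <- parse_tvrs(telo, 0)
    covered <- sum(pp$canonical$end - pp$canonical$start) +
      sum(pp$tvr$end - pp$tvr$start)
    expect_equal(covered, nchar(telo))  # exact tiling
    got <- intervals_to_mask(pp$canonical, nchar(telo))
    expect_identical(got, brute_canonical_mask(telo))
  }
})

test_that("TVR parsing is strand-involutive", {
  telo <- paste0(strrep("TTAGGG", 15), "TTGGGGTTGGGG",
                 strrep("TTAGGG", 15))
  read <- paste0("ACGTACGTAC", telo)  # 10 bp subtelomere
  fwd <- parse_tvrs(read, 10)
  rc <- somaT2T:::revcomp(read)
  rev <- parse_tvrs(rc, nchar(read) - 10)
  expect_equal(fwd$tvr, rev$tvr)
  expect_equal(fwd$canonical, rev$canonical)
})

test_that("telomere length counts bases distal to the junction", {
  read <- strrep("TTAGGG", 1000)
  expect_equal(telomere_length(read, 0), 6000)
  expect_equal(telomere_length(read, nchar(read)), 0)
  expect_error(telomere_length(read, nchar(read) + 1), "outside")
})

test_that("consensus profiles report per-offset TVR fractions and peaks", {
  mk_read <- function(with_tvr) {
    telo <- if (with_tvr) {
      paste0(strrep("TTAGGG", 20), strrep("TTGGGG", 5),
             strrep("TTAGGG", 40))
    } else strrep("TTAGGG", 65)
    data.frame(sequence = telo, boundary_offset = 0)
  }
  ident <- do.call(rbind, replicate(6, mk_read(TRUE), simplify = FALSE))
  prof <- consensus_tvr_profile(ident)
  expect_true(all(prof$fraction %in% c(0, 1)))  # identical reads
  expect_equal(nrow(prof$peaks), 1)
  expect_lte(abs(prof$peaks$offset - 135), 15)

  half <- rbind(ident[1:3, ], do.call(rbind, replicate(3, mk_read(FALSE),
                                                       simplify = FALSE)))
  prof2 <- consensus_tvr_profile(half)
  expect_lt(abs(prof2$peaks$height - 0.5), 0.12)
  expect_error(consensus_tvr_profile(ident[0, ]), "no reads")
})

test_that("restructuring detection follows the peak-matching rule", {
  cfg <- sim_config(seed = 41, telomere_spec = default_telomere_spec(3))
  tel <- simulate_telomeres(cfg)
  for (nm in unique(tel$telomere)) {
    rn <- tel[tel$telomere == nm & tel$sample == "normal", ]
    rt <- tel[tel$telomere == nm & tel$sample == "tumor", ]
    det <- detect_restructuring(consensus_tvr_profile(rn),
                                consensus_tvr_profile(rt))
    expect_true(det$restructured)
    expect_lte(abs(det$distal_boundary - 1502), 50)
    expect_lte(abs(det$proximal_limit - 1378), 50)
  }

  # identical profiles: not restructured
  rn <- tel[tel$telomere == "tel01" & tel$sample == "normal", ]
  pn <- consensus_tvr_profile(rn)
  expect_false(detect_restructuring(pn, pn)$restructured)

  # tumor-only new peak without a lost normal peak: not restructured
  p_norm <- structure(list(peaks = data.frame(offset = c(200, 600),
                                              height = 0.5)),
                      class = "tvr_profile")
  p_tum <- structure(list(peaks = data.frame(offset = c(200, 600, 1500),
                                             height = 0.5)),
                     class = "tvr_profile")
  d <- detect_restructuring(p_norm, p_tum)
  expect_false(d$restructured)
  expect_equal(d$tumor_only, 1500)
})

test_that("attrition/extension summary reports the planted design", {
  calls <- list(
    t1 = list(restructured = TRUE, proximal_limit = 1400),
    t2 = list(restructured = TRUE, proximal_limit = 1350),
    t3 = list(restructured = FALSE))
  lens <- list(t1 = c(3700, 3720), t2 = 3600, t3 = 6000)
  s <- summarize_attrition_extension(calls, lens)
  expect_equal(nrow(s), 2)  # non-restructured excluded
  expect_equal(s$extension[s$telomere == "t1"], 2310)
  expect_false(any(s$internal_deletion))
  # negative extension flags an internal-deletion candidate
  calls$t2$proximal_limit <- 4000
  s2 <- summarize_attrition_extension(calls, lens)
  expect_true(s2$internal_deletion[s2$telomere == "t2"])
})
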