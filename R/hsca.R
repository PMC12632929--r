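# Haplotype-selective chromatin accessibility: per-peak testing, explained
# -variant partition, additive-CNV expectation, boundary-distance enrichment.

#' Test peaks for haplotype-selective accessibility
#'
#' Fisher's exact test on `[accessible, inaccessible] x [hap1, hap2]` per
#' peak, with Benjamini-Hochberg correction across tested peaks; a peak is
#' selective iff q < `fdr`. Peaks with zero total fibers on either
#' haplotype, or on single-haplotype (LOH) loci where one haplotype's copy
#' number is zero, carry no contrast and are excluded (with a warning).
#'
#' @param peaks data.frame with `acc_hap1`, `total_hap1`, `acc_hap2`,
#'   `total_hap2` and optionally `hcn_hap1`, `hcn_hap2`.
#' @param fdr False discovery rate threshold.
#' @return `peaks` with `odds_ratio`, `p`, `q`, `selective`, `tested`.
#' @export
test_haplotype_selectivity <- function(peaks, fdr = 0.05) {
  stopifnot(all(peaks$acc_hap1 <= peaks$total_hap1),
            all(peaks$acc_hap2 <= peaks$total_hap2))
  testable <- peaks$total_hap1 > 0 & peaks$total_hap2 > 0
  if ("hcn_hap1" %in% names(peaks)) {
    testable <- testable & peaks$hcn_hap1 > 0 & peaks$hcn_hap2 > 0
  }
  if (any(!testable)) {
    warning(sum(!testable), " peak(s) without two-haplotype contrast ",
            "excluded from testing")
  }
  n <- nrow(peaks)
  p <- or <- rep(NA_real_, n)
  for (i in which(testable)) {
    tab <- matrix(c(peaks$acc_hap1[i],
                    peaks$total_hap1[i] - peaks$acc_hap1[i],
                    peaks$acc_hap2[i],
                    peaks$total_hap2[i] - peaks$acc_hap2[i]), nrow = 2)
    ft <- fisher.test(tab)
    p[i] <- ft$p.value
    or[i] <- unname(ft$estimate)
  }
  q <- rep(NA_real_, n)
  q[testable] <- p.adjust(p[testable], method = "BH")
  peaks$odds_ratio <- or
  peaks$p <- p
  peaks$q <- q
  peaks$tested <- testable
  peaks$selective <- !is.na(q) & q < fdr
  peaks
}

#' Partition selective peaks by explanation
#'
#' Priority partition of selective peaks: somatic-variant-explained, then
#' germline-het-explained, then imprinted, then unexplained. Non-selective
#' peaks are excluded.
#'
#' @param peaks Output of [test_haplotype_selectivity()], with
#'   `n_somatic_variants`, `n_germline_hets` and `imprinted` columns.
#' @return List with `peaks` (selective peaks plus an `explanation` column)
#'   and `counts` per category.
#' @export
partition_selective <- function(peaks) {
  sel <- peaks[isTRUE_vec(peaks$selective), , drop = FALSE]
  expl <- ifelse(sel$n_somatic_variants > 0, "variant-explained",
          ifelse(sel$n_germline_hets > 0, "germline-explained",
          ifelse(sel$imprinted, "imprinted", "unexplained")))
  sel$explanation <- expl
  lv <- c("variant-explained", "germline-explained", "imprinted",
          "unexplained")
  counts <- table(factor(expl, levels = lv))
  list(peaks = sel, counts = counts)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Additive copy-number expectation for accessibility
#'
#' Under an additive model the expected split of accessible fibers between
#' haplotypes equals the copy-number split `hCN1 : hCN2`. Reports per peak
#' the observed accessible counts and the expected counts given each peak's
#' total accessible fibers, plus the Pearson correlation between observed
#' and expected accessible-fiber counts across peak-haplotypes.
#'
#' @param peaks data.frame with accessible counts and `hcn_hap1`,
#'   `hcn_hap2`.
#' @return List with `peaks` (adds `expected_hap1`, `expected_hap2`,
#'   `observed_ratio`, `expected_ratio`) and `correlation`.
#' @export
additive_expectation <- function(peaks) {
  tot_cn <- peaks$hcn_hap1 + peaks$hcn_hap2
  if (any(tot_cn <= 0)) stop("peaks with zero total copy number")
  tot_acc <- peaks$acc_hap1 + peaks$acc_hap2
  e1 <- tot_acc * peaks$hcn_hap1 / tot_cn
  e2 <- tot_acc * peaks$hcn_hap2 / tot_cn
  peaks$expected_hap1 <- e1
  peaks$expected_hap2 <- e2
  peaks$observed_ratio <- ifelse(tot_acc > 0,
                                 peaks$acc_hap1 / tot_acc, NA_real_)
  peaks$expected_ratio <- peaks$hcn_hap1 / tot_cn
  obs <- c(peaks$acc_hap1, peaks$acc_hap2)
  exp <- c(e1, e2)
  list(peaks = peaks, correlation = cor(obs, exp))
}

segment_boundaries <- function(segments) {
  out <- list()
  for (ct in unique(segments$contig)) {
    s <- segments[segments$contig == ct, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2) next
    chg <- which(s$state[-1] != s$state[-nrow(s)])
    if (length(chg)) {
      out[[ct]] <- data.frame(contig = ct, pos = s$end[chg],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||% data.frame(contig = character(), pos = numeric())
}

distance_to_boundary <- function(peaks, boundaries) {
  vapply(seq_len(nrow(peaks)), function(i) {
    b <- boundaries$pos[boundaries$contig == peaks$contig[i]]
    if (!length(b)) return(NA_real_)
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    min(abs(mid - b))
  }, numeric(1))
}

#' Enrichment of peaks near copy-number boundaries
#'
#' For each peak, the distance to the nearest hCN state change; reported as
#' cumulative fractions within each grid distance for the unexplained
#' selective peaks versus a background peak set, with the difference curve
#' and a bootstrap band from resampling the unexplained set.
#'
#' @param unexplained_peaks,background_peaks Peak data.frames (`contig`,
#'   `start`, `end`).
#' @param segments Classified hCN segments (state changes define
#'   boundaries).
#' @param grid_mb Grid of distances in Mb (default 0.5 to 20 Mb).
#' @param n_boot Bootstrap resamples for the difference band.
#' @param seed Optional seed for the bootstrap.
#' @return data.frame (`distance_mb`, `frac_unexplained`, `frac_background`,
#'   `difference`, `diff_lo`, `diff_hi`).
#' @export
boundary_distance_enrichment <- function(unexplained_peaks,
                                         background_peaks, segments,
                                         grid_mb = seq(0.5, 20, by = 0.5),
                                         n_boot = 1000, seed = NULL) {
  if (is.null(segments) || nrow(segments) == 0) stop("no segments supplied")
  bnd <- segment_boundaries(segments)
  if (nrow(bnd) == 0) stop("segments contain no state changes")
  du <- distance_to_boundary(unexplained_peaks, bnd)
  db <- distance_to_boundary(background_peaks, bnd)
  cum <- function(d, g) mean(d <= g * 1e6, na.rm = TRUE)
  fu <- vapply(grid_mb, function(g) cum(du, g), numeric(1))
  fb <- vapply(grid_mb, function(g) cum(db, g), numeric(1))
  run <- function() {
    boot <- matrix(NA_real_, n_boot, length(grid_mb))
    for (b in seq_len(n_boot)) {
      dd <- sample(du, length(du), replace = TRUE)
      boot[b, ] <- vapply(grid_mb, function(g) cum(dd, g), numeric(1)) - fb
    }
    boot
  }
  boot <- if (is.null(seed)) run() else with_substream(seed, 14L, run())
  data.frame(distance_mb = grid_mb,
             frac_unexplained = fu,
             frac_background = fb,
             difference = fu - fb,
             diff_lo = apply(boot, 2, quantile, 0.025, na.rm = TRUE),
             diff_hi = apply(boot, 2, quantile, 0.975, na.rm = TRUE))
}
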