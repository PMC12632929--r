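# Somatic SNV/DNV filter cascade. Each stage only removes or annotates
# calls, never adds; the intended order is replicates -> normal evidence ->
# deleted segments -> cross-haplotype resolution -> density filter.

call_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Intersect calls from two tumor replicates
#'
#' Keeps calls present in both replicates, keyed by (contig, pos, ref, alt).
#' Depths from replicate A are retained; replicate B depths are attached with
#' a `_rep_b` suffix.
#'
#' @param calls_a,calls_b Call data.frames.
#' @return Shared calls.
#' @export
intersect_replicates <- function(calls_a, calls_b) {
  ka <- call_key(calls_a); kb <- call_key(calls_b)
  keep <- ka %in% kb
  out <- calls_a[keep, , drop = FALSE]
  m <- match(ka[keep], kb)
  out$depth_tumor_rep_b <- calls_b$depth_tumor[m]
  out$alt_depth_tumor_rep_b <- calls_b$alt_depth_tumor[m]
  rownames(out) <- NULL
  out
}

#' Filter calls with alt evidence in the normal sample
#'
#' A call is retained iff the number of alt-supporting reads in the normal is
#' at most `max_alt_reads` (default 1: a single alternate read is tolerated;
#' two or more indicate a germline variant or shared artifact).
#'
#' @param calls Call data.frame.
#' @param normal_pileups Optional data.frame (`contig`, `pos`,
#'   `alt_depth_normal`) overriding the calls' own normal support.
#' @param max_alt_reads Maximum tolerated normal alt depth.
#' @return Retained calls.
#' @export
normal_evidence_filter <- function(calls, normal_pileups = NULL,
                                   max_alt_reads = 1) {
  alt_n <- calls$alt_depth_normal
  if (!is.null(normal_pileups)) {
    m <- match(paste(calls$contig, calls$pos),
               paste(normal_pileups$contig, normal_pileups$pos))
    alt_n <- ifelse(is.na(m), alt_n, normal_pileups$alt_depth_normal[m])
  }
  out <- calls[alt_n <= max_alt_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove calls inside deleted segments
#'
#' Calls falling in DEL-state segments are dropped (such regions are
#' hemizygous from the intact haplotype, and calls there are mismapping
#' artifacts). Calls outside any segment are kept with a warning.
#'
#' @param calls Call data.frame.
#' @param segments Classified hCN segments.
#' @return Retained calls.
#' @export
remove_deleted_segments <- function(calls, segments) {
  if (nrow(calls) == 0) return(calls)
  idx <- point_in_intervals(calls$contig, calls$pos - 1L, segments)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " call(s) outside any segment; kept")
  }
  del <- !is.na(idx) & segments$state[idx] %in% c("DEL", "0")
  out <- calls[!del, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve cross-haplotype duplicate calls
#'
#' Each input row is one variant called at homologous positions on both
#' haplotypes, with alt/ref read counts per haplotype from a first-tier read
#' source and optionally a second tier. A two-sided Fisher's exact test on
#' the 2x2 table `[alt, ref] x [hap1, hap2]` assigns the variant to the
#' haplotype with the higher alt fraction when p < `p_cut`; otherwise the
#' second-tier counts are tested; still-ambiguous records are flagged.
#'
#' @param paired_calls data.frame with columns `alt1`, `ref1`, `alt2`, `ref2`
#'   and optionally `alt1_t2`, `ref1_t2`, `alt2_t2`, `ref2_t2`.
#' @param p_cut Assignment significance threshold.
#' @return `paired_calls` with `assigned_hap` (1, 2 or NA), `p_tier1`,
#'   `p_tier2`, and `ambiguous`.
#' @export
cross_haplotype_resolve <- function(paired_calls, p_cut = 0.01) {
  n <- nrow(paired_calls)
  test_one <- function(a1, r1, a2, r2) {
    if (a1 + r1 + a2 + r2 == 0) return(list(p = NA_real_, hap = NA_integer_))
    p <- fisher.test(matrix(c(a1, r1, a2, r2), nrow = 2))$p.value
    f1 <- if (a1 + r1 > 0) a1 / (a1 + r1) else 0
    f2 <- if (a2 + r2 > 0) a2 / (a2 + r2) else 0
    list(p = p, hap = if (f1 >= f2) 1L else 2L)
  }
  p1 <- p2 <- rep(NA_real_, n)
  hap <- rep(NA_integer_, n)
  has_t2 <- all(c("alt1_t2", "ref1_t2", "alt2_t2", "ref2_t2") %in%
                  names(paired_calls))
  for (i in seq_len(n)) {
    t1 <- test_one(paired_calls$alt1[i], paired_calls$ref1[i],
                   paired_calls$alt2[i], paired_calls$ref2[i])
    p1[i] <- t1$p
    if (!is.na(t1$p) && t1$p < p_cut) {
      hap[i] <- t1$hap
    } else if (has_t2) {
      t2 <- test_one(paired_calls$alt1_t2[i], paired_calls$ref1_t2[i],
                     paired_calls$alt2_t2[i], paired_calls$ref2_t2[i])
      p2[i] <- t2$p
      if (!is.na(t2$p) && t2$p < p_cut) hap[i] <- t2$hap
    }
  }
  paired_calls$p_tier1 <- p1
  paired_calls$p_tier2 <- p2
  paired_calls$assigned_hap <- hap
  paired_calls$ambiguous <- is.na(hap)
  paired_calls
}

#' Density filter for clustered artifact calls
#'
#' Slides 1 kb windows at 500 bp steps, merges windows holding at least
#' `min_snvs` calls, and discards the calls of a merged region if (a) at
#' least three of its calls each have VAF below `vaf_cut`, or (b) the median
#' call depth is below `mu - k_sigma * sqrt(mu)` (Poisson sigma at the
#' haploid coverage mu; default 61.5 - 3 * sqrt(61.5) ~ 38.0). The two rules
#' fire independently.
#'
#' @param calls Call data.frame.
#' @param window,step Window and step size in bp.
#' @param min_snvs Minimum calls for a window to trigger merging.
#' @param vaf_cut VAF threshold of rule (a).
#' @param mu Haploid coverage of the tumor (Poisson mean).
#' @param k_sigma Number of Poisson SDs below `mu` for rule (b).
#' @param drop_all Drop every call in a triggering region (default) or only
#'   sub-threshold ones.
#' @return Retained calls; removed calls are attached as
#'   `attr(, "removed")`.
#' @export
density_filter <- function(calls, window = 1000, step = 500, min_snvs = 3,
                           vaf_cut = 0.75, mu = 61.5, k_sigma = 3,
                           drop_all = TRUE) {
  if (nrow(calls) == 0) {
    attr(calls, "removed") <- calls
    return(calls)
  }
  depth_cut <- mu - k_sigma * sqrt(mu)
  drop <- rep(FALSE, nrow(calls))
  for (ct in unique(calls$contig)) {
    ci <- which(calls$contig == ct)
    pos <- calls$pos[ci] - 1L
    w_starts <- seq(0, max(pos), by = step)
    cnt <- vapply(w_starts, function(s) sum(pos >= s & pos < s + window),
                  integer(1))
    trig <- w_starts[cnt >= min_snvs]
    if (!length(trig)) next
    regions <- merge_intervals(
      data.frame(contig = ct, start = trig, end = trig + window), max_gap = 0)
    for (j in seq_len(nrow(regions))) {
      inside <- ci[pos >= regions$start[j] & pos < regions$end[j]]
      if (!length(inside)) next
      low_vaf <- calls$vaf[inside] < vaf_cut
      rule_a <- sum(low_vaf) >= 3
      rule_b <- median(calls$depth_tumor[inside]) < depth_cut
      if (rule_a || rule_b) {
        if (drop_all) drop[inside] <- TRUE
        else drop[inside[low_vaf]] <- TRUE
      }
    }
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- calls[drop, , drop = FALSE]
  out
}

#' Merge adjacent SNVs into DNVs
#'
#' Runs of calls at consecutive positions are clustered; an even-sized
#' cluster is split into consecutive pairs, and a pair becomes a DNV iff both
#' calls are fixed on the same haplotype (VAF at least `fixed_vaf`) or share
#' a non-missing phase set on the same haplotype. Odd clusters larger than
#' one are flagged for review and left as SNVs; merged DNVs are removed from
#' the SNV set.
#'
#' @param calls Call data.frame.
#' @param fixed_vaf VAF at or above which a call counts as haplotype-fixed.
#' @return List with `dnvs` (2 bp ref/alt records), `snvs` (remaining calls)
#'   and `flagged_clusters` (positions of odd clusters).
#' @export
call_dnvs <- function(calls, fixed_vaf = 0.9) {
  if (nrow(calls) == 0) {
    return(list(dnvs = data.frame(), snvs = calls,
                flagged_clusters = list()))
  }
  o <- order(calls$contig, calls$pos)
  calls <- calls[o, , drop = FALSE]
  adj <- c(FALSE, diff(calls$pos) == 1 &
             calls$contig[-1] == calls$contig[-nrow(calls)])
  cluster <- cumsum(!adj)
  dnv_rows <- list()
  merged <- rep(FALSE, nrow(calls))
  flagged <- list()
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    if (length(idx) < 2) next
    if (length(idx) %% 2 == 1) {
      flagged[[length(flagged) + 1L]] <-
        calls[idx, c("contig", "pos"), drop = FALSE]
      next
    }
    for (p in seq(1, length(idx), by = 2)) {
      i <- idx[p]; j <- idx[p + 1]
      same_hap <- !is.na(calls$haplotype[i]) &&
        !is.na(calls$haplotype[j]) &&
        calls$haplotype[i] == calls$haplotype[j]
      both_fixed <- calls$vaf[i] >= fixed_vaf && calls$vaf[j] >= fixed_vaf
      same_ps <- !is.na(calls$phase_set[i]) && !is.na(calls$phase_set[j]) &&
        calls$phase_set[i] == calls$phase_set[j]
      if (same_hap && (both_fixed || same_ps)) {
        merged[c(i, j)] <- TRUE
        dnv_rows[[length(dnv_rows) + 1L]] <- data.frame(
          contig = calls$contig[i], pos = calls$pos[i],
          ref = paste0(calls$ref[i], calls$ref[j]),
          alt = paste0(calls$alt[i], calls$alt[j]),
          haplotype = calls$haplotype[i], stringsAsFactors = FALSE)
      }
    }
  }
  snvs <- calls[!merged, , drop = FALSE]
  rownames(snvs) <- NULL
  list(dnvs = do.call(rbind, dnv_rows) %||%
         data.frame(contig = character(), pos = integer(), ref = character(),
                    alt = character(), haplotype = integer()),
       snvs = snvs, flagged_clusters = flagged)
}

#' Validate calls against an orthogonal technology
#'
#' @param calls Call data.frame.
#' @param orthogonal_pileups data.frame (`contig`, `pos`, `alt_depth`) of
#'   alt support in a held-out technology.
#' @param min_support Minimum alt reads for a call to count as validated.
#' @return Fraction of calls validated.
#' @export
validate_against <- function(calls, orthogonal_pileups, min_support = 1) {
  if (nrow(calls) == 0) return(NA_real_)
  m <- match(paste(calls$contig, calls$pos),
             paste(orthogonal_pileups$contig, orthogonal_pileups$pos))
  sup <- ifelse(is.na(m), 0L, orthogonal_pileups$alt_depth[m])
  mean(sup >= min_support)
}

#' Haplotype-restricted variant allele fraction
#'
#' The default definition is the VAF among reads assigned to the call's
#' haplotype (`alt_hap_depth / hap_depth`). The alternative definition scales
#' the bulk VAF by the local haploid copy number.
#'
#' @param calls Call data.frame; for `method = "restricted"` it needs
#'   `hap_depth` and `alt_hap_depth` columns (falling back to the bulk
#'   depths when absent, appropriate for fully haplotype-partitioned reads).
#' @param method `"restricted"` or `"vaf_times_hcn"`.
#' @param hcn Local haploid copy number per call (for `"vaf_times_hcn"`).
#' @return Numeric hVAF vector.
#' @export
hvaf <- function(calls, method = c("restricted", "vaf_times_hcn"),
                 hcn = NULL) {
  method <- match.arg(method)
  if (method == "restricted") {
    hd <- calls$hap_depth %||% calls$depth_tumor
    ad <- calls$alt_hap_depth %||% calls$alt_depth_tumor
    ifelse(hd > 0, ad / hd, NA_real_)
  } else {
    if (is.null(hcn)) stop("hcn required for method 'vaf_times_hcn'")
    calls$vaf * hcn
  }
}
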