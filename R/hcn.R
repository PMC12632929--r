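# Haploid copy number: coverage modes, log2 hCN ratio, segmentation,
# classification, altered-genome fraction.

#' Locate the primary and haploid coverage modes
#'
#' The tumor base-level coverage histogram of a genome-duplicated tumor is
#' bimodal: the primary (global-maximum) mode sits on the duplicated
#' segments, while the second, lower-coverage peak marks haploid (1n)
#' coverage. For a unimodal histogram (e.g. the diploid normal) both modes
#' coincide.
#'
#' @param depths Numeric vector of per-base or per-window depths, or a
#'   pre-tabulated histogram given as a named numeric vector (names = depth,
#'   values = count).
#' @param binwidth Histogram bin width in depth units.
#' @param smooth Running-mean smoothing width (bins, odd) applied before mode
#'   finding.
#' @param min_peak_frac Minimum height of a secondary mode relative to the
#'   primary mode.
#' @param valley_frac A secondary mode must be separated from the primary by
#'   a valley below this fraction of the lower of the two peak heights
#'   (suppresses shoulder noise on a unimodal histogram).
#' @return List with `primary` and `haploid` mode depths (bin centers).
#' @export
find_coverage_modes <- function(depths, binwidth = 1, smooth = 5,
                                min_peak_frac = 0.1, valley_frac = 0.8) {
  if (length(depths) == 0) stop("empty depth histogram")
  if (!is.null(names(depths))) {
    centers <- as.numeric(names(depths))
    counts <- as.numeric(depths)
    o <- order(centers)
    centers <- centers[o]; counts <- counts[o]
    # re-bin onto a regular grid
    grid <- seq(floor(min(centers) / binwidth) * binwidth,
                max(centers), by = binwidth)
    idx <- findInterval(centers, grid)
    cnt <- rep(0, length(grid))
    for (i in seq_along(idx)) cnt[idx[i]] <- cnt[idx[i]] + counts[i]
    centers <- grid + binwidth / 2
    counts <- cnt
  } else {
    b <- floor(depths / binwidth)
    rng <- range(b)
    counts <- tabulate(b - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
    centers <- (rng[1]:rng[2]) * binwidth + binwidth / 2
  }
  k <- max(1L, as.integer(smooth))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1 && length(counts) >= k) {
    pad <- (k - 1) / 2
    cs <- cumsum(c(0, counts))
    sm <- vapply(seq_along(counts), function(i) {
      lo <- max(1, i - pad); hi <- min(length(counts), i + pad)
      (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }, numeric(1))
  } else sm <- counts
  primary_i <- which.max(sm)  # leftmost on ties
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i] > sm[i - 1] else TRUE
    right <- if (i < n) sm[i] >= sm[i + 1] else TRUE
    left && right
  }, logical(1))
  below <- which(is_max & seq_len(n) < primary_i)
  # a genuine secondary mode must be tall enough and valley-separated from
  # the primary; monotone shoulders and tail noise fail both
  below <- below[vapply(below, function(i) {
    sm[i] >= min_peak_frac * sm[primary_i] &&
      min(sm[i:primary_i]) < valley_frac * min(sm[i], sm[primary_i])
  }, logical(1))]
  haploid_i <- if (length(below)) below[which.max(sm[below])] else primary_i
  list(primary = centers[primary_i], haploid = centers[haploid_i])
}

#' Per-window log2 haploid copy-number ratio
#'
#' `log2((tumor_w / tumor_1n) / (normal_w / normal_1n))` for matched windows,
#' where the normalization constants are the haploid (1n) coverages of each
#' sample. For a diploid normal the 1n constant is half the unimodal coverage
#' mode. Values below the cap are capped; windows with zero normal coverage
#' are masked (`NA`).
#'
#' @param tumor,normal Matched coverage window data.frames (`contig`, `start`,
#'   `end`, `depth`).
#' @param tumor_1n,normal_1n Positive haploid-coverage normalization
#'   constants.
#' @param cap Lower cap on the ratio (default -1.5).
#' @return A `log2_profile` data.frame (`contig`, `start`, `end`, `ratio`)
#'   with the normalization constants stored as attributes.
#' @export
log2_hcn_ratio <- function(tumor, normal, tumor_1n, normal_1n, cap = -1.5) {
  stopifnot(tumor_1n > 0, normal_1n > 0)
  if (nrow(tumor) != nrow(normal) ||
      any(tumor$start != normal$start | tumor$contig != normal$contig)) {
    stop("tumor and normal windows must match")
  }
  ratio <- log2((tumor$depth / tumor_1n) / (normal$depth / normal_1n))
  ratio[normal$depth == 0] <- NA_real_
  ratio[!is.na(ratio) & ratio < cap] <- cap
  out <- data.frame(contig = tumor$contig, start = tumor$start,
                    end = tumor$end, ratio = ratio,
                    stringsAsFactors = FALSE)
  attr(out, "tumor_1n") <- tumor_1n
  attr(out, "normal_1n") <- normal_1n
  class(out) <- c("log2_profile", "data.frame")
  out
}

trimmed_sd <- function(x, trim = 0.025) {
  q <- quantile(x, c(trim, 1 - trim), na.rm = TRUE, names = FALSE)
  xx <- x[!is.na(x) & x >= q[1] & x <= q[2]]
  if (length(xx) < 2) return(0)
  sd(xx)
}

#' Smooth single-window outliers in a log2 profile
#'
#' A window is an outlier if it deviates more than `outlier_sd_scale` trimmed
#' standard deviations from the median of its `region`-window neighbourhood;
#' outliers are shrunk to that median plus/minus `shrink_sd_scale` trimmed
#' SDs. This is an approximation of the outlier-smoothing step conventionally
#' applied before circular binary segmentation, with all parameters exposed.
#'
#' @param x Numeric vector of per-window ratios (NAs passed through).
#' @param region Neighbourhood size in windows.
#' @param outlier_sd_scale Outlier threshold in trimmed SDs.
#' @param shrink_sd_scale Shrinkage target in trimmed SDs.
#' @param trim Tail fraction excluded from the SD estimate.
#' @return Smoothed numeric vector.
#' @export
smooth_outliers <- function(x, region = 10, outlier_sd_scale = 4,
                            shrink_sd_scale = 2, trim = 0.025) {
  n <- length(x)
  if (n < 3) return(x)
  sd_t <- trimmed_sd(x, trim)
  if (sd_t == 0) return(x)
  half <- max(1L, floor(region / 2))
  out <- x
  for (i in which(!is.na(x))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    nb <- x[setdiff(lo:hi, i)]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    m <- median(nb)
    if (abs(x[i] - m) > outlier_sd_scale * sd_t) {
      out[i] <- m + sign(x[i] - m) * shrink_sd_scale * sd_t
    }
  }
  out
}

# max two-sample t statistic over all admissible splits; cumsum-vectorized.
# Returns list(k = leftmost argmax split index (left segment = 1..k), t = max).
max_split_t <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(list(k = NA_integer_, t = -Inf))
  s <- cumsum(x); ss <- cumsum(x^2)
  k <- min_width:(n - min_width)
  n1 <- k; n2 <- n - k
  m1 <- s[k] / n1
  m2 <- (s[n] - s[k]) / n2
  ss1 <- ss[k] - n1 * m1^2
  ss2 <- (ss[n] - ss[k]) - n2 * m2^2
  vp <- pmax((ss1 + ss2) / (n - 2), 0)  # guard float cancellation
  se <- sqrt(vp * (1 / n1 + 1 / n2))
  tt <- abs(m1 - m2) / se
  tt[se == 0 & m1 != m2] <- Inf
  tt[se == 0 & m1 == m2] <- 0
  best <- which.max(tt)  # leftmost on ties
  list(k = k[best], t = tt[best])
}

# permutation p-value for the max-t split statistic; early exit once the
# exceedance count rules out p < alpha.
split_permutation_p <- function(x, t_obs, min_width, nperm, alpha) {
  if (!is.finite(t_obs)) return(1 / (nperm + 1))
  exceed <- 0L
  limit <- ceiling(alpha * (nperm + 1))
  for (b in seq_len(nperm)) {
    tb <- max_split_t(sample(x), min_width)$t
    if (tb >= t_obs) {
      exceed <- exceed + 1L
      if (exceed >= limit) return((exceed + 1) / (b + 1))
    }
  }
  (exceed + 1) / (nperm + 1)
}

#' Smooth and segment a log2 hCN profile
#'
#' Outlier smoothing followed by recursive binary segmentation: at each step
#' the split maximizing the two-sample t statistic is accepted if its
#' within-segment permutation p-value is below `alpha`; both sides are then
#' segmented recursively. Every segment spans at least `min_width` windows.
#'
#' @param profile A [log2_hcn_ratio()] profile (NA windows are dropped).
#' @param min_width Minimum segment width in windows.
#' @param alpha Permutation significance level for accepting a split.
#' @param nperm Number of permutations per tested split.
#' @param seed Optional seed for the permutation stream.
#' @param smooth Apply [smooth_outliers()] first?
#' @return data.frame of segments (`contig`, `start`, `end`, `median_ratio`,
#'   `n_windows`).
#' @export
smooth_and_segment <- function(profile, min_width = 5, alpha = 1e-4,
                               nperm = 10000, seed = NULL, smooth = TRUE) {
  if (1 / (nperm + 1) >= alpha) {
    warning("nperm too small for alpha: minimum attainable p-value ",
            signif(1 / (nperm + 1), 3), " >= ", alpha,
            "; no split can be accepted")
  }
  run <- function() {
    segs <- list()
    for (ct in unique(profile$contig)) {
      p <- profile[profile$contig == ct & !is.na(profile$ratio), ,
                   drop = FALSE]
      if (nrow(p) == 0) next
      x <- p$ratio
      if (smooth) x <- smooth_outliers(x)
      bounds <- integer(0)  # right edges of segments (window indices)
      recurse <- function(lo, hi) {
        n <- hi - lo + 1
        if (n < 2 * min_width) return()
        sp <- max_split_t(x[lo:hi], min_width)
        if (!is.finite(sp$t) || sp$t == 0) return()
        pv <- split_permutation_p(x[lo:hi], sp$t, min_width, nperm, alpha)
        if (pv < alpha) {
          cut <- lo + sp$k - 1
          bounds <<- c(bounds, cut)
          recurse(lo, cut)
          recurse(cut + 1, hi)
        }
      }
      recurse(1, nrow(p))
      edges <- c(0, sort(unique(bounds)), nrow(p))
      for (i in seq_len(length(edges) - 1)) {
        idx <- (edges[i] + 1):edges[i + 1]
        segs[[length(segs) + 1L]] <- data.frame(
          contig = ct, start = p$start[idx[1]], end = p$end[idx[length(idx)]],
          median_ratio = median(x[idx]), n_windows = length(idx),
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, segs) %||%
      data.frame(contig = character(), start = integer(), end = integer(),
                 median_ratio = numeric(), n_windows = integer())
    rownames(res) <- NULL
    res
  }
  if (is.null(seed)) run() else with_substream(seed, 11L, run())
}

#' hCN classification thresholds
#'
#' Ordered breakpoints between haploid copy states. `"printed"` is the
#' conventional threshold table (-0.415, 0.585, 1.322, 1.848, 2.263);
#' `"formula"` recomputes all five as `log2(n + 0.5)` for n = 0..4, the
#' midpoints between integer copy states on the log2 scale. Two of the
#' printed values (0.585 = log2(1.5), 1.322 = log2(2.5)) coincide with the
#' formula; the remaining printed values are kept verbatim under
#' `"printed"`.
#'
#' @param type `"printed"` or `"formula"`.
#' @return Numeric vector of 5 ordered breakpoints.
#' @export
hcn_thresholds <- function(type = c("printed", "formula")) {
  type <- match.arg(type)
  if (type == "printed") c(-0.415, 0.585, 1.322, 1.848, 2.263)
  else log2((0:4) + 0.5)
}

hcn_states <- c("DEL", "1", "2", "3", "4", "amp")

#' Classify segments into haploid copy states
#'
#' Assigns each segment's state by interval membership of its median log2 hCN
#' ratio: `<= t1` DEL; `(t1, t2]` hCN=1; `(t2, t3]` hCN=2; `(t3, t4]` hCN=3;
#' `(t4, t5]` hCN=4; `> t5` amp.
#'
#' @param segments Output of [smooth_and_segment()].
#' @param thresholds Ordered breakpoint vector (default
#'   `hcn_thresholds("printed")`).
#' @return `segments` with a `state` column.
#' @export
classify_segments <- function(segments, thresholds = hcn_thresholds()) {
  stopifnot(length(thresholds) == 5, !is.unsorted(thresholds))
  idx <- findInterval(segments$median_ratio, thresholds, left.open = TRUE)
  segments$state <- hcn_states[idx + 1L]
  segments
}

#' Fraction of the profiled genome with altered copy number
#'
#' Base pairs in segments whose state differs from the neutral state, divided
#' by total profiled base pairs. The default neutral state is hCN=1, the
#' haploid baseline.
#'
#' @param segments Classified segments (with `state`).
#' @param neutral Neutral copy state.
#' @return Fraction in `[0, 1]`.
#' @export
altered_fraction <- function(segments, neutral = "1") {
  if (nrow(segments) == 0) stop("no segments")
  w <- segments$end - segments$start
  sum(w[segments$state != neutral]) / sum(w)
}
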