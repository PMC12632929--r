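# Per-class mutation rates, fold enrichment, two-proportion Z-test, and the
# breakpoint-vs-CDR Monte Carlo permutation test.

#' Default annotation priority
#'
#' Overlapping annotations are resolved by a fixed priority: kinetochore
#' classes, then satellite subclasses, then other repeat classes, then
#' non-repeat. Classes present in the annotations but not in this list are
#' slotted in just before `non-repeat`.
#'
#' @param annotations Optional annotation data.frame whose extra classes are
#'   appended.
#' @return Character vector, highest priority first.
#' @export
default_class_priority <- function(annotations = NULL) {
  base <- c("CDR", "non-CDR-HOR", "HSat2", "HSat3", "HSat1A", "HSat1B",
            "alpha-satellite", "SINE", "LINE", "LTR", "non-repeat")
  if (!is.null(annotations)) {
    extra <- setdiff(unique(annotations$class), base)
    base <- append(base, extra, after = length(base) - 1)
  }
  base
}

# Priority-partition annotations: each class keeps only bp not claimed by a
# higher-priority class. Returns list of class -> interval data.frame.
partition_by_priority <- function(annotations, priority) {
  grl <- list()
  claimed <- GenomicRanges::GRanges()
  for (cl in priority) {
    rows <- annotations[annotations$class == cl, , drop = FALSE]
    if (nrow(rows) == 0) next
    gr <- GenomicRanges::reduce(intervals_to_gr(rows))
    gr <- GenomicRanges::setdiff(gr, claimed)
    claimed <- GenomicRanges::union(claimed, gr)
    grl[[cl]] <- gr_to_intervals(gr)
  }
  grl
}

#' Somatic mutation rate per repeat class
#'
#' Counts calls and base pairs per annotation class (overlaps resolved by
#' `priority`) and reports the per-bp rate. Classes with zero bp are
#' omitted.
#'
#' @param calls Call data.frame (1-based `pos`).
#' @param annotations Annotation data.frame (`contig`, `start`, `end`,
#'   `class`).
#' @param priority Class priority order for overlapping annotations.
#' @return data.frame (`class`, `bases`, `count`, `rate`).
#' @export
rate_by_class <- function(calls, annotations,
                          priority = default_class_priority(annotations)) {
  parts <- partition_by_priority(annotations, priority)
  rows <- lapply(names(parts), function(cl) {
    iv <- parts[[cl]]
    bp <- sum(iv$end - iv$start)
    if (bp == 0) return(NULL)
    cnt <- if (nrow(calls)) {
      sum(!is.na(point_in_intervals(calls$contig, calls$pos - 1L, iv)))
    } else 0L
    data.frame(class = cl, bases = bp, count = cnt, rate = cnt / bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold enrichment over a baseline class
#'
#' @param rates Output of [rate_by_class()].
#' @param baseline_class Baseline class name (default `"non-repeat"`).
#' @return Named numeric vector of `rate / baseline rate` per class.
#' @export
fold_enrichment <- function(rates, baseline_class = "non-repeat") {
  b <- rates$rate[rates$class == baseline_class]
  if (length(b) != 1) stop("baseline class '", baseline_class,
                           "' not found in rates")
  if (b == 0) stop("baseline rate is zero; fold enrichment undefined")
  setNames(rates$rate / b, rates$class)
}

#' Pooled aggregate rate over a set of classes
#'
#' @param rates Output of [rate_by_class()].
#' @param classes Classes to pool.
#' @return Pooled per-bp rate (total count / total bp).
#' @export
pooled_rate <- function(rates, classes) {
  r <- rates[rates$class %in% classes, , drop = FALSE]
  if (nrow(r) == 0) stop("no matching classes")
  sum(r$count) / sum(r$bases)
}

#' Two-proportion Z-test
#'
#' Pooled-variance z statistic
#' `(p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with the two-sided p-value
#' from the normal tail.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z` and `p`.
#' @export
two_prop_ztest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Project intervals (e.g. CDRs) into the concatenated coordinate space of the
# placement intervals; returns sorted boundary vector for even/odd membership.
project_into_space <- function(target, space) {
  bounds <- numeric(0)
  cum <- 0
  tg <- intervals_to_gr(target)
  for (i in seq_len(nrow(space))) {
    sg <- GenomicRanges::GRanges(
      space$contig[i], IRanges::IRanges(space$start[i] + 1, space$end[i]))
    ov <- GenomicRanges::intersect(tg, sg)
    if (length(ov)) {
      s <- GenomicRanges::start(ov) - 1 - space$start[i] + cum
      e <- GenomicRanges::end(ov) - space$start[i] + cum
      bounds <- c(bounds, rbind(s, e))
    }
    cum <- cum + (space$end[i] - space$start[i])
  }
  sort(bounds)
}

#' Monte Carlo test for breakpoint-CDR co-localization
#'
#' Places the observed number of breakpoints uniformly at random over the
#' placement space (e.g. all alpha-satellite HOR bp) in each iteration and
#' counts how often at least `min_overlap` of them fall inside CDR
#' intervals. The p-value is the +1-corrected fraction of iterations meeting
#' that bar — the probability of observing the co-localization by chance
#' alone.
#'
#' @param breakpoints data.frame (`contig`, `pos` 0-based) of breakpoint
#'   positions.
#' @param cdrs CDR interval data.frame.
#' @param placement_space Interval data.frame of candidate placement bp.
#' @param n_iter Number of Monte Carlo iterations.
#' @param min_overlap Overlap count defining the event.
#' @param seed Optional seed.
#' @return List with `p`, `observed_overlap`, `n_iter`.
#' @export
breakpoint_cdr_permutation <- function(breakpoints, cdrs, placement_space,
                                       n_iter = 1e5, min_overlap = 2,
                                       seed = NULL) {
  n_bp <- nrow(breakpoints)
  obs <- if (n_bp) {
    sum(!is.na(point_in_intervals(breakpoints$contig, breakpoints$pos,
                                  cdrs)))
  } else 0L
  if (n_bp == 0) {
    warning("no breakpoints supplied; p = 1 by convention")
    return(list(p = 1, observed_overlap = 0L, n_iter = n_iter))
  }
  total <- sum(placement_space$end - placement_space$start)
  if (total <= 0) stop("empty placement space")
  bounds <- project_into_space(cdrs, placement_space)
  run <- function() {
    hits <- integer(n_iter)
    chunk <- 10000L
    done <- 0L
    while (done < n_iter) {
      m <- min(chunk, n_iter - done)
      u <- matrix(runif(m * n_bp) * total, nrow = m)
      inside <- matrix(findInterval(u, bounds) %% 2 == 1, nrow = m)
      hits[(done + 1):(done + m)] <- rowSums(inside)
      done <- done + m
    }
    (sum(hits >= min_overlap) + 1) / (n_iter + 1)
  }
  p <- if (is.null(seed)) run() else with_substream(seed, 13L, run())
  list(p = p, observed_overlap = obs, n_iter = n_iter)
}
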