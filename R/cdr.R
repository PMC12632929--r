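# Centromere dip region (CDR) detection from CpG methylation, bulk and
# single-molecule, plus comparison metrics.

#' Prepare alpha-satellite arrays for CDR calling
#'
#' Merges arrays within `max_gap` bp of one another and drops merged arrays
#' shorter than `min_length`.
#'
#' @param alpha_sat Interval data.frame of alpha-satellite annotations.
#' @param max_gap Merge gap in bp (default 10 kb).
#' @param min_length Minimum merged array length in bp (default 100 kb).
#' @return Interval data.frame of arrays.
#' @export
prepare_arrays <- function(alpha_sat, max_gap = 10000, min_length = 100000) {
  m <- merge_intervals(alpha_sat, max_gap = max_gap)
  out <- m[(m$end - m$start) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Flip runs of one state shorter than max_run_bp that are flanked on both
# sides by the opposite state. Applied iteratively in the given order; a
# projection (applying it twice equals once).
smooth_state_runs <- function(low, bin, max_run_bp,
                              order = c("low_first", "high_first")) {
  order <- match.arg(order)
  flip_runs <- function(v, state) {
    repeat {
      r <- rle(v)
      n <- length(r$lengths)
      if (n < 3) return(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      changed <- FALSE
      for (i in 2:(n - 1)) {
        if (r$values[i] == state && r$lengths[i] * bin <= max_run_bp &&
            r$values[i - 1] == !state && r$values[i + 1] == !state) {
          v[starts[i]:ends[i]] <- !state
          changed <- TRUE
          break
        }
      }
      if (!changed) return(v)
    }
  }
  if (order == "low_first") {
    flip_runs(flip_runs(low, TRUE), FALSE)
  } else {
    flip_runs(flip_runs(low, FALSE), TRUE)
  }
}

call_cdr_one <- function(bin_starts, bin_ends, values, array_start,
                         array_end, bin, z_cut, smooth_run, edge,
                         smooth_order) {
  ok <- !is.na(values)
  if (sum(ok) < 2) return(NULL)
  mu <- mean(values[ok])
  sdev <- sqrt(mean((values[ok] - mu)^2))  # population SD of the array bins
  if (sdev == 0) return(NULL)
  z <- (values - mu) / sdev
  low <- !is.na(z) & z < z_cut
  low <- smooth_state_runs(low, bin, smooth_run, smooth_order)
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s_bp <- bin_starts[starts_i[i]]
    e_bp <- bin_ends[ends_i[i]]
    if (s_bp < array_start + edge || e_bp > array_end - edge) next
    idx <- starts_i[i]:ends_i[i]
    segs[[length(segs) + 1L]] <- data.frame(
      start = s_bp, end = e_bp, mean_z = mean(z[idx], na.rm = TRUE),
      n_bins = length(idx), stringsAsFactors = FALSE)
  }
  do.call(rbind, segs)
}

#' Call bulk CDRs within alpha-satellite arrays
#'
#' Bins the methylation track at `bin` bp, computes per-array z-scores from
#' each array's own mean and population SD, flags bins below `z_cut`,
#' smooths short runs (`<= smooth_run` bp flanked by the opposite state are
#' flipped), and retains surviving low runs at least `edge` bp from both
#' array ends. Arrays with zero SD yield no calls (with a warning).
#'
#' @param track bedGraph-style methylation data.frame (`contig`, `start`,
#'   `end`, `value`), binned at (or finer than) `bin`.
#' @param arrays Array intervals from [prepare_arrays()].
#' @param bin Bin width in bp.
#' @param z_cut z-score threshold for a low-methylation bin.
#' @param smooth_run Maximum run length (bp) flipped by smoothing.
#' @param edge Minimum distance (bp) of a retained CDR from array ends.
#' @param smooth_order Smoothing pass order (`"low_first"` default).
#' @return data.frame of CDR calls (`contig`, `start`, `end`, `mean_z`,
#'   `n_bins`, `source = "bulk"`).
#' @export
call_bulk_cdrs <- function(track, arrays, bin = 1000, z_cut = -1.5,
                           smooth_run = 5000, edge = 50000,
                           smooth_order = "low_first") {
  out <- list()
  for (i in seq_len(nrow(arrays))) {
    a0 <- arrays$start[i]; a1 <- arrays$end[i]; ct <- arrays$contig[i]
    rows <- track$contig == ct & track$start >= a0 & track$end <= a1
    tr <- track[rows, , drop = FALSE]
    if (nrow(tr) == 0) next
    # aggregate onto the bin grid anchored at the array start
    g <- floor((tr$start - a0) / bin)
    agg <- tapply(tr$value, g, mean)
    gi <- as.integer(names(agg))
    bs <- a0 + gi * bin
    be <- pmin(bs + bin, a1)
    vals <- as.numeric(agg)
    if (length(vals) >= 2 &&
        sqrt(mean((vals - mean(vals))^2)) == 0) {
      warning("array ", ct, ":", a0, "-", a1, " has zero SD; no calls")
      next
    }
    segs <- call_cdr_one(bs, be, vals, a0, a1, bin, z_cut, smooth_run,
                         edge, smooth_order)
    if (!is.null(segs) && nrow(segs)) {
      segs <- cbind(contig = ct, segs, source = "bulk",
                    stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- segs
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(contig = character(), start = numeric(), end = numeric(),
               mean_z = numeric(), n_bins = integer(), source = character())
  rownames(res) <- NULL
  res
}

#' Call CDRs along single molecules
#'
#' Applies the bulk algorithm per read: each molecule's CpG calls are binned
#' on the array grid, z-scored against the read's own bins, smoothed, and
#' edge-filtered against the array ends. Reads spanning fewer than 2 bins,
#' or with zero internal contrast (SD 0 — e.g. a read entirely inside a
#' dip), are skipped.
#'
#' @param molecules Long data.frame (`read_id`, `contig`, `pos`, `meth`) of
#'   binary per-CpG calls.
#' @param arrays Array intervals.
#' @inheritParams call_bulk_cdrs
#' @return data.frame of per-molecule CDR calls (`source =
#'   "molecule:<read id>"`).
#' @export
call_molecule_cdrs <- function(molecules, arrays, bin = 1000, z_cut = -1.5,
                               smooth_run = 5000, edge = 50000,
                               smooth_order = "low_first") {
  out <- list()
  for (i in seq_len(nrow(arrays))) {
    a0 <- arrays$start[i]; a1 <- arrays$end[i]; ct <- arrays$contig[i]
    mm <- molecules[molecules$contig == ct & molecules$pos >= a0 &
                      molecules$pos < a1, , drop = FALSE]
    if (nrow(mm) == 0) next
    for (rid in unique(mm$read_id)) {
      r <- mm[mm$read_id == rid, , drop = FALSE]
      g <- floor((r$pos - a0) / bin)
      agg <- tapply(r$meth, g, mean)
      if (length(agg) < 2) next
      gi <- as.integer(names(agg))
      # fill the read's spanned grid contiguously (bins with no CpG stay NA)
      grid <- min(gi):max(gi)
      vals <- rep(NA_real_, length(grid))
      vals[match(gi, grid)] <- as.numeric(agg)
      bs <- a0 + grid * bin
      be <- pmin(bs + bin, a1)
      segs <- call_cdr_one(bs, be, vals, a0, a1, bin, z_cut, smooth_run,
                           edge, smooth_order)
      if (!is.null(segs) && nrow(segs)) {
        segs <- cbind(contig = ct, segs,
                      source = paste0("molecule:", rid),
                      stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(contig = character(), start = numeric(), end = numeric(),
               mean_z = numeric(), n_bins = integer(), source = character())
  rownames(res) <- NULL
  res
}

#' Write per-molecule CDR calls as BED12
#'
#' One BED12 record per molecule: the record spans the read extent and the
#' blocks are that molecule's CDR segments.
#'
#' @param calls Output of [call_molecule_cdrs()].
#' @param molecules The molecule records the calls were derived from.
#' @param path Output path.
#' @export
write_molecule_cdrs_bed12 <- function(calls, molecules, path) {
  rows <- list()
  for (src in unique(calls$source)) {
    rid <- sub("^molecule:", "", src)
    cc <- calls[calls$source == src, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    mm <- molecules[molecules$read_id == rid, , drop = FALSE]
    rs <- min(mm$pos); re <- max(mm$pos) + 1
    rows[[length(rows) + 1L]] <- data.frame(
      contig = cc$contig[1], start = rs, end = re, name = rid, score = 0,
      strand = ".", thickStart = rs, thickEnd = re, itemRgb = "0,0,0",
      blockCount = nrow(cc),
      blockSizes = paste(cc$end - cc$start, collapse = ","),
      blockStarts = paste(cc$start - rs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  write_bed(do.call(rbind, rows), path)
}

#' Center of mass of a chromosome's CDRs
#'
#' Size-weighted average of the CDR midpoints.
#'
#' @param cdrs CDR calls for one chromosome.
#' @return Position in bp (NA if no CDRs).
#' @export
cdr_center_of_mass <- function(cdrs) {
  if (nrow(cdrs) == 0) return(NA_real_)
  w <- cdrs$end - cdrs$start
  mid <- (cdrs$start + cdrs$end) / 2
  sum(mid * w) / sum(w)
}

#' Compare CDR sets between two samples
#'
#' Per-chromosome change in center of mass, total CDR bp, and CDR count,
#' plus cohort summaries: the fraction of chromosomes whose center of mass
#' shifted by more than `shift_threshold`, the mean size change, and the
#' median count change.
#'
#' @param normal_cdrs,tumor_cdrs CDR call data.frames.
#' @param shift_threshold Center-of-mass shift (bp) counting as moved.
#' @return List with `per_chrom` data.frame and `summary` list.
#' @export
compare_cdrs <- function(normal_cdrs, tumor_cdrs, shift_threshold = 1e5) {
  chroms <- union(unique(normal_cdrs$contig), unique(tumor_cdrs$contig))
  rows <- lapply(chroms, function(ct) {
    nn <- normal_cdrs[normal_cdrs$contig == ct, , drop = FALSE]
    tt <- tumor_cdrs[tumor_cdrs$contig == ct, , drop = FALSE]
    data.frame(
      contig = ct,
      delta_com = cdr_center_of_mass(tt) - cdr_center_of_mass(nn),
      delta_bp = sum(tt$end - tt$start) - sum(nn$end - nn$start),
      delta_count = nrow(tt) - nrow(nn),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows) %||%
    data.frame(contig = character(), delta_com = numeric(),
               delta_bp = numeric(), delta_count = integer())
  list(per_chrom = per,
       summary = list(
         fraction_shifted = if (nrow(per)) {
           mean(abs(per$delta_com) > shift_threshold, na.rm = TRUE)
         } else NA_real_,
         mean_size_change = if (nrow(per)) mean(per$delta_bp) else NA_real_,
         median_count_change = if (nrow(per)) {
           median(per$delta_count)
         } else NA_real_))
}
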