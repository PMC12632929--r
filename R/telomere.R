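# Telomere parsing, per-molecule length, consensus TVR profiles, and
# somatic restructuring detection.

CANONICAL_G <- "TTAGGG"
CANONICAL_C <- "CCCTAA"

count_motif <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

#' Assign the canonical strand motif of a telomere read
#'
#' Counts TTAGGG and CCCTAA occurrences; the motif with more instances is
#' the canonical motif. Ties yield NA (flagged).
#'
#' @param seq Character vector of read sequences.
#' @return Character vector in `{"TTAGGG", "CCCTAA", NA}`.
#' @export
assign_strand <- function(seq) {
  vapply(seq, function(s) {
    g <- count_motif(s, CANONICAL_G)
    c <- count_motif(s, CANONICAL_C)
    if (g > c) CANONICAL_G else if (c > g) CANONICAL_C else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Orient a read to the G-strand (telomere to the right of the junction).
canonicalize_read <- function(seq, boundary_offset) {
  strand <- assign_strand(seq)
  if (is.na(strand)) {
    return(list(seq = seq, boundary_offset = boundary_offset,
                flagged = TRUE))
  }
  if (strand == CANONICAL_C) {
    seq <- revcomp(seq)
    boundary_offset <- nchar(seq) - boundary_offset
  }
  list(seq = seq, boundary_offset = boundary_offset, flagged = FALSE)
}

#' Parse canonical repeats and TVRs in a telomere read
#'
#' Locates maximal tandem runs of at least `min_copies` exact copies of the
#' canonical hexamer in the telomeric portion of the read (distal to the
#' junction); every base not inside a canonical run is a telomere variant
#' repeat (TVR) base. The returned intervals tile the telomeric portion
#' exactly. Offsets are 0-based from the junction; the read is oriented to
#' the G-strand first, so a reverse-complemented read yields mirror-image
#' intervals at the same offsets.
#'
#' @param seq Read sequence.
#' @param boundary_offset Position of the subtelomere/telomere junction
#'   within the read (G-strand orientation).
#' @param min_copies Minimum tandem copies defining a canonical run
#'   (default 2; singleton hexamers inside degenerate sequence count as TVR
#'   context).
#' @return List with `canonical` and `tvr` interval data.frames (`start`,
#'   `end`, offsets from the junction) and `telomere_length`.
#' @export
parse_tvrs <- function(seq, boundary_offset, min_copies = 2) {
  cr <- canonicalize_read(seq, boundary_offset)
  telo <- substring(cr$seq, cr$boundary_offset + 1)
  tl <- nchar(telo)
  empty <- data.frame(start = integer(), end = integer())
  if (tl == 0) {
    return(list(canonical = empty, tvr = empty, telomere_length = 0L))
  }
  pat <- sprintf("(?:%s){%d,}", CANONICAL_G, min_copies)
  m <- gregexpr(pat, telo, perl = TRUE)[[1]]
  if (m[1] == -1) {
    canonical <- empty
    tvr <- data.frame(start = 0L, end = tl)
  } else {
    cs <- as.integer(m) - 1L
    ce <- cs + attr(m, "match.length")
    canonical <- data.frame(start = cs, end = ce)
    gaps_s <- c(0L, ce)
    gaps_e <- c(cs, tl)
    keep <- gaps_e > gaps_s
    tvr <- data.frame(start = gaps_s[keep], end = gaps_e[keep])
  }
  list(canonical = canonical, tvr = tvr, telomere_length = tl)
}

#' Telomere length of a read
#'
#' Number of read bases distal to the subtelomere/telomere junction.
#'
#' @param seq Read sequence (vector).
#' @param boundary_offset Junction offset within the read (vector, G-strand
#'   orientation as stored).
#' @return Integer vector of lengths in bp.
#' @export
telomere_length <- function(seq, boundary_offset) {
  stopifnot(length(seq) == length(boundary_offset))
  if (any(boundary_offset < 0 | boundary_offset > nchar(seq))) {
    stop("boundary_offset outside read")
  }
  mapply(function(s, b) {
    cr <- canonicalize_read(s, b)
    nchar(cr$seq) - cr$boundary_offset
  }, seq, boundary_offset, USE.NAMES = FALSE)
}

# mean over a centered window, using only in-range neighbours (no padding
# artifacts at the ends).
boxcar_smooth <- function(x, window = 25) {
  n <- length(x)
  if (n == 0 || window <= 1) return(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  tot <- cs[hi + 1] - cs[lo]
  cnt <- cn[hi + 1] - cn[lo]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

find_profile_peaks <- function(smoothed, min_peak_frac, min_peak_gap) {
  # plateau-tolerant peak pattern (boxcar smoothing produces flat tops)
  pk <- pracma::findpeaks(smoothed, minpeakheight = min_peak_frac,
                          minpeakdistance = min_peak_gap,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk)) {
    return(data.frame(offset = integer(), height = numeric()))
  }
  out <- data.frame(offset = as.integer(pk[, 2] - 1), height = pk[, 1])
  out[order(out$offset), , drop = FALSE]
}

#' Consensus TVR profile of one telomere
#'
#' For each offset from the junction, the fraction of covering reads whose
#' base at that offset lies in a TVR interval; smoothed with a boxcar
#' window, with peaks called as local maxima of the smoothed profile above
#' `min_peak_frac` separated by at least `min_peak_gap` bp.
#'
#' @param reads data.frame with `sequence` and `boundary_offset` for the
#'   reads of one telomere in one sample.
#' @param smooth_window Boxcar width in bp (default 25).
#' @param min_peak_frac Minimum smoothed TVR fraction of a peak.
#' @param min_peak_gap Minimum distance between peaks in bp.
#' @param min_copies Passed to [parse_tvrs()].
#' @return A `tvr_profile`: list with `fraction`, `smoothed`, `coverage`,
#'   `peaks` (data.frame `offset`, `height`) and `n_reads`.
#' @export
consensus_tvr_profile <- function(reads, smooth_window = 25,
                                  min_peak_frac = 0.25, min_peak_gap = 50,
                                  min_copies = 2) {
  if (nrow(reads) == 0) stop("no reads for this telomere")
  parsed <- lapply(seq_len(nrow(reads)), function(i) {
    parse_tvrs(reads$sequence[i], reads$boundary_offset[i], min_copies)
  })
  maxlen <- max(vapply(parsed, `[[`, integer(1), "telomere_length"))
  if (maxlen == 0) stop("reads contain no telomeric sequence")
  tvr_sum <- numeric(maxlen)
  cov <- numeric(maxlen)
  for (p in parsed) {
    tl <- p$telomere_length
    if (tl == 0) next
    cov[1:tl] <- cov[1:tl] + 1
    v <- logical(tl)
    for (j in seq_len(nrow(p$tvr))) {
      v[(p$tvr$start[j] + 1):p$tvr$end[j]] <- TRUE
    }
    tvr_sum[1:tl] <- tvr_sum[1:tl] + v
  }
  frac <- ifelse(cov > 0, tvr_sum / cov, NA_real_)
  sm <- boxcar_smooth(frac, smooth_window)
  structure(list(fraction = frac, smoothed = sm, coverage = cov,
                 peaks = find_profile_peaks(sm, min_peak_frac,
                                            min_peak_gap),
                 n_reads = nrow(reads)),
            class = "tvr_profile")
}

#' Detect somatic telomere restructuring
#'
#' Matches TVR peaks between the normal and tumor profiles (within `tol`
#' bp). A telomere is restructured iff at least one normal-only peak lies
#' distal to a shared peak: the most proximal such lost peak is the distal
#' boundary (minimum chew-back), and the most distal shared peak proximal to
#' it is the proximal limit (maximum chew-back).
#'
#' @param profile_normal,profile_tumor [consensus_tvr_profile()] objects.
#' @param tol Peak matching tolerance in bp (default 50, twice the smoothing
#'   window).
#' @return List with `restructured`, `distal_boundary`, `proximal_limit`,
#'   and the `shared`, `normal_only`, `tumor_only` peak offsets.
#' @export
detect_restructuring <- function(profile_normal, profile_tumor, tol = 50) {
  pn <- profile_normal$peaks$offset
  pt <- profile_tumor$peaks$offset
  shared <- pn[vapply(pn, function(p) any(abs(pt - p) <= tol), logical(1))]
  normal_only <- setdiff(pn, shared)
  tumor_only <- pt[!vapply(pt, function(p) any(abs(pn - p) <= tol),
                           logical(1))]
  res <- list(restructured = FALSE, distal_boundary = NA_real_,
              proximal_limit = NA_real_, shared = shared,
              normal_only = normal_only, tumor_only = tumor_only)
  if (length(shared) == 0 || length(normal_only) == 0) return(res)
  cand <- normal_only[normal_only > min(shared)]
  if (length(cand) == 0) return(res)
  res$restructured <- TRUE
  res$distal_boundary <- min(cand)
  res$proximal_limit <- max(shared[shared < res$distal_boundary])
  res
}

#' Summarize attrition and extension across restructured telomeres
#'
#' For each restructured telomere: the minimum retained length is the
#' proximal limit (the maximum chew-back bound), and the telomerase
#' extension is the mean tumor telomere length minus that limit. Negative
#' extensions are flagged as internal-deletion candidates. Telomeres without
#' restructuring are excluded.
#'
#' @param calls Named list of [detect_restructuring()] results per telomere.
#' @param tumor_lengths Named list/vector of tumor read telomere lengths per
#'   telomere (vectors are averaged).
#' @return data.frame (`telomere`, `min_retained`, `extension`,
#'   `internal_deletion`).
#' @export
summarize_attrition_extension <- function(calls, tumor_lengths) {
  rows <- list()
  for (nm in names(calls)) {
    r <- calls[[nm]]
    if (!isTRUE(r$restructured)) next
    mt <- mean(unlist(tumor_lengths[[nm]]))
    ext <- mt - r$proximal_limit
    rows[[length(rows) + 1L]] <- data.frame(
      telomere = nm, min_retained = r$proximal_limit, extension = ext,
      internal_deletion = ext < 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||%
    data.frame(telomere = character(), min_retained = numeric(),
               extension = numeric(), internal_deletion = logical())
}
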