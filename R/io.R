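# Readers/writers and interval arithmetic shared by all stages.
#
# All internal coordinates are 0-based half-open (BED semantics). The VCF
# 1-based boundary is handled only at (de)serialization: a VCF POS p maps to
# internal start p - 1.

#' Read a FASTA file
#'
#' @param path Path to a (optionally faidx-indexed) FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write contig sequences to FASTA
#'
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(contigs, path) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), path,
                              width = 80L)
  invisible(path)
}

bed_check <- function(df) {
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("malformed interval (need 0 <= start < end) at record ", bad[1])
  }
  invisible(df)
}

#' Read a BED file (BED3/BED6/BED12)
#'
#' Columns beyond the first three are kept under their BED names
#' (`name`, `score`, `strand`, ...). Coordinates stay 0-based half-open.
#'
#' @param path Path to a tab-separated BED file.
#' @return data.frame with columns `contig`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`, `thickStart`, `thickEnd`, `itemRgb`,
#'   `blockCount`, `blockSizes`, `blockStarts`.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e))
  )
  cols <- c("contig", "start", "end", "name", "score", "strand",
            "thickStart", "thickEnd", "itemRgb", "blockCount",
            "blockSizes", "blockStarts")
  names(df) <- cols[seq_len(ncol(df))]
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("malformed BED file '", path, "': non-numeric coordinates")
  }
  bed_check(df)
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with `contig`, `start`, `end` and optional further
#'   BED columns (written in order).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  bed_check(df)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a bedGraph (contig, start, end, value).
#' @return data.frame with columns `contig`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) != 4L) stop("bedGraph '", path, "' must have 4 columns")
  names(df) <- c("contig", "start", "end", "value")
  bed_check(df)
  df
}

#' Write a bedGraph file
#' @param df data.frame with `contig`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  write_bed(df[, c("contig", "start", "end", "value")], path)
}

# ---- VCF --------------------------------------------------------------------

#' Write somatic calls as VCF 4.2
#'
#' Serializes the internal call table with FORMAT fields `GT:DP:AD:PS` for the
#' TUMOR and NORMAL samples. The haplotype assignment is encoded in the tumor
#' GT (`1|0` hap1, `0|1` hap2, `./.` unassigned).
#'
#' @param calls Call data.frame (see [simulate_ssnvs()] for the columns).
#' @param path Output path.
#' @param contig_lengths Optional named vector for `##contig` header lines.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=somaT2T",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t")
  )
  n <- nrow(calls)
  gt <- rep("./.", n)
  gt[!is.na(calls$haplotype) & calls$haplotype == 1] <- "1|0"
  gt[!is.na(calls$haplotype) & calls$haplotype == 2] <- "0|1"
  ps <- if ("phase_set" %in% names(calls)) calls$phase_set else rep(NA, n)
  ps_chr <- ifelse(is.na(ps), ".", as.character(ps))
  tum <- sprintf("%s:%d:%d,%d:%s", gt, as.integer(calls$depth_tumor),
                 as.integer(calls$depth_tumor - calls$alt_depth_tumor),
                 as.integer(calls$alt_depth_tumor), ps_chr)
  nor <- sprintf("0|0:%d:%d,%d:.", as.integer(calls$depth_normal),
                 as.integer(calls$depth_normal - calls$alt_depth_normal),
                 as.integer(calls$alt_depth_normal))
  flt <- if ("filter" %in% names(calls)) {
    ifelse(is.na(calls$filter) | calls$filter == "", "PASS", calls$filter)
  } else rep("PASS", n)
  rec <- paste(calls$contig, as.integer(calls$pos), ".", calls$ref, calls$alt,
               ".", flt, ".", "GT:DP:AD:PS", tum, nor, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a somatic call VCF
#'
#' Parses a VCF written by [write_vcf()] (or any VCF with TUMOR/NORMAL samples
#' carrying `GT:DP:AD` FORMAT fields) back into the internal call table.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Call data.frame with 1-based `pos`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      haplotype = integer(), depth_tumor = integer(),
                      alt_depth_tumor = integer(), depth_normal = integer(),
                      alt_depth_normal = integer(), vaf = numeric(),
                      phase_set = integer(), filter = character()))
  }
  samp <- colnames(v@gt)[-1]
  if (!all(c("TUMOR", "NORMAL") %in% samp)) {
    stop("VCF '", path, "' must contain TUMOR and NORMAL samples")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  ps <- suppressWarnings(vcfR::extract.gt(v, element = "PS",
                                          as.numeric = TRUE))
  alt_of <- function(ad_col) {
    as.integer(vapply(strsplit(ad_col, ","), function(z) z[2], ""))
  }
  hap <- ifelse(gt[, "TUMOR"] == "1|0", 1L,
                ifelse(gt[, "TUMOR"] == "0|1", 2L, NA_integer_))
  dpt <- as.integer(dp[, "TUMOR"])
  adt <- alt_of(ad[, "TUMOR"])
  out <- data.frame(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    haplotype = unname(hap),
    depth_tumor = unname(dpt),
    alt_depth_tumor = unname(adt),
    depth_normal = unname(as.integer(dp[, "NORMAL"])),
    alt_depth_normal = unname(alt_of(ad[, "NORMAL"])),
    vaf = unname(ifelse(dpt > 0, adt / dpt, NA_real_)),
    phase_set = unname(as.integer(ps[, "TUMOR"])),
    filter = fix$FILTER,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# ---- interval arithmetic ----------------------------------------------------

intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_to_intervals <- function(gr, label = NULL) {
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- label
  df
}

#' Merge intervals closer than a gap
#'
#' Fuses intervals on the same contig whose gap is `<= max_gap` bp; output is
#' disjoint and sorted. Idempotent.
#'
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param max_gap Maximum gap (bp) across which adjacent intervals are fused.
#' @return Merged intervals data.frame.
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  if (nrow(intervals) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  bed_check(intervals)
  gr <- GenomicRanges::reduce(intervals_to_gr(intervals),
                              min.gapwidth = max_gap + 1)
  out <- gr_to_intervals(GenomicRanges::sort(gr))
  rownames(out) <- NULL
  out
}

# Internal: for point positions (0-based), index of covering interval row
# (first hit in df order), NA if none.
point_in_intervals <- function(contig, pos0, intervals) {
  if (nrow(intervals) == 0) return(rep(NA_integer_, length(pos0)))
  pts <- GenomicRanges::GRanges(contig,
                                IRanges::IRanges(pos0 + 1, pos0 + 1))
  hits <- GenomicRanges::findOverlaps(pts, intervals_to_gr(intervals),
                                      select = "first")
  as.integer(hits)
}
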