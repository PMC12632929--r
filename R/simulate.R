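# Generators for somatic calls, coverage, methylation and telomere reads.

# Internal: total spectrum mass per trinucleotide (64 entries, purine-centered
# contexts inherit their reverse complement's mass). Used to weight mutation
# POSITIONS so the realized spectrum reflects the configured process rather
# than raw context availability.
kmer_mass_table <- function(weights) {
  cls <- sbs96_classes()
  km <- sbs96_kmer()
  mass32 <- tapply(weights[cls], km[cls], sum)
  # order must match the 2-bit index 16*c1 + 4*c2 + c3 (c3 fastest)
  eg <- expand.grid(c3 = BASES, c2 = BASES, c1 = BASES,
                    stringsAsFactors = FALSE)
  kmers64 <- paste0(eg$c1, eg$c2, eg$c3)
  out <- setNames(numeric(64), kmers64)
  for (k in kmers64) {
    key <- if (substr(k, 2, 2) %in% c("A", "G")) revcomp(k) else k
    out[k] <- mass32[[key]]
  }
  out
}

# Per-position context mass for 0-based positions lo .. hi_excl - 1 of a
# contig (positions must have both neighbours in the contig), vectorized via
# 2-bit base codes. Element i corresponds to position lo - 1 + i.
site_context_mass <- function(seq, lo, hi_excl, mass64) {
  sub <- substring(seq, lo, hi_excl + 1)
  code <- utf8ToInt(chartr("ACGT", "\001\002\003\004", sub)) - 1L
  n <- length(code)
  if (n < 3) return(numeric(0))
  idx <- 16L * code[1:(n - 2)] + 4L * code[2:(n - 1)] + code[3:n] + 1L
  unname(mass64[idx])
}

# Internal: draw alternate alleles conditioned on the reference trinucleotide,
# with substitution-type probabilities from the SBS-96 spectrum weights.
draw_alts <- function(contexts, weights) {
  n <- length(contexts)
  alts <- character(n)
  refs <- substr(contexts, 2, 2)
  canon <- contexts
  flip <- refs %in% c("A", "G")
  if (any(flip)) canon[flip] <- revcomp(contexts[flip])
  cref <- substr(canon, 2, 2)
  other <- list(C = c("A", "G", "T"), T = c("A", "C", "G"))
  for (i in seq_len(n)) {
    cands <- other[[cref[i]]]
    cls <- sprintf("%s[%s>%s]%s", substr(canon[i], 1, 1), cref[i], cands,
                   substr(canon[i], 3, 3))
    w <- weights[cls]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) w <- rep(1, 3)
    a <- sample(cands, 1, prob = w)
    alts[i] <- if (flip[i]) revcomp(a) else a
  }
  alts
}

#' Simulate somatic SNV calls
#'
#' Per-base Bernoulli draws at each annotation block's class rate; the
#' substitution type is drawn from the configured SBS-96 spectrum conditioned
#' on the reference trinucleotide. Under the default fully clonal model every
#' call is fixed (VAF 1) on a randomly assigned haplotype; tumor depths are
#' Poisson at the haploid (1n) coverage. Normal-sample alt evidence is zero
#' except for a configurable contamination fraction of calls which receive a
#' planted alt depth.
#'
#' @param genome An [generate_genome()] result.
#' @param config A [sim_config()]; `class_rates` must cover every annotated
#'   class.
#' @return List with `calls` (one row per somatic call) and `normal_pileup`
#'   (per-site normal read support).
#' @export
simulate_ssnvs <- function(genome, config) {
  stopifnot(inherits(genome, "annotated_genome"))
  ann <- genome$annotations
  missing_cls <- setdiff(unique(ann$class), names(config$class_rates))
  if (length(missing_cls)) {
    stop("class_rates missing for class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  with_substream(config$seed, 2L, {
    mass64 <- kmer_mass_table(config$spectrum_weights)
    pos_list <- vector("list", nrow(ann))
    for (i in seq_len(nrow(ann))) {
      wd <- ann$end[i] - ann$start[i]
      rate <- config$class_rates[[ann$class[i]]]
      nmut <- rbinom(1, wd, rate)
      if (nmut > 0) {
        seq_i <- genome$contigs[[ann$contig[i]]]
        # positions with both flanking bases inside the contig
        lo <- max(ann$start[i], 1L)
        hi <- min(ann$end[i], nchar(seq_i) - 1L)
        if (hi <= lo) next
        mass <- site_context_mass(seq_i, lo, hi, mass64)
        # mutable positions drawn proportionally to their context's spectrum
        # mass (alias sampling; duplicate draws collapse, negligible at the
        # simulated rates)
        idx <- unique(sample.int(length(mass), nmut, replace = TRUE,
                                 prob = mass))
        pos_list[[i]] <- data.frame(
          contig = ann$contig[i],
          pos0 = sort(lo - 1L + idx),
          class = ann$class[i], stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, pos_list)
    if (is.null(df) || nrow(df) == 0) {
      empty <- data.frame(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          haplotype = integer(), depth_tumor = integer(),
                          alt_depth_tumor = integer(),
                          depth_normal = integer(),
                          alt_depth_normal = integer(), vaf = numeric(),
                          phase_set = integer(), class = character(),
                          stringsAsFactors = FALSE)
      return(list(calls = empty,
                  normal_pileup = empty[c("contig", "pos")]))
    }
    seqs <- genome$contigs[df$contig]
    # interior positions only: context needs both neighbours
    clen <- nchar(genome$contigs)[match(df$contig, names(genome$contigs))]
    keep <- df$pos0 > 0 & df$pos0 < clen - 1
    df <- df[keep, , drop = FALSE]
    seqs <- seqs[keep]
    ctx <- substring(seqs, df$pos0, df$pos0 + 2)
    ref <- substr(ctx, 2, 2)
    alt <- draw_alts(ctx, config$spectrum_weights)
    n <- nrow(df)
    hap <- sample(1:2, n, replace = TRUE)
    dpt <- rpois(n, config$depth_1n_tumor)
    dpt[dpt == 0] <- 1L
    if (config$clonality == "clonal") {
      vaf_true <- rep(1, n)
    } else {
      sub <- runif(n) < config$subclonal_fraction
      vaf_true <- ifelse(sub, config$subclonal_vaf, 1)
    }
    adt <- rbinom(n, dpt, vaf_true)
    adt[vaf_true == 1] <- dpt[vaf_true == 1]
    dpn <- rpois(n, config$depth_normal)
    adn <- integer(n)
    contam <- runif(n) < config$contamination_fraction
    adn[contam] <- pmin(config$contamination_alt_depth, dpn[contam])
    calls <- data.frame(
      contig = df$contig, pos = df$pos0 + 1L, ref = ref, alt = alt,
      haplotype = hap, depth_tumor = dpt, alt_depth_tumor = adt,
      depth_normal = dpn, alt_depth_normal = adn,
      vaf = adt / dpt, phase_set = NA_integer_, class = df$class,
      stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    list(calls = calls,
         normal_pileup = calls[, c("contig", "pos", "depth_normal",
                                   "alt_depth_normal")])
  })
}

#' Simulate paired coverage windows
#'
#' Normal windows are Poisson at `depth_normal`; tumor windows are Poisson at
#' `hCN x depth_1n_tumor` with the hCN state taken from the configured
#' karyotype at the window midpoint.
#'
#' @param genome An [generate_genome()] result.
#' @param config A [sim_config()]; its karyotype must cover the genome.
#' @return List with `normal` and `tumor` coverage data.frames (`contig`,
#'   `start`, `end`, `depth`).
#' @export
simulate_coverage <- function(genome, config) {
  with_substream(config$seed, 3L, {
    L <- nchar(genome$contigs[[1]])
    contig <- names(genome$contigs)[1]
    ws <- config$window_size
    starts <- seq(0L, L - 1L, by = ws)
    ends <- pmin(starts + ws, L)
    mids <- (starts + ends) / 2
    kar <- config$karyotype
    idx <- findInterval(mids, kar$start)
    state <- kar$state[idx]
    mult <- ifelse(state %in% c("DEL", "0"), 0,
                   ifelse(state == "amp", 5, as.numeric(state)))
    tumor_depth <- rpois(length(starts), mult * config$depth_1n_tumor)
    normal_depth <- rpois(length(starts), config$depth_normal)
    mk <- function(d) data.frame(contig = contig, start = starts, end = ends,
                                 depth = d, stringsAsFactors = FALSE)
    list(normal = mk(normal_depth), tumor = mk(tumor_depth))
  })
}

default_cdr_spec <- function(genome, min_array = 2e5, dip_len = 6e4) {
  ann <- genome$annotations
  arr <- ann[ann$class == "alpha-satellite" &
               (ann$end - ann$start) >= min_array, , drop = FALSE]
  lapply(seq_len(nrow(arr)), function(i) {
    mid <- floor((arr$start[i] + arr$end[i]) / 2)
    list(array = c(arr$start[i], arr$end[i]),
         dips = list(c(mid - dip_len / 2, mid + dip_len / 2)))
  })
}

#' Simulate a CpG methylation track and single molecules
#'
#' The bulk track carries a high baseline methylation fraction with Gaussian
#' noise, and planted dips (lower mean) inside alpha-satellite arrays — the
#' structure a centromere dip region (CDR) caller assumes. Per-molecule
#' records are reads of configurable length carrying binary CpG calls drawn
#' from the local mean.
#'
#' @param genome An [generate_genome()] result.
#' @param config A [sim_config()]. If `config$cdr_spec` is `NULL`, one 60 kb
#'   central dip is planted per alpha-satellite array of at least 200 kb.
#' @param cdr_spec Override for `config$cdr_spec`; a list of
#'   `list(array = c(start, end), dips = list(c(start, end), ...))` entries.
#' @return List with `bulk` (bedGraph-style data.frame), `molecules` (long
#'   data.frame `read_id`, `contig`, `pos`, `meth`) and `arrays` (the array
#'   intervals used).
#' @export
simulate_methylation <- function(genome, config, cdr_spec = NULL) {
  spec <- cdr_spec %||% config$cdr_spec %||% default_cdr_spec(genome)
  contig <- names(genome$contigs)[1]
  with_substream(config$seed, 4L, {
    bin <- config$meth_bin
    bulk_list <- list()
    mol_list <- list()
    arrays <- data.frame(contig = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    rid <- 0L
    for (sp in spec) {
      a0 <- sp$array[1]; a1 <- sp$array[2]
      arrays <- rbind(arrays, data.frame(contig = contig, start = a0,
                                         end = a1))
      starts <- seq(a0, a1 - 1, by = bin)
      ends <- pmin(starts + bin, a1)
      mids <- (starts + ends) / 2
      mu <- rep(config$meth_baseline, length(starts))
      for (d in sp$dips) mu[mids >= d[1] & mids < d[2]] <- config$meth_dip_level
      val <- pmin(1, pmax(0, rnorm(length(mu), mu, config$meth_sd)))
      bulk_list[[length(bulk_list) + 1L]] <-
        data.frame(contig = contig, start = as.integer(starts),
                   end = as.integer(ends), value = val,
                   stringsAsFactors = FALSE)
      # molecules: CpG-like sites every 100 bp, binary calls at the local mean
      n_mol <- max(1L, round(config$molecule_coverage * (a1 - a0) /
                               config$molecule_length))
      for (m in seq_len(n_mol)) {
        rid <- rid + 1L
        rs <- a0 + floor(runif(1) * max(1, (a1 - a0 - config$molecule_length)))
        re <- min(a1, rs + config$molecule_length)
        sites <- seq(rs, re - 1, by = 100)
        smu <- rep(config$meth_baseline, length(sites))
        for (d in sp$dips) smu[sites >= d[1] & sites < d[2]] <-
            config$meth_dip_level
        mol_list[[length(mol_list) + 1L]] <-
          data.frame(read_id = sprintf("mol%05d", rid), contig = contig,
                     pos = as.integer(sites),
                     meth = rbinom(length(sites), 1, smu),
                     stringsAsFactors = FALSE)
      }
    }
    list(bulk = do.call(rbind, bulk_list) %||%
           data.frame(contig = character(), start = integer(),
                      end = integer(), value = numeric()),
         molecules = do.call(rbind, mol_list) %||%
           data.frame(read_id = character(), contig = character(),
                      pos = integer(), meth = integer()),
         arrays = arrays)
  })
}

build_telomere_seq <- function(total_len, tvr_offsets, tvr_motif,
                               canonical = "TTAGGG") {
  nrep <- ceiling(total_len / 6)
  bases <- strsplit(strrep(canonical, nrep), "")[[1]][seq_len(total_len)]
  mlen <- nchar(tvr_motif)
  for (off in tvr_offsets) {
    if (off + mlen <= total_len) {
      bases[(off + 1):(off + mlen)] <- strsplit(tvr_motif, "")[[1]]
    }
  }
  paste(bases, collapse = "")
}

#' Simulate telomere-spanning reads for two samples
#'
#' Normal-sample reads carry the planted TVR layout (non-TTAGGG hexamers at
#' fixed offsets from the subtelomere/telomere junction). For restructured
#' telomeres, tumor reads reproduce the proximal layout up to the planted
#' attrition point, replace distal TVRs with canonical repeats, and extend by
#' the planted length. Half of the reads are stored reverse-complemented
#' (C-strand) to exercise strand assignment. Sequencing noise is i.i.d.
#' substitution at `telomere_noise_rate`.
#'
#' @param config A [sim_config()] with a `telomere_spec`.
#' @return data.frame with `read_id`, `telomere`, `sample`, `tech`,
#'   `sequence`, `boundary_offset` (position of the junction within the read,
#'   G-strand orientation measured from the read start).
#' @export
simulate_telomeres <- function(config) {
  with_substream(config$seed, 5L, {
    out <- list()
    for (sp in config$telomere_spec) {
      sub_len <- 300L
      subtel <- random_dna(sub_len)
      norm_tel <- build_telomere_seq(sp$length_normal, sp$tvr_offsets,
                                     sp$tvr_motif)
      if (isTRUE(sp$restructured)) {
        keep <- sp$tvr_offsets[sp$tvr_offsets + nchar(sp$tvr_motif) <=
                                 sp$attrition_bp]
        tum_len <- sp$attrition_bp + sp$extension_bp
        tum_tel <- build_telomere_seq(tum_len, keep, sp$tvr_motif)
      } else {
        tum_tel <- norm_tel
      }
      for (smp in c("normal", "tumor")) {
        tel <- if (smp == "normal") norm_tel else tum_tel
        full <- paste0(subtel, tel)
        for (r in seq_len(sp$n_reads)) {
          sq <- full
          nerr <- rbinom(1, nchar(sq), config$telomere_noise_rate)
          if (nerr > 0) {
            pos <- sample.int(nchar(sq), nerr)
            ch <- strsplit(sq, "")[[1]]
            ch[pos] <- sample(c("A", "C", "G", "T"), nerr, replace = TRUE)
            sq <- paste(ch, collapse = "")
          }
          rc <- runif(1) < 0.5
          bo <- sub_len
          if (rc) {
            sq <- revcomp(sq)
            bo <- nchar(sq) - sub_len  # junction in stored orientation
          }
          out[[length(out) + 1L]] <- data.frame(
            read_id = sprintf("%s_%s_r%03d", sp$name, smp, r),
            telomere = sp$name, sample = smp, tech = "ont",
            sequence = sq, boundary_offset = bo,
            stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate haplotype-resolved accessibility peaks
#'
#' Generates per-peak accessible/total fiber counts for both haplotypes, with
#' an additive copy-number expectation: each haplotype's total fiber count is
#' Poisson at `fibers_per_copy x hCN`, and accessibility is binomial at a
#' per-peak actuation rate shared between haplotypes except for a planted set
#' of haplotype-selective peaks.
#'
#' @param segments Classified hCN segments (see [classify_segments()]) giving
#'   haplotype-1 copy states along the genome; haplotype 2 is held at hCN 1.
#' @param config A [sim_config()].
#' @param n_peaks Number of peaks to place uniformly over the segments.
#' @param n_selective Number of planted haplotype-selective peaks.
#' @param fibers_per_copy Mean fiber count per haploid copy.
#' @param selective_shift Actuation-rate drop applied to haplotype 1 of
#'   planted selective peaks.
#' @return data.frame of peaks with per-haplotype counts, local hCN, and
#'   planted-truth column `planted_selective`.
#' @export
simulate_peaks <- function(segments, config, n_peaks = 200,
                           n_selective = 10, fibers_per_copy = 30,
                           selective_shift = 0.5) {
  with_substream(config$seed, 6L, {
    tot_bp <- sum(segments$end - segments$start)
    off <- floor(runif(n_peaks) * tot_bp)
    cum <- cumsum(segments$end - segments$start)
    seg_idx <- findInterval(off, c(0, head(cum, -1)), left.open = FALSE)
    seg_idx <- pmax(1L, pmin(nrow(segments), seg_idx))
    pos <- segments$start[seg_idx] + (off - c(0, head(cum, -1))[seg_idx])
    state <- segments$state[seg_idx]
    hcn1 <- ifelse(state %in% c("DEL", "0"), 0,
                   ifelse(state == "amp", 5,
                          suppressWarnings(as.numeric(state))))
    hcn2 <- rep(1, n_peaks)
    base_rate <- runif(n_peaks, 0.2, 0.8)
    rate1 <- base_rate
    sel <- rep(FALSE, n_peaks)
    sel[sample.int(n_peaks, min(n_selective, n_peaks))] <- TRUE
    rate1[sel] <- pmax(0.02, base_rate[sel] * (1 - selective_shift))
    tot1 <- rpois(n_peaks, fibers_per_copy * hcn1)
    tot2 <- rpois(n_peaks, fibers_per_copy * hcn2)
    acc1 <- rbinom(n_peaks, tot1, rate1)
    acc2 <- rbinom(n_peaks, tot2, base_rate)
    data.frame(
      contig = segments$contig[seg_idx],
      start = as.integer(pos), end = as.integer(pos + 200),
      acc_hap1 = acc1, total_hap1 = tot1,
      acc_hap2 = acc2, total_hap2 = tot2,
      hcn_hap1 = hcn1, hcn_hap2 = hcn2,
      n_somatic_variants = 0L, n_germline_hets = 0L,
      imprinted = FALSE, planted_selective = sel,
      stringsAsFactors = FALSE)
  })
}
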