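# SBS-96 / DBS-78 spectra, 3-mer normalization, predicted mutability, NNLS
# signature fitting, AMSD.

BASES <- c("A", "C", "G", "T")

#' SBS-96 class labels
#'
#' Fixed class order: substitution types C>A, C>G, C>T, T>A, T>C, T>G, each
#' expanded over 5' then 3' flanking base (A, C, G, T) — the conventional
#' pyrimidine-centered 96-class order used by signature catalogues.
#'
#' @return Character vector of 96 labels like `"T[C>T]A"`.
#' @export
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (f in BASES) for (t in BASES) {
    out <- c(out, sprintf("%s[%s]%s", f, s, t))
  }
  out
}

#' Canonical pyrimidine-centered 3-mers
#' @return Character vector of the 32 canonical trinucleotides.
#' @export
canonical_kmers <- function() {
  out <- character(0)
  for (f in BASES) for (c in c("C", "T")) for (t in BASES) {
    out <- c(out, paste0(f, c, t))
  }
  out
}

#' 3-mer of each SBS-96 class
#' @return Named character vector mapping class label to its canonical 3-mer.
#' @export
sbs96_kmer <- function() {
  cls <- sbs96_classes()
  setNames(paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7)),
           cls)
}

#' Classify substitutions into SBS-96 classes
#'
#' If the reference base is a purine, the trinucleotide and substitution are
#' reverse-complemented so that every class is pyrimidine-centered; a call
#' and its reverse-complement representation therefore map to the same
#' class.
#'
#' @param ref,alt Single reference/alternate bases (vectors).
#' @param context Reference trinucleotide centered on the variant (vector).
#' @return Character vector of SBS-96 class labels.
#' @export
classify_sbs96 <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  if (any(ref == alt)) stop("ref == alt at record ",
                            which(ref == alt)[1])
  if (any(substr(context, 2, 2) != ref)) {
    stop("context center does not match ref at record ",
         which(substr(context, 2, 2) != ref)[1])
  }
  flip <- ref %in% c("A", "G")
  ctx <- context; a <- alt
  if (any(flip)) {
    ctx[flip] <- revcomp(context[flip])
    a[flip] <- revcomp(alt[flip])
  }
  sprintf("%s[%s>%s]%s", substr(ctx, 1, 1), substr(ctx, 2, 2), a,
          substr(ctx, 3, 3))
}

#' Classify SNV calls against a genome
#'
#' Looks up each call's trinucleotide context in the genome and classifies
#' it with [classify_sbs96()]. Calls at contig edges (no flanking base) are
#' dropped with a warning.
#'
#' @param calls Call data.frame (`contig`, 1-based `pos`, `ref`, `alt`).
#' @param genome An `annotated_genome` (or list with `contigs`).
#' @return Character vector of class labels (one per retained call).
#' @export
classify_calls_sbs96 <- function(calls, genome) {
  if (nrow(calls) == 0) return(character(0))
  clen <- nchar(genome$contigs)[match(calls$contig, names(genome$contigs))]
  edge <- calls$pos <= 1 | calls$pos >= clen
  if (any(edge)) {
    warning(sum(edge), " call(s) at contig edges dropped from spectrum")
    calls <- calls[!edge, , drop = FALSE]
  }
  ctx <- substring(genome$contigs[calls$contig], calls$pos - 1,
                   calls$pos + 1)
  classify_sbs96(calls$ref, calls$alt, unname(ctx))
}

#' DBS-78 class labels
#'
#' The 78 canonical doublet substitution classes: reference doublets
#' AC, AT, CC, CG, CT, GC, TA, TC, TG, TT, each with the alternate doublets
#' differing at both positions, collapsed by reverse complement for the
#' palindromic references.
#'
#' @return Character vector of 78 labels like `"CC>TT"`.
#' @export
dbs78_classes <- function() {
  refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  palin <- c("AT", "CG", "GC", "TA")
  out <- character(0)
  for (r in refs) {
    r1 <- substr(r, 1, 1); r2 <- substr(r, 2, 2)
    alts <- as.vector(outer(setdiff(BASES, r1), setdiff(BASES, r2),
                            paste0))
    if (r %in% palin) {
      alts <- unique(vapply(alts, function(a) min(a, revcomp(a)), ""))
    }
    out <- c(out, paste0(r, ">", sort(alts)))
  }
  out
}

#' Classify doublet substitutions into DBS-78 classes
#'
#' @param ref,alt Two-base reference/alternate doublets (vectors); both
#'   positions must differ.
#' @return Character vector of DBS-78 class labels.
#' @export
classify_dbs78 <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(nchar(ref) != 2 | nchar(alt) != 2)) stop("doublets must be 2 bp")
  if (any(substr(ref, 1, 1) == substr(alt, 1, 1) |
            substr(ref, 2, 2) == substr(alt, 2, 2))) {
    stop("a doublet substitution must differ at both positions")
  }
  refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  palin <- c("AT", "CG", "GC", "TA")
  flip <- !(ref %in% refs)
  r <- ref; a <- alt
  if (any(flip)) {
    r[flip] <- revcomp(ref[flip])
    a[flip] <- revcomp(alt[flip])
  }
  pal <- r %in% palin
  if (any(pal)) {
    a[pal] <- pmin(a[pal], vapply(a[pal], revcomp, ""))
  }
  paste0(r, ">", a)
}

#' Build SBS-96 and DBS-78 spectra
#'
#' @param snvs SNV call data.frame (may be empty).
#' @param dnvs DNV data.frame with 2 bp `ref`/`alt` (may be empty or NULL).
#' @param genome `annotated_genome` providing trinucleotide contexts.
#' @return List with `sbs96` and `dbs78` named count vectors.
#' @export
build_spectra <- function(snvs, dnvs = NULL, genome) {
  s96 <- setNames(numeric(96), sbs96_classes())
  if (!is.null(snvs) && nrow(snvs) > 0) {
    tab <- table(classify_calls_sbs96(snvs, genome))
    s96[names(tab)] <- as.numeric(tab)
  }
  d78 <- setNames(numeric(78), dbs78_classes())
  if (!is.null(dnvs) && nrow(dnvs) > 0) {
    tab <- table(classify_dbs78(dnvs$ref, dnvs$alt))
    d78[names(tab)] <- as.numeric(tab)
  }
  list(sbs96 = s96, dbs78 = d78)
}

#' Count canonical 3-mers in genomic regions
#'
#' Counts every overlapping trinucleotide of the (sub)sequences and collapses
#' purine-centered 3-mers onto their reverse complement, matching the
#' pyrimidine-centered class scheme (each double-stranded site counted
#' once).
#'
#' @param genome `annotated_genome` (or list with `contigs`).
#' @param regions Optional interval data.frame restricting the count;
#'   `NULL` counts the whole genome.
#' @return Named numeric vector over the 32 canonical 3-mers.
#' @export
count_kmers <- function(genome, regions = NULL) {
  seqs <- if (is.null(regions)) {
    Biostrings::DNAStringSet(unlist(genome$contigs))
  } else {
    bed_check(regions)
    Biostrings::DNAStringSet(substring(
      genome$contigs[regions$contig], regions$start + 1, regions$end))
  }
  m <- Biostrings::oligonucleotideFrequency(seqs, width = 3)
  cnt <- colSums(m)
  out <- setNames(numeric(32), canonical_kmers())
  for (k in names(cnt)) {
    key <- if (substr(k, 2, 2) %in% c("A", "G")) revcomp(k) else k
    if (key %in% names(out)) out[key] <- out[key] + cnt[[k]]
  }
  out
}

#' Region-specific 3-mer enrichment
#'
#' Ratio of each canonical 3-mer's frequency in a region set to its frequency
#' in a baseline (conventionally the non-repetitive genome).
#'
#' @param region_kmers,baseline_kmers Named 32-vectors from [count_kmers()].
#' @return Named 32-vector of enrichment ratios (NA where the baseline
#'   frequency is zero).
#' @export
kmer_enrichment <- function(region_kmers, baseline_kmers) {
  fr <- region_kmers / sum(region_kmers)
  fb <- baseline_kmers / sum(baseline_kmers)
  e <- fr / fb
  e[fb == 0] <- NA_real_
  e
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Normalize an SBS-96 spectrum by 3-mer frequencies
#'
#' Rescales each class count by the ratio of genome-wide to region-specific
#' frequency of its 3-mer, then applies a global scaling factor so the total
#' equals the input total, and rounds to integers (half away from zero).
#'
#' @param spec Named SBS-96 count vector.
#' @param region_kmers,genome_kmers Named 32-vectors from [count_kmers()].
#' @return Normalized integer count vector (same names and total, up to
#'   rounding).
#' @export
normalize_spectrum <- function(spec, region_kmers, genome_kmers) {
  stopifnot(length(spec) == 96)
  km <- sbs96_kmer()[names(spec)]
  fr <- region_kmers / sum(region_kmers)
  fg <- genome_kmers / sum(genome_kmers)
  zero <- fr[km] == 0 & spec > 0
  if (any(zero)) {
    stop("region 3-mer frequency is zero for class with nonzero count: ",
         names(spec)[zero][1])
  }
  fac <- fg[km] / fr[km]
  fac[!is.finite(fac)] <- 0
  adj <- spec * unname(fac)
  tot <- sum(spec)
  if (sum(adj) > 0) adj <- adj * tot / sum(adj)
  out <- round_half_away(adj)
  names(out) <- names(spec)
  out
}

#' Predicted mutability of a region
#'
#' The sum over the 96 classes of the reference spectrum fraction times the
#' region's 3-mer enrichment factor for that class's context: the expected
#' relative mutation rate of the region given its sequence composition.
#' Equals 1 under uniform enrichment.
#'
#' @param reference_spec_fractions SBS-96 fraction vector (sums to 1),
#'   conventionally the non-repeat spectrum.
#' @param enrichment Named 32-vector from [kmer_enrichment()].
#' @return Scalar predicted mutability.
#' @export
predicted_mutability <- function(reference_spec_fractions, enrichment) {
  stopifnot(length(reference_spec_fractions) == 96)
  km <- sbs96_kmer()[names(reference_spec_fractions) %||% sbs96_classes()]
  sum(reference_spec_fractions * unname(enrichment[km]))
}

#' Fit signature exposures by non-negative least squares
#'
#' `argmin_{x >= 0} || S x - spec ||_2` over a fixed column-stochastic
#' signature matrix, reporting raw exposures, contribution fractions, and the
#' cosine similarity between the reconstruction and the observed spectrum.
#'
#' @param spec Named SBS-96 count vector.
#' @param sigs 96 x S signature matrix with column sums 1 (within 1e-6).
#' @return List with `exposures`, `fractions`, `cosine`.
#' @export
fit_signatures_nnls <- function(spec, sigs) {
  stopifnot(nrow(sigs) == 96, length(spec) == 96)
  cs <- colSums(sigs)
  if (any(abs(cs - 1) > 1e-6)) stop("signature columns must sum to 1")
  if (sum(spec) == 0) {
    x <- setNames(numeric(ncol(sigs)), colnames(sigs))
    return(list(exposures = x, fractions = x, cosine = NA_real_))
  }
  x <- pracma::lsqnonneg(as.matrix(sigs), as.numeric(spec))$x
  names(x) <- colnames(sigs)
  recon <- as.numeric(as.matrix(sigs) %*% x)
  cosine <- sum(recon * spec) /
    (sqrt(sum(recon^2)) * sqrt(sum(spec^2)))
  list(exposures = x, fractions = x / sum(x), cosine = cosine)
}

#' Synthetic signature matrix
#'
#' A deterministic, column-stochastic 96 x 13 matrix of synthetic mutational
#' signatures under the conventional names of the melanoma-associated set.
#' The shapes are mechanism-inspired stand-ins (UV dipyrimidine C>T for the
#' 7a-d family, NpCpG C>T for the clock-like signature, TpC-focused C>T/C>G
#' for the APOBEC pair, broad flat backgrounds, a C>A-dominated and two
#' T>A/T>G-dominated shapes); they are NOT the reference catalogue entries
#' and carry no external data.
#'
#' @param names Signature names to return (subset of the default set).
#' @return 96 x length(names) matrix, columns summing to 1.
#' @export
synthetic_signatures <- function(names = c("SBS1", "SBS2", "SBS5", "SBS7a",
                                           "SBS7b", "SBS7c", "SBS7d",
                                           "SBS13", "SBS17a", "SBS17b",
                                           "SBS38", "SBS40", "SBS97")) {
  cls <- sbs96_classes()
  five <- substr(cls, 1, 1)
  ref <- substr(cls, 3, 3)
  alt <- substr(cls, 5, 5)
  three <- substr(cls, 7, 7)
  sub <- paste0(ref, ">", alt)
  w <- function(expr, amount = 1) ifelse(expr, amount, 0)
  shapes <- list(
    SBS1  = w(sub == "C>T" & three == "G", 1),
    SBS2  = w(sub == "C>T" & five == "T", 1),
    SBS5  = 0.3 + w(sub == "T>C", 1),
    SBS7a = w(sub == "C>T" & five == "T", 2) +
      w(sub == "C>T" & five == "C", 0.5),
    SBS7b = w(sub == "C>T" & five == "C", 2) +
      w(sub == "C>T" & five == "T", 0.5),
    SBS7c = w(sub == "T>A" & three == "T", 1),
    SBS7d = w(sub == "T>C" & three == "T", 1),
    SBS13 = w(sub == "C>G" & five == "T", 1),
    SBS17a = w(sub == "T>A" & five == "C", 1),
    SBS17b = w(sub == "T>G" & five == "C" & three == "T", 2) +
      w(sub == "T>G", 0.2),
    SBS38 = w(sub == "C>A", 1),
    SBS40 = rep(1, 96),
    SBS97 = w(sub == "T>G" & five == "A", 1)
  )
  eps <- 1e-3
  m <- vapply(names, function(nm) {
    v <- shapes[[nm]]
    if (is.null(v)) stop("unknown signature name: ", nm)
    v <- v + eps
    v / sum(v)
  }, numeric(96))
  rownames(m) <- cls
  m
}

cosine_distance <- function(a, b) {
  1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Aggregate mutation spectrum distance (AMSD) test
#'
#' Compares the cosine distance between two observed spectra with the
#' distribution obtained by pooling all mutations and re-drawing two
#' multinomial spectra of the original sizes (each mutation treated as
#' independent). The p-value is the +1-corrected fraction of re-samplings
#' with a cosine distance at least as large as observed, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param spec_a,spec_b SBS-96 count vectors.
#' @param n_perm Number of multinomial re-samplings.
#' @param seed Optional seed.
#' @return List with `distance` (observed cosine distance on
#'   fraction-normalized vectors), `p`, and `n_perm`.
#' @export
amsd <- function(spec_a, spec_b, n_perm = 1e5, seed = NULL) {
  stopifnot(length(spec_a) == length(spec_b))
  na <- sum(spec_a); nb <- sum(spec_b)
  if (na == 0 || nb == 0) stop("both spectra must contain mutations")
  d_obs <- cosine_distance(spec_a / na, spec_b / nb)
  run <- function() {
    pool <- (spec_a + spec_b) / (na + nb)
    ra <- rmultinom(n_perm, na, pool)
    rb <- rmultinom(n_perm, nb, pool)
    num <- colSums(ra * rb)
    dnull <- 1 - num / (sqrt(colSums(ra^2)) * sqrt(colSums(rb^2)))
    (sum(dnull >= d_obs - 1e-12) + 1) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else with_substream(seed, 12L, run())
  list(distance = d_obs, p = p, n_perm = n_perm)
}
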