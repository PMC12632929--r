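# Simulation configuration: the study conditions every generator emulates.

#' Default genome composition by repeat class
#'
#' Fractions of the simulated genome assigned to each repeat class. Satellite
#' families total 4.27% of the genome, matching the donor genome composition
#' the analyses assume; the remainder is split between the major interspersed
#' repeat families and non-repeat sequence.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_class_fractions <- function() {
  c("non-repeat" = 0.55,
    "SINE" = 0.15,
    "LINE" = 0.15,
    "LTR" = 0.107,
    "alpha-satellite" = 0.0177,
    "HSat1A" = 0.003,
    "HSat1B" = 0.003,
    "HSat2" = 0.01,
    "HSat3" = 0.009)
}

#' Default per-class somatic mutation rates (per bp)
#'
#' The per-class Bernoulli rates used by [simulate_ssnvs()]. The anchor values
#' are the HSat2 rate of 6.1e-5 SNVs/bp, a 7.78-fold HSat2 enrichment over the
#' non-repeat baseline, a 5.05-fold spread between the highest and lowest
#' satellite family, and pooled satellite and repeat enrichments of 3.79x and
#' 1.4x over non-repeat sequence (at the [default_class_fractions()]
#' composition). The remaining classes are interpolated so the pooled rates
#' reproduce those folds exactly. CDR / non-CDR-HOR rates (4.20e-5 and
#' 2.32e-5 per bp) are included for configurations that annotate kinetochore
#' domains as their own class.
#'
#' @return Named numeric vector of per-base mutation probabilities.
#' @export
default_class_rates <- function() {
  r0 <- 6.1e-5 / 7.78
  c("non-repeat" = r0,
    "SINE" = 9.5e-6,
    "LINE" = 8.6e-6,
    "LTR" = 8.932e-6,
    "alpha-satellite" = 2.0e-5,
    "HSat1A" = 6.1e-5 / 5.05,
    "HSat1B" = 1.8e-5,
    "HSat2" = 6.1e-5,
    "HSat3" = 2.384816e-5,
    "CDR" = 4.20e-5,
    "non-CDR-HOR" = 2.32e-5)
}

#' UV-dominated SBS-96 spectrum weights
#'
#' Default substitution-class probabilities for the simulator: 72% of the mass
#' on C>T at dipyrimidine contexts (5' C or T), the hallmark of UV-induced
#' cyclobutane pyrimidine dimers, with the remainder uniform over the other
#' classes.
#'
#' @param dipyrimidine_mass Total probability assigned to C>T classes with a
#'   pyrimidine 5' neighbour.
#' @return Named numeric 96-vector summing to 1, in SBS-96 class order.
#' @export
uv_spectrum_weights <- function(dipyrimidine_mass = 0.72) {
  cls <- sbs96_classes()
  five <- substr(cls, 1, 1)
  sub <- substr(cls, 3, 5)
  uv <- sub == "C>T" & five %in% c("C", "T")
  w <- numeric(96)
  w[uv] <- dipyrimidine_mass / sum(uv)
  w[!uv] <- (1 - dipyrimidine_mass) / sum(!uv)
  names(w) <- cls
  w
}

default_karyotype <- function(genome_length_bp) {
  frac <- c("1" = 0.22, "2" = 0.60, "3" = 0.12, "4" = 0.06)
  ends <- round(cumsum(frac) * genome_length_bp)
  starts <- c(0, head(ends, -1))
  data.frame(start = as.integer(starts), end = as.integer(ends),
             state = names(frac), stringsAsFactors = FALSE)
}

#' Default telomere cohort specification
#'
#' Ten telomeres carrying an identical TVR layout, each restructured in the
#' tumor sample: attrition to 1.4 kb of retained proximal sequence followed by
#' 2.3 kb of telomerase-mediated extension, against a 6 kb germline telomere
#' (so the tumor telomeres are on average 2.3 kb shorter).
#'
#' @param n_telomeres Number of telomeres in the cohort.
#' @param restructured Logical (recycled): whether each telomere undergoes
#'   attrition + extension in the tumor.
#' @param attrition_bp Length of proximal telomere retained after attrition.
#' @param extension_bp De novo telomerase extension beyond the attrition point.
#' @return List of per-telomere specification lists.
#' @export
default_telomere_spec <- function(n_telomeres = 10, restructured = TRUE,
                                  attrition_bp = 1400, extension_bp = 2300) {
  restructured <- rep_len(restructured, n_telomeres)
  lapply(seq_len(n_telomeres), function(i) {
    list(name = sprintf("tel%02d", i),
         length_normal = 6000L,
         tvr_offsets = c(200L, 602L, 1000L, 1378L, 1502L, 2200L, 3098L,
                         4202L),
         tvr_motif = "TTGGGGTTGGGG",
         n_reads = 20L,
         restructured = restructured[i],
         attrition_bp = if (restructured[i]) attrition_bp else NA,
         extension_bp = if (restructured[i]) extension_bp else NA)
  })
}

known_hcn_states <- c("DEL", "0", "1", "2", "3", "4", "5", "amp")

#' Build a simulation configuration
#'
#' Bundles and validates every parameter the synthetic-data generators
#' consume. The defaults are the study conditions the analyses assume: a
#' UV-dominated spectrum, the per-class rates of [default_class_rates()], a
#' diploid normal at 176x coverage, a tumor haploid (1n) coverage of 61.5x,
#' and a karyotype in which 78% of the genome departs from the hCN=1 baseline.
#'
#' @param seed Single global integer seed; every generator derives its own
#'   stream from it.
#' @param genome_length_bp Total simulated genome length (>= 10 kb).
#' @param class_fractions Named fractions of the genome per repeat class
#'   (must sum to <= 1; remainder is non-repeat).
#' @param class_rates Named per-base mutation probabilities, all in `[0, 1]`.
#' @param spectrum_weights SBS-96 class probabilities (96-vector summing
#'   to 1).
#' @param depth_normal Mean read depth of the normal sample.
#' @param depth_1n_tumor Haploid-copy (1n) read depth of the tumor.
#' @param karyotype data.frame (`start`, `end`, `state`) of hCN states
#'   covering the genome; `NULL` for the default mixed karyotype.
#' @param cdr_spec List of per-array methylation-dip specifications (see
#'   [simulate_methylation()]); `NULL` derives one 60 kb central dip per
#'   alpha-satellite array.
#' @param telomere_spec Per-telomere TVR layout and attrition/extension plan
#'   (see [default_telomere_spec()]).
#' @param window_size Coverage window size in bp.
#' @param contamination_fraction Fraction of simulated somatic calls that
#'   carry alt evidence in the normal sample.
#' @param contamination_alt_depth Alt read depth planted in the normal for
#'   contaminated calls.
#' @param clonality `"clonal"` (default; retained somatic variants are fixed
#'   on their haplotype) or `"subclonal"` (a fraction of calls at a lower
#'   VAF).
#' @param subclonal_vaf,subclonal_fraction Subclonal VAF and the fraction of
#'   calls drawn from it when `clonality = "subclonal"`.
#' @param meth_baseline,meth_sd Baseline methylation fraction and Gaussian
#'   noise SD of the bulk CpG track.
#' @param meth_dip_level Mean methylation fraction inside planted CDR dips.
#' @param meth_bin Bin width (bp) of the bulk methylation track.
#' @param molecule_length,molecule_coverage Length (bp) and mean coverage of
#'   simulated single molecules carrying per-CpG calls.
#' @param telomere_noise_rate Per-base substitution noise added to telomere
#'   reads.
#' @param satellite_divergence Per-copy substitution divergence of satellite
#'   monomer copies.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length_bp = 2e6,
                       class_fractions = default_class_fractions(),
                       class_rates = default_class_rates(),
                       spectrum_weights = uv_spectrum_weights(),
                       depth_normal = 176,
                       depth_1n_tumor = 61.5,
                       karyotype = NULL,
                       cdr_spec = NULL,
                       telomere_spec = default_telomere_spec(),
                       window_size = 100000L,
                       contamination_fraction = 0,
                       contamination_alt_depth = 2L,
                       clonality = c("clonal", "subclonal"),
                       subclonal_vaf = 0.5,
                       subclonal_fraction = 0.3,
                       meth_baseline = 0.85,
                       meth_sd = 0.05,
                       meth_dip_level = 0.45,
                       meth_bin = 1000L,
                       molecule_length = 30000L,
                       molecule_coverage = 10,
                       telomere_noise_rate = 0.001,
                       satellite_divergence = 0.02) {
  clonality <- match.arg(clonality)
  genome_length_bp <- as.numeric(genome_length_bp)
  if (genome_length_bp < 1e4) {
    stop("configuration error: genome_length_bp must be >= 10 kb")
  }
  if (sum(class_fractions) > 1 + 1e-9) {
    stop("configuration error: class_fractions sum to ",
         round(sum(class_fractions), 4), " > 1")
  }
  if (any(class_fractions < 0)) {
    stop("configuration error: negative class fraction")
  }
  if (any(class_rates < 0 | class_rates > 1)) {
    stop("configuration error: class_rates must lie in [0, 1]")
  }
  if (length(spectrum_weights) != 96 || any(spectrum_weights < 0) ||
      sum(spectrum_weights) <= 0) {
    stop("configuration error: spectrum_weights must be 96 non-negative ",
         "values with positive sum")
  }
  spectrum_weights <- spectrum_weights / sum(spectrum_weights)
  if (is.null(names(spectrum_weights))) {
    names(spectrum_weights) <- sbs96_classes()
  }
  if (is.null(karyotype)) karyotype <- default_karyotype(genome_length_bp)
  if (!all(karyotype$state %in% known_hcn_states)) {
    stop("configuration error: karyotype states must be among ",
         paste(known_hcn_states, collapse = ", "))
  }
  if (karyotype$start[1] != 0 ||
      karyotype$end[nrow(karyotype)] < genome_length_bp ||
      any(karyotype$start[-1] != head(karyotype$end, -1))) {
    stop("configuration error: karyotype must tile the genome contiguously")
  }
  structure(list(
    seed = as.integer(seed),
    genome_length_bp = genome_length_bp,
    class_fractions = class_fractions,
    class_rates = class_rates,
    spectrum_weights = spectrum_weights,
    depth_normal = depth_normal,
    depth_1n_tumor = depth_1n_tumor,
    karyotype = karyotype,
    cdr_spec = cdr_spec,
    telomere_spec = telomere_spec,
    window_size = as.integer(window_size),
    contamination_fraction = contamination_fraction,
    contamination_alt_depth = as.integer(contamination_alt_depth),
    clonality = clonality,
    subclonal_vaf = subclonal_vaf,
    subclonal_fraction = subclonal_fraction,
    meth_baseline = meth_baseline,
    meth_sd = meth_sd,
    meth_dip_level = meth_dip_level,
    meth_bin = as.integer(meth_bin),
    molecule_length = as.integer(molecule_length),
    molecule_coverage = molecule_coverage,
    telomere_noise_rate = telomere_noise_rate,
    satellite_divergence = satellite_divergence
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "| genome",
      format(x$genome_length_bp, big.mark = ","), "bp |",
      length(x$class_fractions), "classes |",
      nrow(x$karyotype), "karyotype blocks\n")
  invisible(x)
}
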