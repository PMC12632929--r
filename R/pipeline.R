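# End-to-end pipeline over the synthetic inputs, with YAML config, manifest,
# and deterministic seed plumbing.

pipeline_known_keys <- c(
  "seed", "genome_length_bp", "class_fractions", "class_rates",
  "depth_normal", "depth_1n_tumor", "window_size", "contamination_fraction",
  "n_telomeres", "segment_nperm", "segment_alpha", "n_peaks", "amsd_n_perm")

#' Validate a pipeline configuration
#'
#' Accepts a list or a YAML file path; unknown keys are rejected.
#'
#' @param config List or path to a YAML file.
#' @return Validated configuration list (defaults filled in).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: config must be a list or YAML path")
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(seed = 1L, genome_length_bp = 2e6,
                   class_fractions = NULL, class_rates = NULL,
                   depth_normal = 176, depth_1n_tumor = 61.5,
                   window_size = 20000L, contamination_fraction = 0.02,
                   n_telomeres = 4L, segment_nperm = 2000L,
                   segment_alpha = 0.001,
                   n_peaks = 150L, amsd_n_perm = 5000L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> hCN -> sSNV cascade -> spectra/rates -> CDR ->
#' telomere -> accessibility on synthetic inputs, writing standard-format
#' artifacts plus a JSON manifest of files, checksums, seed and parameters.
#' Deterministic for a fixed config.
#'
#' @param config List or YAML path (see [pipeline_config()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), outdir) {
  cfg <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc_args <- list(seed = cfg$seed, genome_length_bp = cfg$genome_length_bp,
                  depth_normal = cfg$depth_normal,
                  depth_1n_tumor = cfg$depth_1n_tumor,
                  window_size = cfg$window_size,
                  contamination_fraction = cfg$contamination_fraction,
                  telomere_spec = default_telomere_spec(cfg$n_telomeres))
  if (!is.null(cfg$class_fractions)) {
    sc_args$class_fractions <- unlist(cfg$class_fractions)
  }
  if (!is.null(cfg$class_rates)) {
    sc_args$class_rates <- unlist(cfg$class_rates)
  }
  sc <- do.call(sim_config, sc_args)

  genome <- generate_genome(sc)
  fa <- file.path(outdir, "genome.fa")
  write_fasta(genome$contigs, fa)
  ann_bed <- file.path(outdir, "annotations.bed")
  write_bed(stats::setNames(genome$annotations,
                            c("contig", "start", "end", "name")), ann_bed)

  cov <- simulate_coverage(genome, sc)
  write_bedgraph(stats::setNames(cov$normal,
                                 c("contig", "start", "end", "value")),
                 file.path(outdir, "coverage_normal.bedgraph"))
  write_bedgraph(stats::setNames(cov$tumor,
                                 c("contig", "start", "end", "value")),
                 file.path(outdir, "coverage_tumor.bedgraph"))
  modes_t <- find_coverage_modes(cov$tumor$depth, binwidth = 5)
  modes_n <- find_coverage_modes(cov$normal$depth, binwidth = 5)
  # Window depths here are diploid totals, so the normal normalization
  # constant is the diploid mode itself (normal term ~ 1); with per-haplotype
  # window depths it would be half that. See the methods vignette.
  prof <- log2_hcn_ratio(cov$tumor, cov$normal,
                         tumor_1n = modes_t$haploid,
                         normal_1n = modes_n$primary)
  segs <- smooth_and_segment(prof, nperm = cfg$segment_nperm,
                             alpha = cfg$segment_alpha, seed = cfg$seed)
  segs <- classify_segments(segs)
  seg_bed <- file.path(outdir, "hcn_segments.bed")
  write_bed(data.frame(contig = segs$contig, start = segs$start,
                       end = segs$end, name = segs$state,
                       score = round(segs$median_ratio, 4)), seg_bed)

  sim <- simulate_ssnvs(genome, sc)
  raw_vcf <- file.path(outdir, "ssnv_raw.vcf")
  write_vcf(sim$calls, raw_vcf,
            contig_lengths = nchar(genome$contigs))
  calls <- normal_evidence_filter(sim$calls)
  calls <- remove_deleted_segments(calls, segs)
  calls <- density_filter(calls)
  dn <- call_dnvs(calls)
  filt_vcf <- file.path(outdir, "ssnv_filtered.vcf")
  write_vcf(dn$snvs, filt_vcf, contig_lengths = nchar(genome$contigs))

  spec <- build_spectra(dn$snvs, dn$dnvs, genome)
  spec_tsv <- file.path(outdir, "sbs96.tsv")
  write.table(data.frame(class = names(spec$sbs96),
                         count = as.numeric(spec$sbs96)),
              spec_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- fit_signatures_nnls(spec$sbs96, synthetic_signatures())
  rates <- rate_by_class(dn$snvs, genome$annotations)
  rates_tsv <- file.path(outdir, "rates_by_class.tsv")
  folds <- fold_enrichment(rates)
  rates$fold <- unname(folds[rates$class])
  write.table(rates, rates_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  meth <- simulate_methylation(genome, sc)
  cdr_bed <- file.path(outdir, "cdrs_bulk.bed")
  cdrs <- if (nrow(meth$arrays)) {
    call_bulk_cdrs(meth$bulk, meth$arrays, edge = 20000)
  } else meth$arrays
  if (nrow(cdrs)) {
    write_bed(cdrs[, c("contig", "start", "end")], cdr_bed)
  } else {
    writeLines(character(0), cdr_bed)
  }

  tel <- simulate_telomeres(sc)
  tel_rows <- list()
  for (nm in unique(tel$telomere)) {
    rn <- tel[tel$telomere == nm & tel$sample == "normal", ]
    rt <- tel[tel$telomere == nm & tel$sample == "tumor", ]
    det <- detect_restructuring(consensus_tvr_profile(rn),
                                consensus_tvr_profile(rt))
    tel_rows[[nm]] <- data.frame(
      telomere = nm, restructured = det$restructured,
      distal_boundary = det$distal_boundary,
      proximal_limit = det$proximal_limit,
      mean_tumor_length = mean(telomere_length(rt$sequence,
                                               rt$boundary_offset)),
      stringsAsFactors = FALSE)
  }
  tel_tsv <- file.path(outdir, "telomere_restructuring.tsv")
  write.table(do.call(rbind, tel_rows), tel_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)

  peaks <- simulate_peaks(segs, sc, n_peaks = cfg$n_peaks)
  peaks <- test_haplotype_selectivity(peaks)
  peaks_tsv <- file.path(outdir, "accessibility_peaks.tsv")
  write.table(peaks, peaks_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- c(fa, ann_bed, file.path(outdir, "coverage_normal.bedgraph"),
             file.path(outdir, "coverage_tumor.bedgraph"), seg_bed,
             raw_vcf, filt_vcf, spec_tsv, rates_tsv, cdr_bed, tel_tsv,
             peaks_tsv)
  manifest <- list(
    package = "somaT2T",
    version = as.character(utils::packageVersion("somaT2T")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "seed")],
    coverage_modes = list(tumor = modes_t, normal = modes_n),
    altered_fraction = altered_fraction(segs),
    n_calls_raw = nrow(sim$calls),
    n_calls_filtered = nrow(dn$snvs),
    n_dnvs = nrow(dn$dnvs),
    top_signature = names(which.max(sig$fractions)),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
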