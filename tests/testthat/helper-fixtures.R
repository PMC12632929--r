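# Fixture builders shared across tests; all data constructed in code.

make_calls <- function(pos, contig = "sim1", ref = "C", alt = "T",
                       haplotype = 1L, depth_tumor = 60L,
                       alt_depth_tumor = depth_tumor,
                       depth_normal = 170L, alt_depth_normal = 0L,
                       phase_set = NA_integer_) {
  n <- length(pos)
  df <- data.frame(
    contig = rep_len(contig, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    haplotype = rep_len(haplotype, n),
    depth_tumor = rep_len(as.integer(depth_tumor), n),
    alt_depth_tumor = rep_len(as.integer(alt_depth_tumor), n),
    depth_normal = rep_len(as.integer(depth_normal), n),
    alt_depth_normal = rep_len(as.integer(alt_depth_normal), n),
    phase_set = rep_len(phase_set, n),
    stringsAsFactors = FALSE)
  df$vaf <- df$alt_depth_tumor / df$depth_tumor
  df
}

make_profile <- function(ratio, contig = "c", window = 1e5) {
  n <- length(ratio)
  data.frame(contig = contig, start = (seq_len(n) - 1) * window,
             end = seq_len(n) * window, ratio = ratio,
             stringsAsFactors = FALSE)
}

make_segments <- function(states, contig = "c", width = 1e6,
                          ratio = NULL) {
  n <- length(states)
  contig <- rep_len(contig, n)
  data.frame(contig = contig, start = (seq_len(n) - 1) * width,
             end = seq_len(n) * width,
             median_ratio = rep_len(ratio %||% 0, n),
             n_windows = rep(as.integer(width / 1e5), n),
             state = states, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# methylation track for one array with optional dips
make_meth_track <- function(array_start = 0, array_end = 5e5, bin = 1000,
                            baseline = 0.85, sd = 0.04, dips = list(),
                            dip_level = 0.45, contig = "ct") {
  starts <- seq(array_start, array_end - 1, by = bin)
  ends <- pmin(starts + bin, array_end)
  mids <- (starts + ends) / 2
  mu <- rep(baseline, length(starts))
  for (d in dips) mu[mids >= d[1] & mids < d[2]] <- dip_level
  data.frame(contig = contig, start = starts, end = ends,
             value = pmin(1, pmax(0, rnorm(length(mu), mu, sd))),
             stringsAsFactors = FALSE)
}
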