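# Synthetic annotated genome.

satellite_monomer_length <- c("alpha-satellite" = 171L, "CDR" = 171L,
                              "non-CDR-HOR" = 171L, "HSat1A" = 42L,
                              "HSat1B" = 42L, "HSat2" = 26L, "HSat3" = 26L)

random_dna <- function(n, prob = rep(0.25, 4)) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Tandem monomer with per-copy substitution divergence: realistic k-mer
# composition without real satellite sequence.
satellite_block <- function(len, monomer_len, divergence) {
  monomer <- strsplit(random_dna(monomer_len), "")[[1]]
  ncopy <- ceiling(len / monomer_len)
  bases <- rep.int(monomer, ncopy)[seq_len(len)]
  nmut <- rbinom(1, len, divergence)
  if (nmut > 0) {
    idx <- sample.int(len, nmut)
    bases[idx] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
  }
  paste(bases, collapse = "")
}

#' Generate a synthetic annotated genome
#'
#' Lays out one contiguous block per repeat class (in the order of
#' `config$class_fractions`), with any remaining length appended as
#' non-repeat sequence. Satellite classes are built as tandem monomers (171 bp
#' for alpha-satellite-like classes, 26 bp for HSat2/HSat3-like, 42 bp for
#' HSat1-like) with per-copy substitution divergence; all other classes are
#' i.i.d. random sequence. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return An `annotated_genome`: list with `contigs` (named character vector)
#'   and `annotations` (data.frame `contig`, `start`, `end`, `class`; 0-based
#'   half-open).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, 1L, {
    L <- config$genome_length_bp
    frac <- config$class_fractions
    lens <- round(frac * L)
    # rounding bookkeeping: shrink the largest block if we overshoot
    over <- sum(lens) - L
    if (over > 0) {
      i <- which.max(lens)
      lens[i] <- lens[i] - over
    }
    classes <- names(frac)
    blocks <- character(length(classes))
    for (i in seq_along(classes)) {
      cl <- classes[i]
      if (lens[i] == 0) { blocks[i] <- ""; next }
      blocks[i] <- if (cl %in% names(satellite_monomer_length)) {
        satellite_block(lens[i], satellite_monomer_length[[cl]],
                        config$satellite_divergence)
      } else {
        random_dna(lens[i])
      }
    }
    rest <- L - sum(lens)
    if (rest > 0) {
      blocks <- c(blocks, random_dna(rest))
      classes <- c(classes, "non-repeat")
      lens <- c(lens, rest)
    }
    keep <- lens > 0
    blocks <- blocks[keep]; classes <- classes[keep]; lens <- lens[keep]
    ends <- cumsum(lens)
    ann <- data.frame(contig = "sim1",
                      start = as.integer(c(0, head(ends, -1))),
                      end = as.integer(ends),
                      class = classes,
                      stringsAsFactors = FALSE)
    genome <- structure(
      list(contigs = c(sim1 = paste(blocks, collapse = "")),
           annotations = ann),
      class = "annotated_genome")
    genome
  })
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome>", length(x$contigs), "contig(s),",
      format(sum(nchar(x$contigs)), big.mark = ","), "bp,",
      nrow(x$annotations), "annotation blocks\n")
  invisible(x)
}

# Internal: class label of 0-based positions, using annotation order.
class_at <- function(genome, contig, pos0) {
  ann <- genome$annotations
  idx <- point_in_intervals(contig, pos0, ann)
  ann$class[idx]
}
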