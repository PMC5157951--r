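#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. The defaults
#' describe the study design the downstream analysis assumes: six embryonic
#' tissues (forelimb FL, hindlimb HL, genital tubercle GT and three trunk
#' segments T1--T3), two genotypes (wild type `wt` and homozygous deletion
#' `del`), two biological replicates per (tissue, genotype), stranded
#' single-end 100 nt reads, and a desk-scale toy chromosome of 600 kb with
#' ~200 background genes.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param n_background_genes number of background genes outside the Hox-like
#'   locus.
#' @param tissues character vector of tissue labels.
#' @param genotypes character vector, first entry is the reference genotype.
#' @param replicates_per_group biological replicates per (tissue, genotype).
#' @param library_size_mean expected number of clean reads per sample;
#'   realised sizes are drawn log-normally around this mean.
#' @param library_size_sdlog log-scale SD of the per-sample library sizes.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-12 switch to Poisson sampling.
#' @param planted_effects data frame with columns `gene_id`, `tissue`,
#'   `log2fc`: genotype effects (del vs wt) planted into the counts.
#' @param readthrough_rate fraction of deletion-allele locus transcripts that
#'   extend past the deleted termination signals (read-through).
#' @param multi_overlap_rate fraction of the library emitted as contaminant
#'   reads spanning two same-strand overlapping genes.
#' @param high_mismatch_rate fraction of the library emitted as contaminant
#'   reads carrying >2 mismatches or a small indel.
#' @param read_length single-end read length in nt.
#' @param chrom_length toy chromosome length in bp.
#' @param library_strandedness `"antisense"` (dUTP/TruSeq stranded: reads
#'   align opposite to the transcript) or `"sense"`.
#' @param chip_total_reads,input_total_reads total mapped reads assumed for
#'   the simulated ChIP and input tracks (used for per-million scaling).
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background_genes = 200L,
                       tissues = c("FL", "HL", "GT", "T1", "T2", "T3"),
                       genotypes = c("wt", "del"),
                       replicates_per_group = 2L,
                       library_size_mean = 2e4,
                       library_size_sdlog = 0.15,
                       nb_dispersion = 0.05,
                       planted_effects = default_planted_effects(),
                       readthrough_rate = 0.8,
                       multi_overlap_rate = 0.02,
                       high_mismatch_rate = 0.02,
                       read_length = 100L,
                       chrom_length = 600000L,
                       library_strandedness = c("antisense", "sense"),
                       chip_total_reads = 2e7,
                       input_total_reads = 2e7) {
  library_strandedness <- match.arg(library_strandedness)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_background_genes < 0 || replicates_per_group < 1 ||
      library_size_mean <= 0 || nb_dispersion < 0 || read_length <= 0 ||
      chrom_length <= 0) {
    stop("invalid configuration: sizes and rates must be positive", call. = FALSE)
  }
  if (readthrough_rate < 0 || readthrough_rate > 1 ||
      multi_overlap_rate < 0 || high_mismatch_rate < 0) {
    stop("invalid configuration: rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(tissues) < 1 || anyDuplicated(tissues)) {
    stop("invalid configuration: tissues must be unique labels", call. = FALSE)
  }
  if (length(genotypes) != 2L) {
    stop("invalid configuration: exactly two genotypes (reference first)", call. = FALSE)
  }
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("gene_id", "tissue", "log2fc") %in% names(planted_effects)))
    bad <- setdiff(planted_effects$tissue, tissues)
    if (length(bad)) {
      stop("planted_effects references unknown tissues: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_background_genes = as.integer(n_background_genes),
    tissues = tissues,
    genotypes = genotypes,
    replicates_per_group = as.integer(replicates_per_group),
    library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog,
    nb_dispersion = nb_dispersion,
    planted_effects = planted_effects,
    readthrough_rate = readthrough_rate,
    multi_overlap_rate = multi_overlap_rate,
    high_mismatch_rate = high_mismatch_rate,
    read_length = as.integer(read_length),
    chrom_length = as.integer(chrom_length),
    library_strandedness = library_strandedness,
    chip_total_reads = chip_total_reads,
    input_total_reads = input_total_reads
  ), class = "sim_config")
}

#' Default planted genotype effects
#'
#' The cis effects the analysis is designed to detect: a light gain of
#' Hoxc11 and a light loss of Hoxc12 in the posterior tissues where they are
#' transcribed, and a gain of the AntiHotair unit whose termination signal is
#' removed by the deletion.
#'
#' @return data frame with columns `gene_id`, `tissue`, `log2fc`.
#' @export
default_planted_effects <- function() {
  data.frame(
    gene_id = c("Hoxc11", "Hoxc11", "Hoxc11", "Hoxc12", "Hoxc12",
                "AHotair", "AHotair"),
    tissue  = c("GT", "T2", "T3", "T2", "T3", "T2", "T3"),
    log2fc  = c(0.6, 0.6, 0.6, -0.6, -0.6, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Sample sheet for a simulation design
#'
#' @param config a [sim_config()].
#' @return data frame with columns `sample_id`, `tissue`, `genotype`,
#'   `replicate`, one row per simulated library.
#' @export
sample_sheet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(replicate = seq_len(config$replicates_per_group),
                      genotype = config$genotypes,
                      tissue = config$tissues,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "genotype", "replicate")]
  grid$sample_id <- sprintf("%s_%s_%d", grid$genotype, grid$tissue, grid$replicate)
  grid[, c("sample_id", "tissue", "genotype", "replicate")]
}

#' Write / read a sample sheet as TSV
#'
#' @param samples data frame as returned by [sample_sheet()].
#' @param path file path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
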