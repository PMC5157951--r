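#' Simulate H3K27me3 ChIP and input coverage tracks
#'
#' Builds piecewise-constant per-base coverage for a ChIP (H3K27me3) and an
#' input library over the toy chromosome. Planted target genes receive a
#' promoter ChIP enrichment well above the calling thresholds (normalized
#' coverage ~0.25 per million mapped reads against an input of ~0.02, i.e.
#' a ratio >= 8), non-targets stay at the genome-wide baseline (ratio
#' <= 2/3), and satellite repeats are given an artifactual ChIP enrichment
#' so that the satellite-exclusion rule of the caller is exercised: at
#' least one planted target's promoter overlaps a satellite repeat and must
#' therefore be rejected downstream.
#'
#' @param annotation a `toy_annotation`.
#' @param target_genes genes to plant as Polycomb targets; defaults to the
#'   annotation's `default_chip_targets` (which include the
#'   satellite-overlapped gene).
#' @param config the [sim_config()] (provides total mapped reads and seed).
#' @return object of class `sim_chip`: list with `chip` and `input`
#'   (GRanges with `score` = raw per-base coverage), `chip_total_reads`,
#'   `input_total_reads`, `target_genes` and `promoters`.
#' @export
simulate_chip <- function(annotation,
                          target_genes = annotation$default_chip_targets,
                          config = sim_config()) {
  stopifnot(inherits(annotation, "toy_annotation"), inherits(config, "sim_config"))
  genes <- annotation_genes(annotation)
  bad <- setdiff(target_genes, genes$gene_id)
  if (length(bad)) {
    stop("target genes absent from the annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed + 3L)
  chrom <- annotation$layout$chrom
  len <- annotation$chrom_lengths[[chrom]]
  per_m_chip <- config$chip_total_reads / 1e6
  per_m_input <- config$input_total_reads / 1e6

  models <- flatten_gene_models(annotation, canonical_overrides = annotation$canonical)
  promoters <- define_promoters(models, mode = "upstream2kb",
                                chrom_lengths = annotation$chrom_lengths)

  base_chip <- Rle(0.02 * per_m_chip, len)
  base_input <- Rle(0.02 * per_m_input, len)

  add_block <- function(rle, gr, level) {
    for (k in seq_along(gr)) {
      idx <- start(gr)[k]:end(gr)[k]
      rle[idx] <- rle[idx] + level
    }
    rle
  }
  tg <- promoters[promoters$gene_id %in% target_genes]
  # per-target jitter keeps the margin >= 2x the calling thresholds
  lv <- (0.23 + runif(length(tg), 0, 0.08)) * per_m_chip
  for (k in seq_along(tg)) {
    idx <- start(tg)[k]:end(tg)[k]
    base_chip[idx] <- base_chip[idx] + lv[k]
  }
  sats <- annotation$repeats[grepl("satellite", annotation$repeats$class,
                                   ignore.case = TRUE)]
  base_chip <- add_block(base_chip, sats, 0.30 * per_m_chip)

  rle_to_gr <- function(r) {
    gr <- as(setNames(RleList(r), chrom), "GRanges")
    gr[gr$score != 0]
  }
  structure(list(chip = rle_to_gr(base_chip),
                 input = rle_to_gr(base_input),
                 chip_total_reads = config$chip_total_reads,
                 input_total_reads = config$input_total_reads,
                 target_genes = target_genes,
                 promoters = promoters),
            class = "sim_chip")
}
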