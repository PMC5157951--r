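#' Quantify named strand-specific locus regions
#'
#' Counts strand-matched reads over arbitrary named regions (the Hotair,
#' AHotair, LAHotair and Ghostair windows around the deleted segment) and
#' converts them to RPKM with the region length in place of the exonic
#' length, using the same per-sample nuclear totals as the gene-level
#' quantification. Scale factors from the median-scaling normalization can
#' be applied on top.
#'
#' @param alignments per-sample list of alignment data frames, a single
#'   data frame, or a `sim_alignments` object.
#' @param regions named GRanges with strand (the *transcript* strand of the
#'   expected product).
#' @param totals named per-sample nuclear mapped-read totals.
#' @param strandedness library strandedness, as in [count_unique_reads()].
#' @param scale_factors optional per-sample normalization factors.
#' @param contained require reads fully contained in the region instead of
#'   >= 1 overlapping base.
#' @param chrom_lengths named chromosome lengths for validation (optional).
#' @return numeric matrix regions x samples of (normalized) RPKM.
#' @export
quantify_regions <- function(alignments, regions, totals,
                             strandedness = c("antisense", "sense", "unstranded"),
                             scale_factors = NULL, contained = FALSE,
                             chrom_lengths = NULL) {
  strandedness <- match.arg(strandedness)
  if (inherits(alignments, "sim_alignments")) alignments <- alignments$alignments
  if (is.data.frame(alignments)) alignments <- list(S1 = alignments)
  if (is.null(names(regions))) stop("regions must be named", call. = FALSE)
  if (!is.null(chrom_lengths)) {
    over <- end(regions) > chrom_lengths[as.character(seqnames(regions))] |
      start(regions) < 1
    if (any(over)) {
      stop("region(s) outside chromosome bounds: ",
           paste(names(regions)[over], collapse = ", "), call. = FALSE)
    }
  }
  totals <- totals[names(alignments)]
  if (any(is.na(totals)) || any(totals <= 0)) {
    stop("positive totals required for every sample", call. = FALSE)
  }
  out <- matrix(0, length(regions), length(alignments),
                dimnames = list(names(regions), names(alignments)))
  for (s in seq_along(alignments)) {
    aln <- alignments[[s]]
    if (!nrow(aln)) next
    keep <- aln$nh == 1L & aln$nm <= 2L & !grepl("[ID]", aln$cigar)
    aln <- aln[keep, , drop = FALSE]
    if (!nrow(aln)) next
    tx_strand <- switch(strandedness,
                        antisense = chartr("+-", "-+", aln$strand),
                        sense = aln$strand,
                        unstranded = rep("*", nrow(aln)))
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(aln$cigar,
                                                                   pos = aln$start)
    ridx <- rep(seq_len(nrow(aln)), lengths(blocks))
    bgr <- GRanges(rep(aln$chrom, lengths(blocks)), unlist(blocks),
                   strand = rep(tx_strand, lengths(blocks)))
    for (r in seq_along(regions)) {
      hit <- findOverlaps(bgr, regions[r],
                          type = if (contained) "within" else "any",
                          ignore.strand = FALSE)
      n_reads <- length(unique(ridx[queryHits(hit)]))
      if (contained) {
        # every block of the read must lie within the region
        inreads <- unique(ridx[queryHits(hit)])
        nb_in <- table(factor(ridx[queryHits(hit)], levels = inreads))
        nb_all <- table(factor(ridx, levels = inreads))
        n_reads <- sum(nb_in == nb_all)
      }
      out[r, s] <- n_reads / (width(regions)[r] / 1000) / (totals[s] / 1e6)
    }
  }
  if (!is.null(scale_factors)) {
    out <- sweep(out, 2, scale_factors[colnames(out)], "*")
  }
  out
}

#' Collapse a coverage track onto the deletion-allele coordinate system
#'
#' Removes the deleted segment from a per-base coverage vector, fusing the
#' flanks as they are fused in the deletion allele. Transcription that runs
#' across the breakpoint then appears as one contiguous covered segment,
#' which is how read-through products are detected.
#'
#' @param cov per-base coverage: an `Rle`, or an `RleList` (the deleted
#'   segment's chromosome is used).
#' @param deleted GRanges of length 1 describing the deleted segment.
#' @return list with `coverage` (collapsed Rle) and `boundary` (the fused
#'   breakpoint: the last retained coordinate before the deletion).
#' @export
collapse_deletion <- function(cov, deleted) {
  stopifnot(is(deleted, "GRanges"), length(deleted) == 1)
  if (is(cov, "RleList")) {
    cov <- cov[[as.character(seqnames(deleted))]]
    if (is.null(cov)) stop("coverage lacks the deleted segment's chromosome",
                           call. = FALSE)
  }
  st <- start(deleted)
  en <- end(deleted)
  stopifnot(st >= 1, en <= length(cov))
  left <- if (st > 1) window(cov, 1L, st - 1L) else Rle(numeric(0))
  right <- if (en < length(cov)) window(cov, en + 1L, length(cov)) else Rle(numeric(0))
  list(coverage = c(left, right), boundary = st - 1L)
}

#' Segment a coverage track into transcribed regions
#'
#' Finds maximal runs of per-base coverage at or above `min_cov`, merging
#' runs separated by fewer than `max_gap` low-coverage bases. When a
#' `boundary` coordinate is supplied (the fused deletion breakpoint in
#' collapsed coordinates), each segment is flagged if it strictly contains
#' it — coverage merely touching the breakpoint on one side does not
#' count as read-through.
#'
#' @param cov an `Rle` of per-base coverage.
#' @param min_cov minimum coverage (default 0.05).
#' @param max_gap maximum internal gap to bridge, in bases (default 50).
#' @param boundary optional breakpoint coordinate.
#' @return data frame: `start`, `end`, `mean_cov`, `crosses_boundary`.
#' @export
segment_transcribed <- function(cov, min_cov = 0.05, max_gap = 50L,
                                boundary = NULL) {
  stopifnot(is(cov, "Rle"))
  ir <- as(slice(cov, lower = min_cov, rangesOnly = TRUE), "IRanges")
  if (length(ir) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      mean_cov = numeric(), crosses_boundary = logical()))
  }
  if (max_gap > 0) ir <- reduce(ir, min.gapwidth = max_gap)
  mc <- vapply(seq_along(ir), function(k) {
    mean(window(cov, start(ir)[k], end(ir)[k]))
  }, 1.0)
  crosses <- if (is.null(boundary)) rep(FALSE, length(ir)) else
    start(ir) < boundary & end(ir) > boundary
  data.frame(start = start(ir), end = end(ir), mean_cov = mc,
             crosses_boundary = crosses)
}

#' Correlate the expression of two genes or regions
#'
#' Pearson and Spearman coefficients on `log2(x + offset)`-transformed
#' (normalized) RPKM values across the selected samples.
#'
#' @param rpkm expression matrix (genes/regions x samples).
#' @param gene_a,gene_b row names to correlate.
#' @param samples optional sample subset (default: all columns).
#' @param offset added before the log2 transform (default 1).
#' @return list with `pearson`, `spearman`, `n`.
#' @export
correlate_pair <- function(rpkm, gene_a, gene_b, samples = NULL, offset = 1) {
  if (is.null(samples)) samples <- colnames(rpkm)
  stopifnot(gene_a %in% rownames(rpkm), gene_b %in% rownames(rpkm))
  if (length(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  a <- log2(rpkm[gene_a, samples] + offset)
  b <- log2(rpkm[gene_b, samples] + offset)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant expression vector; correlation undefined")
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(samples)))
  }
  list(pearson = cor(a, b, method = "pearson"),
       spearman = cor(a, b, method = "spearman"),
       n = length(samples))
}
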