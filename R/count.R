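#' Count unique reads over flattened gene models
#'
#' Assigns each alignment to at most one gene under the filtering rules of
#' strand-specific quantification: a read is counted for a gene iff it is
#' uniquely mapping (`nh == 1`), carries at most 2 mismatches, contains no
#' small insertion or deletion, its transcript strand (derived from the
#' alignment strand via the library strandedness) matches the gene strand,
#' at least `min_overlap` aligned bases fall on the gene's flattened exons,
#' and exactly one gene on that strand satisfies the overlap (reads
#' touching two or more overlapping same-strand genes are discarded for
#' all of them). Per-sample totals are the nuclear mapped reads, i.e. all
#' mapped records excluding mitochondrial chromosomes.
#'
#' @param alignments a per-sample named list of alignment data frames
#'   (columns `read_id`, `chrom`, `start`, `cigar`, `strand`, `nm`, `nh`;
#'   see [read_sam()]), a single such data frame (treated as one sample),
#'   or a `sim_alignments` object.
#' @param models a `flat_models` object from [flatten_gene_models()].
#' @param strandedness `"antisense"` (default; dUTP/TruSeq stranded, the
#'   transcript strand is opposite the alignment strand), `"sense"`, or
#'   `"unstranded"`.
#' @param min_overlap minimum aligned bases on the exons (default 1).
#' @param mito_chroms chromosome names excluded from the totals.
#' @return list with `counts` (integer matrix genes x samples) and `totals`
#'   (named numeric vector of nuclear mapped reads).
#' @export
count_unique_reads <- function(alignments, models,
                               strandedness = c("antisense", "sense", "unstranded"),
                               min_overlap = 1L,
                               mito_chroms = c("chrM", "MT")) {
  strandedness <- match.arg(strandedness)
  stopifnot(inherits(models, "flat_models"))
  if (inherits(alignments, "sim_alignments")) alignments <- alignments$alignments
  if (is.data.frame(alignments)) alignments <- list(S1 = alignments)
  if (!length(alignments)) stop("no alignment samples supplied", call. = FALSE)
  if (!length(models$exons)) stop("empty model list", call. = FALSE)

  exon_gr <- unlist(models$exons, use.names = FALSE)
  exon_gene <- rep(seq_along(models$exons), lengths(models$exons))
  gene_ids <- names(models$exons)
  known_chroms <- unique(models$info$chrom)

  counts <- matrix(0L, length(gene_ids), length(alignments),
                   dimnames = list(gene_ids, names(alignments)))
  totals <- setNames(numeric(length(alignments)), names(alignments))

  for (s in seq_along(alignments)) {
    aln <- alignments[[s]]
    if (!nrow(aln)) next
    bad_chrom <- setdiff(unique(aln$chrom), c(known_chroms, mito_chroms))
    if (length(bad_chrom)) {
      stop("alignments on unknown chromosome(s): ",
           paste(bad_chrom, collapse = ", "), call. = FALSE)
    }
    nuclear <- !(aln$chrom %in% mito_chroms)
    totals[s] <- sum(nuclear)
    aln <- aln[nuclear, , drop = FALSE]
    clean <- aln$nh == 1L & aln$nm <= 2L & !grepl("[ID]", aln$cigar)
    aln <- aln[clean, , drop = FALSE]
    if (!nrow(aln)) next

    tx_strand <- switch(strandedness,
                        antisense = chartr("+-", "-+", aln$strand),
                        sense = aln$strand,
                        unstranded = rep("*", nrow(aln)))
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(aln$cigar,
                                                                   pos = aln$start)
    read_idx <- rep(seq_len(nrow(aln)), lengths(blocks))
    bgr <- GRanges(rep(aln$chrom, lengths(blocks)), unlist(blocks),
                   strand = rep(tx_strand, lengths(blocks)))
    hits <- findOverlaps(bgr, exon_gr, minoverlap = min_overlap,
                         ignore.strand = FALSE)
    if (!length(hits)) next
    pair <- unique(data.frame(read = read_idx[queryHits(hits)],
                              gene = exon_gene[subjectHits(hits)]))
    ngenes <- tabulate(pair$read, nbins = nrow(aln))
    ok <- pair[ngenes[pair$read] == 1L, , drop = FALSE]
    if (nrow(ok)) {
      tab <- tabulate(ok$gene, nbins = length(gene_ids))
      counts[, s] <- counts[, s] + tab
    }
  }
  list(counts = counts, totals = totals)
}
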