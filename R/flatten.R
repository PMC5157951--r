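#' Flatten gene models to disjoint exon unions
#'
#' Builds the per-gene counting unit: the union of exon intervals from the
#' retained transcript isoforms. Isoform retention follows the rules used
#' for stranded embryonic RNA-seq quantification: for protein-coding genes
#' only transcripts of class `protein_coding` contribute (isoforms flagged
#' `retained_intron`, `nonsense_mediated_decay` and similar are discarded);
#' for genes listed in `canonical_overrides` (typically the Hox genes,
#' whose annotations carry read-through isoforms) only the named canonical
#' transcript contributes; for non-coding genes all annotated isoforms are
#' kept.
#'
#' @param annotation a `toy_annotation` or exon data frame (see
#'   [read_annotation_gtf()]).
#' @param canonical_overrides named character vector mapping `gene_id` to
#'   the single transcript_id to retain.
#' @return object of class `flat_models`: list with `info` (data frame:
#'   `gene_id`, `chrom`, `strand`, `gene_biotype`, `exonic_length`) and
#'   `exons` (GRangesList of disjoint sorted intervals, one element per
#'   gene).
#' @export
flatten_gene_models <- function(annotation, canonical_overrides = NULL) {
  ex <- as_exon_table(annotation)
  if (!is.null(canonical_overrides)) {
    for (g in names(canonical_overrides)) {
      tx <- ex$transcript_id[ex$gene_id == g]
      if (!canonical_overrides[[g]] %in% tx) {
        stop("canonical override for gene '", g, "' names absent transcript '",
             canonical_overrides[[g]], "'", call. = FALSE)
      }
    }
  }
  keep <- rep(TRUE, nrow(ex))
  pc <- ex$gene_biotype == "protein_coding"
  keep[pc] <- ex$transcript_class[pc] == "protein_coding"
  if (!is.null(canonical_overrides)) {
    ov <- ex$gene_id %in% names(canonical_overrides)
    keep[ov] <- ex$transcript_id[ov] ==
      unname(canonical_overrides[ex$gene_id[ov]])
  }
  dropped <- setdiff(unique(ex$gene_id), unique(ex$gene_id[keep]))
  if (length(dropped)) {
    message("flatten_gene_models: ", length(dropped),
            " gene(s) without retained transcripts excluded: ",
            paste(head(dropped, 5), collapse = ", "))
  }
  ex <- ex[keep, , drop = FALSE]
  gr <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  grl <- reduce(split(gr, ex$gene_id))
  info <- data.frame(
    gene_id = names(grl),
    chrom = vapply(seq_along(grl), function(i) as.character(seqnames(grl[[i]])[1]), ""),
    strand = vapply(seq_along(grl), function(i) as.character(strand(grl[[i]])[1]), ""),
    gene_biotype = ex$gene_biotype[match(names(grl), ex$gene_id)],
    exonic_length = vapply(grl, function(g) sum(width(g)), 1L),
    stringsAsFactors = FALSE
  )
  rownames(info) <- info$gene_id
  structure(list(info = info, exons = grl), class = "flat_models")
}
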