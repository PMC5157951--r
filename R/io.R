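#' Write an annotation to GTF
#'
#' Serializes the exon table through `rtracklayer` in the standard 1-based
#' closed GTF dialect, with `gene_id`, `transcript_id`, `gene_name`,
#' `gene_biotype` and `transcript_class` attributes.
#'
#' @param annotation a `toy_annotation` or exon data frame.
#' @param path output file path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ex <- as_exon_table(annotation)
  gr <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand,
                source = "hoxcis", type = "exon",
                gene_id = ex$gene_id, transcript_id = ex$transcript_id,
                gene_name = ex$gene_name, gene_biotype = ex$gene_biotype,
                transcript_class = ex$transcript_class)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation
#'
#' @param path GTF file with `gene_id`, `transcript_id`, `gene_biotype` and
#'   `transcript_class` attributes on exon records.
#' @return exon data frame in the shape accepted by [flatten_gene_models()].
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  mc <- mcols(gr)
  gene_name <- if ("gene_name" %in% names(mc)) mc$gene_name else mc$gene_id
  tclass <- if ("transcript_class" %in% names(mc)) mc$transcript_class else "protein_coding"
  data.frame(gene_id = mc$gene_id, gene_name = gene_name,
             gene_biotype = mc$gene_biotype,
             transcript_id = mc$transcript_id,
             transcript_class = tclass,
             chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write stranded coverage as bedGraph
#'
#' @param cov an `RleList` (per-chromosome run-length coverage) or a GRanges
#'   with a `score` column.
#' @param path output path (plain-text bedGraph, 0-based half-open).
#' @export
write_bedgraph <- function(cov, path) {
  if (is(cov, "RleList")) {
    gr <- as(cov, "GRanges")
    gr <- gr[gr$score != 0]
  } else {
    gr <- cov
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file.
#' @return GRanges with a `score` column (1-based closed internally).
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write / read repeat or region intervals as BED
#'
#' Named strand-aware intervals (regions) keep their name and strand in
#' columns 4 and 6; the repeat class travels in the name column as
#' `name|class`.
#'
#' @param gr GRanges (with optional `name`/`class` metadata).
#' @param path file path.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(gr$name)) gr$name else names(gr)
  if (is.null(nm)) nm <- paste0("iv", seq_along(gr))
  if (!is.null(gr$class)) nm <- paste0(nm, "|", gr$class)
  out <- gr
  out$name <- nm
  out$class <- NULL
  out$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- gr$name
  if (!is.null(nm) && any(grepl("|", nm, fixed = TRUE))) {
    parts <- strsplit(nm, "|", fixed = TRUE)
    gr$name <- vapply(parts, `[`, "", 1L)
    gr$class <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  }
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write alignments as SAM
#'
#' Emits single-end records with the mismatch count as an `NM` tag and the
#' number of reported hits as `NH` (1 for uniquely mapping reads). Sequence
#' and quality are omitted (`*`), as the downstream filters operate on tags
#' and CIGAR only.
#'
#' @param alignments data frame with columns `read_id`, `chrom`, `start`,
#'   `cigar`, `strand` (alignment strand), `nm`, `nh`.
#' @param path output SAM path.
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @export
write_sam <- function(alignments, path, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    mapq <- ifelse(alignments$nh == 1L, 50L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNM:i:%d\tNH:i:%d",
                       alignments$read_id, flag, alignments$chrom,
                       as.integer(alignments$start), mapq, alignments$cigar,
                       as.integer(alignments$nm), as.integer(alignments$nh)),
               con)
  }
  invisible(path)
}

#' Read a SAM/BAM file into an alignment table
#'
#' SAM text is converted through `Rsamtools::asBam()` and read with
#' `GenomicAlignments::readGAlignments()`; `NM` and `NH` tags are retained.
#'
#' @param path SAM or BAM file.
#' @return alignment data frame (`read_id`, `chrom`, `start`, `cigar`,
#'   `strand`, `nm`, `nh`).
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("qname"), tag = c("NM", "NH"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  nm <- mcols(ga)$NM
  nh <- mcols(ga)$NH
  nm[is.na(nm)] <- 0L
  nh[is.na(nh)] <- 1L
  data.frame(read_id = mcols(ga)$qname,
             chrom = as.character(seqnames(ga)),
             start = start(ga),
             cigar = GenomicAlignments::cigar(ga),
             strand = as.character(strand(ga)),
             nm = nm, nh = nh,
             stringsAsFactors = FALSE)
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
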