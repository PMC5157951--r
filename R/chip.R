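#' Define promoter regions
#'
#' Gene-level promoters anchored on the transcription start site of the
#' flattened model (5' end of the exon union on the gene's strand), or
#' transcript-level promoters anchored on each isoform's own TSS. In
#' `upstream2kb` mode the promoter is the `upstream` bases 5' of the TSS
#' (TSS excluded); in `centered4kb` mode it is the window of `2 * upstream`
#' bases centered on the TSS. Promoters are clipped to chromosome bounds.
#'
#' @param x a `flat_models` object (gene level) or a `toy_annotation` /
#'   exon data frame (transcript level when `level = "transcript"`).
#' @param mode `"upstream2kb"` or `"centered4kb"`.
#' @param upstream promoter extent in bp (default 2000).
#' @param chrom_lengths named vector used for clipping (optional).
#' @param level `"gene"` or `"transcript"`.
#' @return GRanges with metadata columns `gene_id` (and `transcript_id` at
#'   transcript level).
#' @export
define_promoters <- function(x, mode = c("upstream2kb", "centered4kb"),
                             upstream = 2000L, chrom_lengths = NULL,
                             level = c("gene", "transcript")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (level == "gene") {
    stopifnot(inherits(x, "flat_models"))
    info <- x$info
    tss <- ifelse(info$strand == "+",
                  vapply(x$exons, function(g) min(start(g)), 1L),
                  vapply(x$exons, function(g) max(end(g)), 1L))
    chrom <- info$chrom
    strand <- info$strand
    meta <- DataFrame(gene_id = info$gene_id)
  } else {
    ex <- as_exon_table(x)
    sp <- split(ex, ex$transcript_id)
    tss <- vapply(sp, function(d) {
      as.numeric(if (d$strand[1] == "+") min(d$start) else max(d$end))
    }, 1.0)
    chrom <- vapply(sp, function(d) d$chrom[1], "")
    strand <- vapply(sp, function(d) d$strand[1], "")
    meta <- DataFrame(gene_id = vapply(sp, function(d) d$gene_id[1], ""),
                      transcript_id = names(sp))
  }
  if (mode == "upstream2kb") {
    st <- ifelse(strand == "+", tss - upstream, tss + 1L)
    en <- ifelse(strand == "+", tss - 1L, tss + upstream)
  } else {
    st <- tss - upstream
    en <- tss + upstream - 1L
  }
  st <- pmax(st, 1L)
  if (!is.null(chrom_lengths)) {
    en <- pmin(en, unname(chrom_lengths[chrom]))
  }
  keep <- en >= st
  gr <- GRanges(chrom[keep], IRanges(st[keep], en[keep]), strand = strand[keep])
  mcols(gr) <- meta[keep, , drop = FALSE]
  gr
}

# coverage input (GRanges with score, or RleList) -> RleList
as_coverage_rle <- function(cov) {
  if (is(cov, "RleList")) return(cov)
  if (is(cov, "GRanges")) {
    if (is.null(cov$score)) stop("coverage GRanges needs a score column", call. = FALSE)
    return(coverage(cov, weight = "score"))
  }
  stop("coverage must be an RleList or a scored GRanges", call. = FALSE)
}

# mean per-base coverage of intervals, erroring on absent chromosomes
mean_coverage <- function(cov, gr) {
  rle <- as_coverage_rle(cov)
  miss <- setdiff(unique(as.character(seqnames(gr))), names(rle))
  if (length(miss)) {
    stop("coverage track lacks chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- numeric(length(gr))
  for (ch in unique(as.character(seqnames(gr)))) {
    idx <- which(as.character(seqnames(gr)) == ch)
    r <- rle[[ch]]
    for (k in idx) {
      st <- start(gr)[k]
      en <- min(end(gr)[k], length(r))
      out[k] <- if (en >= st) mean(window(r, st, en)) else 0
    }
  }
  out
}

#' Score promoters for H3K27me3 enrichment
#'
#' Computes the mean per-base ChIP and input coverage over each promoter,
#' normalizes both by the total number of million mapped reads of the
#' respective library, forms the ChIP/input ratio (with a pseudocount added
#' to the normalized input mean so that zero-input promoters keep a finite,
#' monotone ratio), and flags promoters intersected by any repeat of class
#' Satellite (matched case-insensitively on the repeat class/name).
#'
#' @param chip,input coverage tracks (scored GRanges from a bedGraph, or
#'   RleList) of raw per-base read coverage.
#' @param promoters GRanges from [define_promoters()].
#' @param repeats GRanges of repeats with a `class` (or `name`) column;
#'   `NULL` for none.
#' @param chip_total_reads,input_total_reads total mapped reads of each
#'   library.
#' @param pseudocount added to the normalized input mean (default 0.01).
#' @return data frame: `gene_id` (+ `transcript_id` if present), `chrom`,
#'   `start`, `end`, `strand`, `chip_mean`, `input_mean` (normalized per
#'   million mapped reads), `ratio`, `satellite_overlap`.
#' @export
score_promoters <- function(chip, input, promoters, repeats = NULL,
                            chip_total_reads, input_total_reads,
                            pseudocount = 0.01) {
  chip_mean <- mean_coverage(chip, promoters) / (chip_total_reads / 1e6)
  input_mean <- mean_coverage(input, promoters) / (input_total_reads / 1e6)
  sat <- rep(FALSE, length(promoters))
  if (!is.null(repeats) && length(repeats)) {
    cls <- repeats$class
    if (is.null(cls)) cls <- repeats$name
    if (is.null(cls)) cls <- rep("", length(repeats))
    sat_rep <- repeats[grepl("satellite", cls, ignore.case = TRUE)]
    sat <- overlapsAny(promoters, sat_rep, ignore.strand = TRUE)
  }
  out <- data.frame(gene_id = promoters$gene_id,
                    chrom = as.character(seqnames(promoters)),
                    start = start(promoters), end = end(promoters),
                    strand = as.character(strand(promoters)),
                    chip_mean = chip_mean, input_mean = input_mean,
                    ratio = chip_mean / (input_mean + pseudocount),
                    satellite_overlap = sat,
                    stringsAsFactors = FALSE)
  if (!is.null(promoters$transcript_id)) {
    out$transcript_id <- promoters$transcript_id
  }
  out
}

#' Call putative Polycomb target genes
#'
#' A promoter passes iff its ChIP/input ratio is at least `ratio_min`, its
#' normalized ChIP coverage is at least `cov_min` (both thresholds
#' inclusive) and it is not overlapped by a satellite repeat. At transcript
#' level a gene is a target if any of its promoters passes.
#'
#' @param scores data frame from [score_promoters()].
#' @param ratio_min minimum ChIP/input ratio (default 5).
#' @param cov_min minimum normalized ChIP coverage (default 0.1).
#' @return list with `targets` (character vector of gene ids) and `scores`
#'   (the input with an `is_target` column).
#' @export
call_targets <- function(scores, ratio_min = 5.0, cov_min = 0.1) {
  pass <- scores$ratio >= ratio_min & scores$chip_mean >= cov_min &
    !scores$satellite_overlap
  scores$is_target <- pass
  list(targets = sort(unique(scores$gene_id[pass])), scores = scores)
}
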