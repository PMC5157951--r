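#' Compute RPKM expression levels
#'
#' RPKM(g, s) = count(g, s) / (exonic_length(g) / 1000) / (total(s) / 1e6),
#' with the flattened exonic length as gene length and the nuclear mapped
#' read total as the per-sample denominator.
#'
#' @param counts integer matrix genes x samples (or the list returned by
#'   [count_unique_reads()], in which case `totals` is taken from it).
#' @param models a `flat_models` object covering every counted gene.
#' @param totals named per-sample totals of nuclear mapped reads.
#' @return numeric matrix of RPKM values, same dimnames as `counts`.
#' @export
compute_rpkm <- function(counts, models, totals = NULL) {
  if (is.list(counts) && !is.null(counts$counts)) {
    if (is.null(totals)) totals <- counts$totals
    counts <- counts$counts
  }
  stopifnot(inherits(models, "flat_models"), is.matrix(counts))
  if (is.null(totals)) stop("per-sample totals are required", call. = FALSE)
  totals <- totals[colnames(counts)]
  if (any(is.na(totals)) || any(totals <= 0)) {
    stop("every sample needs a positive mapped-read total", call. = FALSE)
  }
  miss <- setdiff(rownames(counts), models$info$gene_id)
  if (length(miss)) {
    stop("no flattened model for gene(s): ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  len <- models$info[rownames(counts), "exonic_length"]
  if (any(len <= 0)) stop("gene with zero exonic length", call. = FALSE)
  sweep(counts / (len / 1000), 2, totals / 1e6, "/")
}

#' Select rank-stable mid-expressed standard genes
#'
#' Identifies the normalization standard: the `n_standard` genes with the
#' least expression *rank* variation across samples among genes whose
#' median RPKM lies in the central (by default 25--75%) range of all
#' per-gene median RPKMs. Rank variation is the standard deviation across
#' samples of the gene's within-sample expression rank (average ranks for
#' ties); ties in the score are broken by gene identifier.
#'
#' @param rpkm RPKM matrix genes x samples.
#' @param n_standard number of standard genes (default 100).
#' @param q_low,q_high quantile window applied to the per-gene median RPKM.
#' @return list with `gene_ids` (length `n_standard`) and `scores` (data
#'   frame: `gene_id`, `median_rpkm`, `rank_sd`, `eligible`).
#' @export
select_standard_genes <- function(rpkm, n_standard = 100L,
                                  q_low = 0.25, q_high = 0.75) {
  stopifnot(is.matrix(rpkm), ncol(rpkm) >= 2)
  med <- apply(rpkm, 1, median)
  qs <- quantile(med, c(q_low, q_high))
  eligible <- med >= qs[1] & med <= qs[2]
  ranks <- apply(rpkm, 2, rank, ties.method = "average")
  rank_sd <- apply(ranks, 1, sd)
  scores <- data.frame(gene_id = rownames(rpkm), median_rpkm = med,
                       rank_sd = rank_sd, eligible = eligible,
                       stringsAsFactors = FALSE)
  n_el <- sum(eligible)
  if (n_el < n_standard) {
    stop("only ", n_el, " genes fall in the expression window; ",
         n_standard, " required (shortfall ", n_standard - n_el, ")",
         call. = FALSE)
  }
  el <- scores[eligible, ]
  el <- el[order(el$rank_sd, el$gene_id), ]
  list(gene_ids = el$gene_id[seq_len(n_standard)], scores = scores)
}

#' Median-scaling normalization against a standard gene set
#'
#' Per sample `s`, `m(s)` is the median RPKM of the standard genes; the
#' reference level `R` is the median of `m(s)` over samples; the scale
#' factor is `f(s) = R / m(s)` and normalized values are `rpkm * f(s)`.
#' After normalization the standard-gene median is identical (= R) in every
#' sample.
#'
#' @param rpkm RPKM matrix genes x samples.
#' @param standard the list returned by [select_standard_genes()], or a
#'   character vector of standard gene ids.
#' @return list with `normalized` (matrix), `scale_factors` (named vector)
#'   and `reference` (the common standard-gene median).
#' @export
median_scale_normalize <- function(rpkm, standard) {
  genes <- if (is.list(standard)) standard$gene_ids else standard
  miss <- setdiff(genes, rownames(rpkm))
  if (length(miss)) {
    stop("standard genes absent from the expression table: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  m <- apply(rpkm[genes, , drop = FALSE], 2, median)
  if (any(m == 0)) {
    stop("standard-gene median is zero in sample(s): ",
         paste(names(m)[m == 0], collapse = ", "), call. = FALSE)
  }
  R <- median(m)
  f <- R / m
  list(normalized = sweep(rpkm, 2, f, "*"), scale_factors = f, reference = R)
}
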