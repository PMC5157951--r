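#' Centered PCA of expression profiles
#'
#' Principal component analysis of `log2(RPKM + 1)` expression levels for
#' the genes passing the expression filter (RPKM above `rpkm_min` in at
#' least one sample). Genes are centered — the mean expression of each
#' gene is brought to zero, removing between-gene level differences — but
#' not scaled, so highly variable genes keep their weight.
#'
#' @param rpkm expression matrix genes x samples.
#' @param rpkm_min expression filter (default 1).
#' @param genes optional gene subset applied before the filter (e.g.
#'   protein-coding genes only).
#' @return list with `scores` (samples x components), `var_prop`
#'   (per-component proportion of variance), `sdev` and `genes_used`.
#' @export
pca_expression <- function(rpkm, rpkm_min = 1.0, genes = NULL) {
  if (!is.null(genes)) rpkm <- rpkm[intersect(genes, rownames(rpkm)), , drop = FALSE]
  stopifnot(ncol(rpkm) >= 2)
  keep <- apply(rpkm, 1, max) > rpkm_min
  if (sum(keep) < 2) stop("fewer than 2 genes pass the expression filter",
                          call. = FALSE)
  x <- t(log2(rpkm[keep, , drop = FALSE] + 1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  var_prop <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_prop = var_prop, sdev = pc$sdev,
       genes_used = rownames(rpkm)[keep])
}

#' Euclidean sample distances and hierarchical clustering
#'
#' Pairwise Euclidean distances between samples on `log2(RPKM + 1)` values,
#' clustered agglomeratively (complete linkage by default).
#'
#' @param rpkm expression matrix genes x samples.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `dist` (a `dist` object) and `hclust`.
#' @export
sample_distance_clustering <- function(rpkm, linkage = "complete") {
  d <- dist(t(log2(rpkm + 1)), method = "euclidean")
  list(dist = d, hclust = hclust(d, method = linkage))
}

#' Correlations between replicate samples
#'
#' Pearson and Spearman correlations of `log2(RPKM + 1)` values between
#' replicate pairs, over the expressed genes (RPKM above `expressed_rpkm`
#' in at least one sample of the pair).
#'
#' @param rpkm expression matrix.
#' @param pairs data frame with columns `sample_a`, `sample_b`.
#' @param expressed_rpkm expression filter (default 1).
#' @return data frame: `sample_a`, `sample_b`, `n_genes`, `pearson`,
#'   `spearman`.
#' @export
replicate_correlation <- function(rpkm, pairs, expressed_rpkm = 1.0) {
  stopifnot(all(c("sample_a", "sample_b") %in% names(pairs)))
  out <- pairs
  out$n_genes <- 0L
  out$pearson <- out$spearman <- NA_real_
  for (k in seq_len(nrow(pairs))) {
    a <- rpkm[, pairs$sample_a[k]]
    b <- rpkm[, pairs$sample_b[k]]
    keep <- pmax(a, b) > expressed_rpkm
    out$n_genes[k] <- sum(keep)
    if (sum(keep) < 3) {
      warning("fewer than 3 expressed genes for pair ", pairs$sample_a[k],
              " / ", pairs$sample_b[k])
      next
    }
    la <- log2(a[keep] + 1)
    lb <- log2(b[keep] + 1)
    out$pearson[k] <- cor(la, lb)
    out$spearman[k] <- cor(la, lb, method = "spearman")
  }
  out
}

#' Construct a GO-enrichment background gene list
#'
#' The background contains every gene sequenced at least as deeply as the
#' least-covered differentially expressed gene: the threshold is the
#' minimum, over the DE genes, of the read counts summed across the
#' relevant samples, and all genes with an equal or higher summed count
#' are kept (the DE genes are therefore always a subset).
#'
#' @param de_genes character vector of differentially expressed gene ids.
#' @param counts integer matrix genes x samples.
#' @param relevant_samples sample columns to sum over.
#' @param genes optional restriction (e.g. protein-coding gene ids).
#' @return list with `background` (character vector) and `threshold`.
#' @export
build_go_background <- function(de_genes, counts, relevant_samples,
                                genes = NULL) {
  if (!length(de_genes)) stop("de_genes must be non-empty", call. = FALSE)
  miss <- setdiff(de_genes, rownames(counts))
  if (length(miss)) {
    stop("DE gene(s) absent from the count table: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  stopifnot(length(relevant_samples) >= 1,
            all(relevant_samples %in% colnames(counts)))
  sums <- rowSums(counts[, relevant_samples, drop = FALSE])
  threshold <- min(sums[de_genes])
  bg <- rownames(counts)[sums >= threshold]
  if (!is.null(genes)) bg <- union(intersect(bg, genes), de_genes)
  list(background = bg, threshold = threshold)
}

#' Pearson chi-square test on a contingency table
#'
#' Thin wrapper around [stats::chisq.test()] with no continuity correction
#' by default (matching the reporting convention for the vertebral-formula
#' and DE-direction tables), validating the table shape and margins.
#'
#' @param tab matrix of non-negative counts, at least 2x2.
#' @param continuity apply the Yates correction (2x2 only).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_contingency <- function(tab, continuity = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2", call. = FALSE)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (sum(tab) <= 0) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = continuity))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Hypergeometric gene-set enrichment
#'
#' Plain hypergeometric over-representation test of a gene set within a
#' focal list against a background, provided as convenience plumbing for
#' user-supplied gene-to-term maps. This is a generic tail probability,
#' not a re-implementation of any dedicated GO enrichment tool.
#'
#' @param focal character vector (e.g. up-regulated genes).
#' @param set character vector (genes annotated to a term).
#' @param background character vector containing `focal`.
#' @return list with `overlap`, `expected`, `p_value`.
#' @export
enrichment_hypergeometric <- function(focal, set, background) {
  focal <- intersect(focal, background)
  set <- intersect(set, background)
  q <- length(intersect(focal, set))
  p <- phyper(q - 1, length(set), length(background) - length(set),
              length(focal), lower.tail = FALSE)
  list(overlap = q, expected = length(focal) * length(set) / length(background),
       p_value = p)
}

#' Vertebral-formula phenotype counts
#'
#' Bundled published skeletal scoring of the lumbar region for wild-type,
#' heterozygous and homozygous Hotair-deletion animals at postnatal day 22:
#' numbers of animals with six lumbar vertebrae (L6), a mixed L6/S1
#' vertebra, or five lumbar vertebrae (L5).
#'
#' @return 3x3 integer matrix (genotype x vertebral class).
#' @export
vertebral_phenotype_counts <- function() {
  m <- matrix(c(1L, 2L, 8L,
                1L, 1L, 9L,
                1L, 1L, 8L), nrow = 3, byrow = TRUE,
              dimnames = list(c("wt", "het", "hom"), c("L6", "L6_S1", "L5")))
  m
}

#' Direction of differential expression for Polycomb targets
#'
#' Bundled published summary of the posterior-trunk (T3) comparison:
#' numbers of up- and down-regulated genes among expressed putative
#' Polycomb targets and among expressed non-target protein-coding genes
#' (fold change > 1.5, FDR < 10%).
#'
#' @return 2x2 integer matrix (set x direction).
#' @export
polycomb_de_direction_counts <- function() {
  matrix(c(10L, 50L,
           141L, 423L), nrow = 2, byrow = TRUE,
         dimnames = list(c("pc_target", "non_target"), c("up", "down")))
}
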