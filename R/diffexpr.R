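#' Median-of-ratios size factors
#'
#' Computes per-sample scaling constants: for each gene with strictly
#' positive counts in all samples, the ratio of its count to its geometric
#' mean across samples is taken; the size factor of a sample is the median
#' of these ratios.
#'
#' @param counts integer matrix genes x samples.
#' @param allow_pseudo_reference if no gene is positive in every sample,
#'   fall back to a pseudo-reference built from the geometric mean over the
#'   non-zero entries of each gene (instead of erroring).
#' @return named numeric vector of size factors.
#' @export
estimate_size_factors <- function(counts, allow_pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    if (!allow_pseudo_reference) {
      stop("no gene has positive counts in every sample; re-run with ",
           "allow_pseudo_reference = TRUE to use a pseudo-reference",
           call. = FALSE)
    }
    keep <- rowSums(counts > 0) > 0
    ref <- apply(counts[keep, , drop = FALSE], 1, function(x) {
      exp(mean(log(x[x > 0])))
    })
    ratios <- counts[keep, , drop = FALSE] / ref
    return(apply(ratios, 2, function(r) median(r[r > 0])))
  }
  sub <- counts[allpos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  apply(sub / ref, 2, median)
}

#' Negative-binomial GLM likelihood-ratio test of a genotype effect
#'
#' For each gene, contrasts a log-link negative-binomial GLM explaining the
#' counts as a function of the genotype (full model: intercept + genotype,
#' with `log(size factor)` offsets) against an intercept-only null model.
#' The LRT statistic `2 (ll_full - ll_null)` is referred to a chi-square
#' distribution with 1 df; the log2 fold change is the fitted genotype
#' coefficient divided by `ln 2`.
#'
#' Dispersions are method-of-moments estimates on size-factor-normalized
#' counts (pooled within-genotype variance), shared between the full and
#' null fits and floored at `dispersion_floor`. With few replicates the
#' per-gene estimates are too noisy to calibrate the chi-square reference,
#' so the default (`dispersion_method = "common"`) plugs in the mean of the
#' positive per-gene estimates across all genes — a common-dispersion
#' moment estimator; `"per_gene"` uses each gene's own estimate.
#'
#' @param counts integer matrix genes x samples for one tissue.
#' @param genotype factor/character of length `ncol(counts)`; the first
#'   level is the reference (wild type).
#' @param size_factors per-sample factors; estimated with
#'   [estimate_size_factors()] when `NULL`.
#' @param dispersion_method `"common"` (default) or `"per_gene"`.
#' @param dispersion_floor lower bound on the dispersion.
#' @param test `"lrt"` (default) or `"wald"` (asymptotic normal on the
#'   genotype coefficient, as a control).
#' @return data frame per gene: `gene_id`, `base_mean` (mean normalized
#'   count), `log2fc`, `dispersion`, `stat`, `pvalue`, `tested`.
#' @export
fit_nb_lrt <- function(counts, genotype, size_factors = NULL,
                       dispersion_method = c("common", "per_gene"),
                       dispersion_floor = 1e-8,
                       test = c("lrt", "wald")) {
  dispersion_method <- match.arg(dispersion_method)
  test <- match.arg(test)
  stopifnot(is.matrix(counts))
  if (!is.factor(genotype)) genotype <- factor(genotype, levels = unique(genotype))
  if (nlevels(genotype) != 2) stop("exactly two genotype groups required", call. = FALSE)
  if (any(table(genotype) < 2)) {
    stop("at least two replicates per genotype are required", call. = FALSE)
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  size_factors <- size_factors[colnames(counts)]
  if (any(is.na(size_factors)) || any(size_factors <= 0)) {
    stop("positive size factors required for every sample", call. = FALSE)
  }

  norm <- sweep(counts, 2, size_factors, "/")
  g1 <- genotype == levels(genotype)[1]
  phi_gene <- apply(norm, 1, function(y) {
    vw <- mean(c(var(y[g1]), var(y[!g1])))
    m <- mean(y)
    if (m <= 0) return(NA_real_)
    (vw - m) / m^2
  })
  phi_common <- mean(pmax(phi_gene, 0), na.rm = TRUE)
  if (!is.finite(phi_common)) phi_common <- dispersion_floor
  phi_used <- switch(dispersion_method,
                     common = rep(phi_common, nrow(counts)),
                     per_gene = phi_gene)
  phi_used <- pmax(phi_used, dispersion_floor)

  off <- log(size_factors)
  x <- as.integer(genotype == levels(genotype)[2])
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = NA_real_, dispersion = phi_used,
                    stat = NA_real_, pvalue = NA_real_,
                    tested = FALSE, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    if (all(y == 0)) {
      res$dispersion[g] <- NA_real_
      next
    }
    fit <- nb_contrast_fit(y, x, off, phi_used[g], test)
    if (is.null(fit)) next
    res$log2fc[g] <- fit["log2fc"]
    res$stat[g] <- fit["stat"]
    res$pvalue[g] <- fit["p"]
    res$tested[g] <- TRUE
  }
  rownames(res) <- NULL
  res
}

# one-gene NB GLM contrast with fixed dispersion phi; glm first, direct
# likelihood maximisation as a step-halving fallback
nb_contrast_fit <- function(y, x, off, phi, test = "lrt") {
  theta <- 1 / phi
  fam <- MASS::negative.binomial(theta = theta)
  ctrl <- glm.control(epsilon = 1e-12, maxit = 100)
  full <- tryCatch(suppressWarnings(
    glm(y ~ x + offset(off), family = fam, control = ctrl)), error = function(e) NULL)
  null <- tryCatch(suppressWarnings(
    glm(y ~ 1 + offset(off), family = fam, control = ctrl)), error = function(e) NULL)
  ll <- function(beta, xx) {
    mu <- exp(off + beta[1] + if (length(beta) > 1) beta[2] * xx else 0)
    sum(dnbinom(y, mu = mu, size = theta, log = TRUE))
  }
  if (is.null(full) || is.null(null) || !full$converged || !null$converged) {
    b0 <- log(max(mean(y), 0.5))
    o_full <- tryCatch(optim(c(b0, 0), function(b) -ll(b, x),
                             method = "BFGS"), error = function(e) NULL)
    o_null <- tryCatch(optim(b0, function(b) -ll(b, x), method = "BFGS"),
                       error = function(e) NULL)
    if (is.null(o_full) || is.null(o_null)) return(NULL)
    stat <- max(2 * (o_null$value - o_full$value), 0)
    lfc <- o_full$par[2] / log(2)
    if (test == "wald") return(NULL)  # fallback supports the LRT only
    return(c(log2fc = lfc, stat = stat,
             p = pchisq(stat, df = 1, lower.tail = FALSE)))
  }
  lfc <- unname(coef(full)[2]) / log(2)
  if (test == "wald") {
    se <- unname(sqrt(diag(suppressWarnings(vcov(full))))[2])
    z <- unname(coef(full)[2]) / se
    return(c(log2fc = lfc, stat = z^2, p = 2 * pnorm(-abs(z))))
  }
  # likelihoods evaluated directly at the fitted means: the family deviance
  # loses precision to cancellation when theta is huge (Poisson limit)
  ll_full <- sum(dnbinom(y, mu = fitted(full), size = theta, log = TRUE))
  ll_null <- sum(dnbinom(y, mu = fitted(null), size = theta, log = TRUE))
  stat <- max(2 * (ll_full - ll_null), 0)
  c(log2fc = lfc, stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Joint Benjamini-Hochberg adjustment
#'
#' Standard BH step-up on the pooled vector of all (gene, tissue) p-values
#' at once, so that the FDR of a gene in one tissue depends on the p-values
#' observed in every other tissue. `NA` entries (untested genes) are
#' excluded from the denominator and preserved as `NA`.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return vector of adjusted values, same length and order.
#' @export
adjust_fdr_joint <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Classify differential expression calls
#'
#' `up` if `FDR < fdr_threshold` and fold change `> fc_threshold`; `down`
#' if `FDR < fdr_threshold` and fold change `< 1/fc_threshold`; `ns`
#' otherwise; `not_tested` where the p-value is missing. Thresholds are
#' strict inequalities, so a fold change of exactly `fc_threshold` is `ns`.
#'
#' @param log2fc,fdr numeric vectors.
#' @param fc_threshold fold-change threshold on the natural scale (1.5).
#' @param fdr_threshold FDR threshold (0.05; relaxed to 0.10 for the
#'   gene-set analyses).
#' @return character vector in `{up, down, ns, not_tested}`.
#' @export
classify_de <- function(log2fc, fdr, fc_threshold = 1.5, fdr_threshold = 0.05) {
  fc <- 2^log2fc
  out <- rep("ns", length(log2fc))
  out[!is.na(fdr) & fdr < fdr_threshold & fc > fc_threshold] <- "up"
  out[!is.na(fdr) & fdr < fdr_threshold & fc < 1 / fc_threshold] <- "down"
  out[is.na(fdr) | is.na(log2fc)] <- "not_tested"
  out
}

#' Per-tissue differential expression with joint FDR
#'
#' Orchestrates the genotype contrast for every tissue of the design:
#' size factors per tissue, NB GLM likelihood-ratio tests, one joint BH
#' correction across all tissues, and fold-change/FDR classification.
#'
#' @param counts integer matrix genes x samples.
#' @param samples design data frame (`sample_id`, `tissue`, `genotype`).
#' @param fc_threshold,fdr_threshold classification thresholds.
#' @param ... passed to [fit_nb_lrt()] (e.g. `test`, `dispersion_method`).
#' @return long data frame: `gene_id`, `tissue`, `base_mean`, `log2fc`,
#'   `dispersion`, `stat`, `pvalue`, `fdr`, `class`.
#' @export
run_de <- function(counts, samples, fc_threshold = 1.5, fdr_threshold = 0.05,
                   ...) {
  stopifnot(all(samples$sample_id %in% colnames(counts)))
  parts <- lapply(unique(samples$tissue), function(t) {
    sel <- samples[samples$tissue == t, ]
    sub <- counts[, sel$sample_id, drop = FALSE]
    geno <- factor(sel$genotype, levels = unique(samples$genotype))
    de <- fit_nb_lrt(sub, geno, ...)
    de$tissue <- t
    de
  })
  de <- do.call(rbind, parts)
  de$fdr <- adjust_fdr_joint(de$pvalue)
  de$class <- classify_de(de$log2fc, de$fdr, fc_threshold, fdr_threshold)
  de[, c("gene_id", "tissue", "base_mean", "log2fc", "dispersion",
         "stat", "pvalue", "fdr", "class")]
}

#' Summarise differential expression inside a gene set
#'
#' Restricts a tissue's DE results to a gene set (e.g. putative Polycomb
#' targets or imprinted genes), applies the expression filter (RPKM above
#' `expressed_rpkm` in at least one sample of the tissue, either genotype),
#' counts up/down/DE genes and tests the up-versus-down direction against
#' the complement set with a Pearson chi-square (2x2, no continuity
#' correction).
#'
#' @param de DE results for one tissue (rows of [run_de()] output).
#' @param gene_set character vector of gene ids.
#' @param rpkm (normalized) RPKM matrix.
#' @param sample_ids the tissue's sample columns in `rpkm`.
#' @param expressed_rpkm expression filter threshold (default 1).
#' @return list with `n_expressed`, `n_de`, `n_up`, `n_down`, `percent_up`,
#'   `table` (2x2 direction-by-set counts), `chisq_stat`, `p_value`.
#' @export
subset_summary <- function(de, gene_set, rpkm, sample_ids,
                           expressed_rpkm = 1.0) {
  stopifnot(all(sample_ids %in% colnames(rpkm)))
  expressed <- rownames(rpkm)[apply(rpkm[, sample_ids, drop = FALSE], 1, max) >
                                expressed_rpkm]
  in_set <- intersect(gene_set, expressed)
  out_set <- setdiff(expressed, gene_set)
  cls <- setNames(de$class, de$gene_id)
  count_dir <- function(g) {
    c(up = sum(cls[g] == "up", na.rm = TRUE),
      down = sum(cls[g] == "down", na.rm = TRUE))
  }
  ins <- count_dir(in_set)
  outs <- count_dir(out_set)
  n_de <- sum(ins)
  res <- list(n_expressed = length(in_set), n_de = n_de,
              n_up = unname(ins["up"]), n_down = unname(ins["down"]),
              percent_up = if (n_de > 0) 100 * ins[["up"]] / n_de else NA_real_,
              table = rbind(set = ins, complement = outs),
              chisq_stat = NA_real_, p_value = NA_real_)
  if (length(in_set) == 0 || length(out_set) == 0) {
    warning("degenerate gene-set split; direction test skipped")
    return(res)
  }
  tab <- res$table
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in the direction table; test skipped")
    return(res)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  res$chisq_stat <- unname(ct$statistic)
  res$p_value <- ct$p.value
  res
}
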