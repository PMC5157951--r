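# Independent oracles and small builders used across the test files.
# Each oracle recomputes the quantity by brute force (per-base enumeration,
# textbook step-up, closed-form likelihood), never through the package
# functions it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# textbook Benjamini-Hochberg step-up, computed by hand
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  adj
}

# per-base union size of a list of (start, end) interval pairs
union_size <- function(starts, ends) {
  if (!length(starts)) return(0L)
  v <- logical(max(ends))
  for (k in seq_along(starts)) v[starts[k]:ends[k]] <- TRUE
  sum(v)
}

# closed-form Poisson GLM LRT with offsets (two groups)
poisson_lrt_oracle <- function(y, is_del, sf) {
  ll <- function(mu) sum(dpois(y, lambda = sf * mu, log = TRUE))
  m_full_wt <- sum(y[!is_del]) / sum(sf[!is_del])
  m_full_del <- sum(y[is_del]) / sum(sf[is_del])
  m_null <- sum(y) / sum(sf)
  mu_full <- ifelse(is_del, m_full_del, m_full_wt)
  ll_full <- sum(dpois(y, lambda = sf * mu_full, log = TRUE))
  ll_null <- ll(m_null)
  list(stat = 2 * (ll_full - ll_null),
       log2fc = log2(m_full_del / m_full_wt))
}

# per-base mean coverage of an interval from a scored GRanges track
brute_mean_cov <- function(track, chrom, from, to) {
  vals <- numeric(to - from + 1)
  tr <- track[as.character(seqnames(track)) == chrom]
  for (k in seq_along(tr)) {
    lo <- max(from, start(tr)[k]); hi <- min(to, end(tr)[k])
    if (lo <= hi) vals[(lo:hi) - from + 1] <- vals[(lo:hi) - from + 1] + tr$score[k]
  }
  mean(vals)
}

# minimal exon-table builder: one row per exon
toy_exons <- function(gene_id, transcript_id, starts, ends, strand = "+",
                      biotype = "protein_coding", tclass = "protein_coding",
                      chrom = "chrT") {
  data.frame(gene_id = gene_id, gene_name = gene_id, gene_biotype = biotype,
             transcript_id = transcript_id, transcript_class = tclass,
             chrom = chrom, start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

# minimal alignment-table builder
toy_aln <- function(start, cigar = "100M", strand = "+", nm = 0L, nh = 1L,
                    chrom = "chrT", read_id = NULL) {
  n <- max(length(start), length(cigar), length(strand), length(nm))
  data.frame(read_id = if (is.null(read_id)) sprintf("r%d", seq_len(n)) else read_id,
             chrom = chrom, start = start, cigar = cigar, strand = strand,
             nm = nm, nh = nh, stringsAsFactors = FALSE)
}

# small simulation shared by several test files
small_sim <- function(seed = 5, n_bg = 40, lib = 3000, ...) {
  cfg <- sim_config(seed = seed, n_background_genes = n_bg,
                    library_size_mean = lib, ...)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  list(cfg = cfg, ann = ann, sim = sim)
}
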