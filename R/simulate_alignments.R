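#' Simulate stranded single-end alignments and coverage
#'
#' Turns a simulated count table into aligned single-end records. Each
#' counted read is placed uniformly along its gene's transcript (exon-block
#' aware: reads crossing an exon junction or a deletion breakpoint become
#' two-block `M N M` records, as a spliced aligner would report them) in
#' wild-type reference coordinates. Under the default dUTP/TruSeq stranded
#' convention the alignment strand is *opposite* to the transcript strand.
#' For deletion-allele samples, a `readthrough_rate` fraction of Hotair
#' transcripts initiated at the surviving start sites extend across the
#' former position of the deleted segment to near the Hoxc12 termination
#' site (the Ghostair product), and AntiHotair transcripts extend to the
#' Hoxc11 start (long AntiHotair). Contaminant reads (more than 2
#' mismatches, small indels, and reads spanning two same-strand overlapping
#' genes) are injected on top of the clean counts at the configured rates.
#'
#' @param sim a `sim_counts` object (or a list with `counts` and `samples`).
#' @param annotation the matching `toy_annotation`.
#' @param config the [sim_config()] used throughout.
#' @return object of class `sim_alignments`: list with `alignments` (named
#'   list of per-sample data frames: `read_id`, `chrom`, `start`, `cigar`,
#'   `strand`, `nm`, `nh`), `coverage` (per sample, list of `plus`/`minus`
#'   RleLists keyed by *alignment* strand), `totals` (all nuclear mapped
#'   reads per sample) and `clean_totals` (reads traceable to the count
#'   table).
#' @export
simulate_alignments <- function(sim, annotation, config = sim_config()) {
  stopifnot(inherits(annotation, "toy_annotation"), inherits(config, "sim_config"))
  counts <- sim$counts
  samples <- sim$samples
  stopifnot(is.matrix(counts), is.data.frame(samples))
  set.seed(config$seed + 2L)
  genes <- annotation_genes(annotation)
  unknown <- setdiff(rownames(counts), genes$gene_id)
  if (length(unknown)) {
    stop("counts reference unknown genes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  chrom <- annotation$layout$chrom
  rl <- config$read_length
  flip <- config$library_strandedness == "antisense"
  locus_units <- intersect(names(annotation$layout$base_weight), rownames(counts))

  # primary transcript blocks for background genes (mature mRNA of the
  # first non-retained isoform)
  ex <- annotation$exons
  bg_blocks <- lapply(setdiff(rownames(counts), locus_units), function(g) {
    d <- ex[ex$gene_id == g & ex$transcript_class != "retained_intron", ]
    d <- d[d$transcript_id == d$transcript_id[1], ]
    list(ir = IRanges(sort(d$start), sort(d$end)), strand = d$strand[1])
  })
  names(bg_blocks) <- setdiff(rownames(counts), locus_units)

  out_aln <- vector("list", nrow(samples))
  out_cov <- vector("list", nrow(samples))
  totals <- clean_totals <- setNames(integer(nrow(samples)), samples$sample_id)

  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    geno <- samples$genotype[s]
    acc_start <- acc_nread <- integer(0)
    acc_cigar <- acc_id <- acc_strand <- character(0)
    acc_blocks <- list()
    acc_bstrand <- character(0)
    running <- 0L
    for (g in rownames(counts)) {
      n <- counts[g, s]
      if (n == 0) next
      if (g %in% locus_units) {
        tx_strand <- locus_unit_strand(g)
        if (geno != "wt" && g %in% c("Hotair", "AHotair")) {
          n_rt <- rbinom(1L, n, config$readthrough_rate)
          parts <- list(
            list(ir = locus_transcript_blocks(annotation$layout, g, "del", "readthrough"), n = n_rt),
            list(ir = locus_transcript_blocks(annotation$layout, g, "del", "truncated"), n = n - n_rt))
        } else {
          parts <- list(list(ir = locus_transcript_blocks(annotation$layout, g, geno), n = n))
        }
      } else {
        tx_strand <- bg_blocks[[g]]$strand
        parts <- list(list(ir = bg_blocks[[g]]$ir, n = n))
      }
      aln_strand <- if (flip) chartr("+-", "-+", tx_strand) else tx_strand
      for (p in parts) {
        if (p$n == 0) next
        pl <- place_reads(p$ir, p$n, rl)
        acc_id <- c(acc_id, sprintf("%s:%s:%d", sid, g, running + seq_len(p$n)))
        running <- running + p$n
        acc_start <- c(acc_start, pl$start)
        acc_cigar <- c(acc_cigar, pl$cigar)
        acc_strand <- c(acc_strand, rep(aln_strand, p$n))
        acc_blocks[[length(acc_blocks) + 1L]] <- pl$blocks
        acc_bstrand <- c(acc_bstrand, rep(aln_strand, length(pl$blocks)))
      }
    }
    clean <- data.frame(read_id = acc_id,
                        chrom = rep(chrom, length(acc_id)),
                        start = acc_start, cigar = acc_cigar,
                        strand = acc_strand,
                        nm = rep(0L, length(acc_id)),
                        nh = rep(1L, length(acc_id)),
                        stringsAsFactors = FALSE)
    clean_totals[s] <- nrow(clean)

    # contaminants: reads spanning the planted same-strand overlapping pair
    ctm <- list()
    lib_n <- max(clean_totals[s], 1L)
    if (config$multi_overlap_rate > 0 && "bgOvlA" %in% genes$gene_id) {
      n_mo <- round(config$multi_overlap_rate * lib_n)
      if (n_mo > 0) {
        st <- 161801L + floor(runif(n_mo, 0, 300L - rl + 1L))
        ctm[[length(ctm) + 1L]] <- data.frame(
          read_id = sprintf("%s:ovl:%d", sid, seq_len(n_mo)),
          chrom = chrom, start = st, cigar = paste0(rl, "M"),
          strand = if (flip) "-" else "+", nm = 0L, nh = 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (config$high_mismatch_rate > 0 && length(bg_blocks)) {
      n_hm <- round(config$high_mismatch_rate * lib_n)
      if (n_hm > 0) {
        host <- sample(names(bg_blocks), n_hm, replace = TRUE)
        st <- vapply(host, function(g) {
          ir <- bg_blocks[[g]]$ir
          start(ir)[1] + floor(runif(1, 0, max(width(ir)[1] - rl, 1)))
        }, 1)
        mm <- seq_len(n_hm) %% 2 == 0
        tx_str <- sample(c("+", "-"), n_hm, replace = TRUE)
        ctm[[length(ctm) + 1L]] <- data.frame(
          read_id = sprintf("%s:mm:%d", sid, seq_len(n_hm)),
          chrom = chrom, start = as.integer(st),
          cigar = ifelse(mm, paste0(rl, "M"),
                         sprintf("%dM1I%dM", rl %/% 2, rl - rl %/% 2 - 1L)),
          strand = if (flip) chartr("+-", "-+", tx_str) else tx_str,
          nm = ifelse(mm, 3L, 1L), nh = 1L, stringsAsFactors = FALSE)
      }
    }
    aln <- rbind(clean, if (length(ctm)) do.call(rbind, ctm))
    rownames(aln) <- NULL
    totals[s] <- nrow(aln)
    out_aln[[s]] <- aln

    blk <- if (length(acc_blocks)) {
      GRanges(chrom, do.call(c, acc_blocks), strand = acc_bstrand)
    } else GRanges()
    ctm_gr <- if (nrow(aln) > clean_totals[s]) {
      extra <- aln[(clean_totals[s] + 1L):nrow(aln), ]
      br <- GenomicAlignments::extractAlignmentRangesOnReference(extra$cigar,
                                                                 pos = extra$start)
      GRanges(chrom, unlist(br),
              strand = rep(extra$strand, lengths(br)))
    } else GRanges()
    allb <- c(blk, ctm_gr)
    seqlengths(allb) <- setNames(annotation$chrom_lengths[chrom], chrom)
    out_cov[[s]] <- list(
      plus = coverage(allb[strand(allb) == "+"]),
      minus = coverage(allb[strand(allb) == "-"])
    )
  }
  names(out_aln) <- names(out_cov) <- samples$sample_id
  structure(list(alignments = out_aln, coverage = out_cov,
                 totals = totals, clean_totals = clean_totals,
                 samples = samples),
            class = "sim_alignments")
}

# uniform placement of n reads of length rl along the concatenation of the
# given genomic blocks; returns per-read start/cigar plus the aligned-block
# ranges for coverage bookkeeping
place_reads <- function(ir, n, rl) {
  ir <- sort(ir)
  w <- width(ir)
  L <- sum(w)
  if (L < rl) {
    stop("transcript shorter than the read length", call. = FALSE)
  }
  cum <- cumsum(w)
  begin0 <- c(0L, cum[-length(cum)])
  off <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
  i <- findInterval(off, begin0)
  j <- findInterval(off + rl - 1L, begin0)
  gstart <- start(ir)[i] + (off - begin0[i])
  if (any(j - i > 1L)) {
    stop("read length exceeds an internal exon block", call. = FALSE)
  }
  cigar <- character(n)
  single <- i == j
  cigar[single] <- paste0(rl, "M")
  multi <- which(!single)
  m1 <- cum[i[multi]] - off[multi]
  gap <- start(ir)[i[multi] + 1L] - end(ir)[i[multi]] - 1L
  m2 <- rl - m1
  cigar[multi] <- sprintf("%dM%dN%dM", m1, gap, m2)
  blocks <- IRanges(
    start = c(gstart[single], gstart[multi], start(ir)[i[multi] + 1L]),
    width = c(rep(rl, sum(single)), m1, m2)
  )
  list(start = gstart, cigar = cigar, blocks = blocks)
}
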