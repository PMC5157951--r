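#' Generate the toy genome annotation
#'
#' Builds a GTF-serializable annotation for a toy chromosome carrying a
#' compact Hox-like cluster (Hoxc12 -- Hotair antisense with alternative
#' start sites -- an AntiHotair CpG-promoter transcript -- Hoxc11) plus
#' background genes, together with a description of the deletion allele
#' (the deleted segment), named locus quantification regions and a repeat
#' annotation. The output deliberately contains the awkward cases the
#' quantification filters must handle: one gene carries a
#' `retained_intron` isoform, two background genes overlap on the same
#' strand, and a satellite repeat overlaps one gene promoter.
#'
#' @param config a [sim_config()].
#' @return an object of class `toy_annotation`: list with elements
#'   `exons` (data frame: gene_id, gene_name, gene_biotype, transcript_id,
#'   transcript_class, chrom, start, end, strand; 1-based closed),
#'   `layout` ([toy_locus_layout()]), `repeats` (GRanges with `name` and
#'   `class`), `deleted` (GRanges), `regions` (named GRanges), `chrom_lengths`
#'   (named integer), `canonical` (named character: Hox canonical-isoform
#'   overrides), `default_chip_targets` (character) and
#'   `satellite_promoter_gene` (the planted target whose promoter a satellite
#'   overlaps).
#' @export
generate_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- toy_locus_layout(config$chrom_length)
  chrom <- layout$chrom

  exon_row <- function(gene_id, gene_biotype, transcript_id, transcript_class,
                       ir, strand) {
    data.frame(gene_id = gene_id, gene_name = gene_id,
               gene_biotype = gene_biotype,
               transcript_id = transcript_id,
               transcript_class = transcript_class,
               chrom = chrom, start = start(ir), end = end(ir),
               strand = strand, stringsAsFactors = FALSE)
  }

  exons <- rbind(
    exon_row("Hoxc12", "protein_coding", "Hoxc12-201", "protein_coding",
             layout$hoxc12_exons, "+"),
    exon_row("Hoxc12", "protein_coding", "Hoxc12-202", "protein_coding",
             layout$hoxc12_alt_exons, "+"),
    exon_row("Hoxc11", "protein_coding", "Hoxc11-201", "protein_coding",
             layout$hoxc11_exons, "+"),
    exon_row("Hoxc11", "protein_coding", "Hoxc11-202", "retained_intron",
             IRanges(159001L, 161000L), "+"),
    exon_row("Hotair", "lncRNA", "Hotair-201", "lncRNA",
             layout$hotair_annotated_exons, "-"),
    exon_row("Hotair", "lncRNA", "Hotair-202", "lncRNA",
             layout$hotair_tss2_exons, "-"),
    exon_row("Hotair", "lncRNA", "Hotair-203", "lncRNA",
             layout$hotair_tss3_exons, "-"),
    exon_row("AHotair", "lncRNA", "AHotair-201", "lncRNA",
             layout$ahotair_exon, "+")
  )

  n_bg <- config$n_background_genes
  if (n_bg > 0) {
    arenas <- rbind(c(1001L, 149000L), c(162600L, config$chrom_length - 2000L))
    widths <- arenas[, 2] - arenas[, 1] + 1L
    n_a <- round(n_bg * widths[1] / sum(widths))
    n_per <- c(n_a, n_bg - n_a)
    for (a in 1:2) {
      if (n_per[a] == 0) next
      spacing <- (arenas[a, 2] - arenas[a, 1] + 1L) %/% n_per[a]
      if (spacing < 800L) {
        stop("invalid configuration: chromosome too short for ",
             n_bg, " background genes", call. = FALSE)
      }
      for (i in seq_len(n_per[a])) {
        idx <- if (a == 1) i else n_per[1] + i
        slot <- arenas[a, 1] + (i - 1L) * spacing
        gstart <- slot + floor(runif(1, 0, min(200, spacing - 700)))
        glen <- floor(runif(1, 400, min(900, spacing - 350)))
        gend <- gstart + glen - 1L
        strand <- sample(c("+", "-"), 1L)
        biotype <- if (idx %% 10 == 0) "lncRNA" else "protein_coding"
        gid <- sprintf("bg%03d", idx)
        tclass <- if (biotype == "lncRNA") "lncRNA" else "protein_coding"
        if (runif(1) < 0.6 && glen >= 500) {
          e1 <- floor(glen * 0.4)
          gap <- floor(glen * 0.2)
          ir <- IRanges(start = c(gstart, gstart + e1 + gap),
                        end = c(gstart + e1 - 1L, gend))
        } else {
          ir <- IRanges(gstart, gend)
        }
        exons <- rbind(exons, exon_row(gid, biotype, paste0(gid, "-201"),
                                       tclass, ir, strand))
        if (idx == 1L && biotype == "protein_coding") {
          # retained-intron isoform: one exon covering the whole gene body
          exons <- rbind(exons, exon_row(gid, biotype, paste0(gid, "-202"),
                                         "retained_intron",
                                         IRanges(gstart, gend), strand))
        }
      }
    }
  }
  if (n_bg >= 2) {
    # two same-strand overlapping genes in a reserved window downstream of
    # Hoxc11, to exercise the ambiguous-read filter
    exons <- rbind(
      exons,
      exon_row("bgOvlA", "protein_coding", "bgOvlA-201", "protein_coding",
               IRanges(161501L, 162100L), "+"),
      exon_row("bgOvlB", "protein_coding", "bgOvlB-201", "protein_coding",
               IRanges(161801L, 162400L), "+")
    )
  }
  rownames(exons) <- NULL

  # Candidate ChIP targets: background protein-coding genes whose 2 kb
  # promoter is quasi-isolated (no other promoter shares more than 15% of
  # its bases with it, and no two planted promoters overlap), so that the
  # planted enrichment cannot push a neighbouring promoter past the
  # calling thresholds.
  gene_span <- split(exons, exons$gene_id)
  prom_of <- function(d) {
    if (d$strand[1] == "+") {
      c(max(1L, min(d$start) - 2000L), min(d$start) - 1L)
    } else {
      c(max(d$end) + 1L, max(d$end) + 2000L)
    }
  }
  proms <- t(vapply(gene_span, prom_of, c(1L, 1L)))
  ovl_frac <- function(a, b) {
    ov <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
    ov / (b[2] - b[1] + 1L)
  }
  pc_bg_all <- names(gene_span)[vapply(gene_span, function(d)
    d$gene_biotype[1] == "protein_coding", TRUE) & grepl("^bg\\d", names(gene_span))]
  candidates <- character(0)
  for (g in pc_bg_all) {
    others <- setdiff(rownames(proms), g)
    fr <- vapply(others, function(o) ovl_frac(proms[g, ], proms[o, ]), 1.0)
    if (all(fr <= 0.15) &&
        !any(vapply(candidates, function(t)
          ovl_frac(proms[t, ], proms[g, ]) > 0, TRUE))) {
      candidates <- c(candidates, g)
    }
  }

  # repeats: one satellite overlapping a planted-target promoter, one
  # intergenic satellite, one non-satellite repeat
  sat_gene <- if (length(candidates)) candidates[1] else "Hoxc11"
  ge <- exons[exons$gene_id == sat_gene, ]
  tss <- if (ge$strand[1] == "+") min(ge$start) else max(ge$end)
  sat_prom <- if (ge$strand[1] == "+") {
    IRanges(max(1L, tss - 400L), max(1L, tss - 200L))
  } else {
    IRanges(tss + 200L, tss + 400L)
  }
  repeats <- GRanges(chrom,
                     c(sat_prom, IRanges(140001L, 140500L), IRanges(30001L, 30300L)),
                     strand = "*",
                     name = c("SAT_prom", "SAT_intergenic", "ALU_1"),
                     class = c("Satellite/major", "Satellite/minor", "SINE/Alu"))

  extra <- setdiff(candidates, sat_gene)
  targets <- unique(c(sat_gene, head(extra, 11L)))

  structure(list(
    exons = exons,
    layout = layout,
    repeats = repeats,
    deleted = layout$deleted,
    regions = layout$regions,
    chrom_lengths = setNames(config$chrom_length, chrom),
    canonical = c(Hoxc12 = "Hoxc12-201", Hoxc11 = "Hoxc11-201"),
    default_chip_targets = targets,
    satellite_promoter_gene = sat_gene
  ), class = "toy_annotation")
}

#' Gene-level summary of an annotation
#'
#' @param annotation a `toy_annotation` or an exon data frame.
#' @return data frame with one row per gene: `gene_id`, `gene_biotype`,
#'   `chrom`, `strand`, `start`, `end`.
#' @export
annotation_genes <- function(annotation) {
  ex <- as_exon_table(annotation)
  sp <- split(ex, ex$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(gene_id = d$gene_id[1], gene_biotype = d$gene_biotype[1],
               chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

# normalise annotation inputs to the exon data frame
as_exon_table <- function(annotation) {
  if (inherits(annotation, "toy_annotation")) return(annotation$exons)
  if (is.data.frame(annotation)) {
    need <- c("gene_id", "gene_biotype", "transcript_id", "transcript_class",
              "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(annotation))
    if (length(miss)) {
      stop("annotation is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(annotation)
  }
  stop("annotation must be a toy_annotation or an exon data frame", call. = FALSE)
}
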