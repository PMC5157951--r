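#' Toy Hox-like locus layout
#'
#' Fixed geometry of the simulated locus on the toy chromosome `chrS`
#' (1-based closed coordinates, the native GRanges convention). The Hox
#' strand is `+`; the antisense lncRNA (Hotair) is on `-`. Along the
#' chromosome: Hoxc12 < Ghostair region < deleted segment < long-AntiHotair
#' region < Hoxc11. The deleted segment removes the two annotated Hotair
#' exons together with the termination signals of both strands, while two
#' alternative Hotair start sites (TSS2, TSS3) and the AntiHotair CpG-island
#' promoter survive outside it.
#'
#' @param chrom_length chromosome length in bp (>= 165000 so that the locus
#'   fits).
#' @return an object of class `locus_layout`: a list with the chromosome
#'   name/length, per-feature coordinates, the deleted segment, the named
#'   quantification regions (Hotair, AHotair, LAHotair, Ghostair) and
#'   per-unit tissue activity.
#' @export
toy_locus_layout <- function(chrom_length = 200000L) {
  if (chrom_length < 165000L) {
    stop("invalid configuration: chrom_length must be at least 165000", call. = FALSE)
  }
  chrom <- "chrS"
  # Hox-strand genes
  hoxc12_exons <- IRanges(start = c(150001L, 151201L), end = c(150800L, 152000L))
  hoxc12_alt   <- IRanges(start = c(150001L, 151201L), end = c(150800L, 152300L))
  hoxc11_exons <- IRanges(start = c(159001L, 160201L), end = c(159600L, 161000L))
  # Antisense lncRNA: annotated isoform (two major exons, TSS1 at 154800)
  # plus two isoforms from upstream alternative start sites TSS2/TSS3.
  hotair_tss <- c(TSS1 = 154800L, TSS2 = 157300L, TSS3 = 158400L)
  hotair_annotated <- IRanges(start = c(153001L, 154001L), end = c(153600L, 154800L))
  hotair_tss2 <- IRanges(start = c(153001L, 154001L), end = c(153600L, 157300L))
  hotair_tss3 <- IRanges(start = c(153001L, 154001L), end = c(153600L, 158400L))
  # Un-annotated CpG-island promoter transcript on the Hox strand; its
  # wild-type termination site lies inside the deleted segment.
  ahotair_exon <- IRanges(start = 152601L, end = 154400L)
  deleted <- GRanges(chrom, IRanges(153001L, 155500L))
  regions <- GRanges(
    seqnames = chrom,
    ranges = IRanges(start = c(153001L, 152601L, 155501L, 152001L),
                     end   = c(154800L, 153000L, 159000L, 153000L)),
    strand = c("-", "+", "+", "-")
  )
  names(regions) <- c("Hotair", "AHotair", "LAHotair", "Ghostair")
  structure(list(
    chrom = chrom,
    chrom_length = as.integer(chrom_length),
    hoxc12_exons = hoxc12_exons,
    hoxc12_alt_exons = hoxc12_alt,
    hoxc11_exons = hoxc11_exons,
    hotair_tss = hotair_tss,
    hotair_annotated_exons = hotair_annotated,
    hotair_tss2_exons = hotair_tss2,
    hotair_tss3_exons = hotair_tss3,
    ahotair_exon = ahotair_exon,
    deleted = deleted,
    regions = regions,
    # Tissues in which each locus transcription unit is active; Hotair and
    # its read-through product are silent in forelimb and the anterior trunk.
    activity = list(
      Hotair  = c("HL", "GT", "T2", "T3"),
      AHotair = c("T2", "T3"),
      Hoxc11  = c("HL", "GT", "T2", "T3"),
      Hoxc12  = c("T2", "T3")
    ),
    # Relative expression weight of each locus unit (same scale as the
    # background gene weights drawn in simulate_counts()).
    base_weight = c(Hotair = 30, AHotair = 8, Hoxc11 = 40, Hoxc12 = 25)
  ), class = "locus_layout")
}

#' Genomic exon blocks of a locus transcription unit
#'
#' Returns the genomic intervals covered by the transcripts of one locus
#' unit under a given allele. For the deletion allele, `variant` selects the
#' read-through product (transcription proceeding past the removed
#' termination signal and across the former position of the deleted
#' segment) or the truncated product that stops at the deletion boundary.
#'
#' @param layout a [toy_locus_layout()].
#' @param unit one of `"Hotair"`, `"AHotair"`, `"Hoxc11"`, `"Hoxc12"`.
#' @param genotype `"wt"` or `"del"`.
#' @param variant for `del` Hotair/AHotair: `"readthrough"` or `"truncated"`.
#' @return IRanges of genomic blocks (sorted; reads are placed uniformly
#'   along their concatenation).
#' @export
locus_transcript_blocks <- function(layout, unit, genotype = "wt",
                                    variant = c("readthrough", "truncated")) {
  variant <- match.arg(variant)
  stopifnot(inherits(layout, "locus_layout"))
  if (unit == "Hoxc12") return(layout$hoxc12_exons)
  if (unit == "Hoxc11") return(layout$hoxc11_exons)
  dl <- start(layout$deleted)  # 153001: first deleted base
  dr <- end(layout$deleted)    # 155500: last deleted base
  if (unit == "Hotair") {
    if (genotype == "wt") {
      # annotated exons plus the continuous extension to the most upstream
      # alternative start site (TSS3)
      return(IRanges(start = c(153001L, 154001L), end = c(153600L, 158400L)))
    }
    if (variant == "readthrough") {
      # initiated at a surviving TSS, crosses the former deleted segment and
      # terminates within 100 bp of the Hoxc12 termination site (152000)
      return(IRanges(start = c(152051L, dr + 1L), end = c(dl - 1L, 158400L)))
    }
    return(IRanges(start = dr + 1L, end = 158400L))
  }
  if (unit == "AHotair") {
    if (genotype == "wt") return(layout$ahotair_exon)
    if (variant == "readthrough") {
      # long AntiHotair: CpG promoter across the breakpoint up to Hoxc11 TSS
      return(IRanges(start = c(152601L, dr + 1L), end = c(dl - 1L, 159000L)))
    }
    return(IRanges(start = 152601L, end = dl - 1L))
  }
  stop("unknown locus unit: ", unit, call. = FALSE)
}

#' Strand of a locus transcription unit
#' @param unit unit name.
#' @return `"+"` (Hox strand) or `"-"` (anti-Hox strand).
#' @export
locus_unit_strand <- function(unit) {
  ifelse(unit == "Hotair", "-", "+")
}
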