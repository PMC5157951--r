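---
title: "Methods: quantifying cis effects of a Hox-cluster lncRNA deletion"
author: "hoxcis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cis effects of a Hox-cluster lncRNA deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

*Hotair* is a long non-coding RNA transcribed antisense to the Hox genes,
between *Hoxc11* and *Hoxc12*. Whether deleting its locus perturbs distant
Polycomb-target genes in *trans*, or only reorganises transcription of its
immediate chromosomal neighbourhood in *cis*, is a question that turns
entirely on careful quantification: strand-aware counting, a normalization
that does not absorb genuine genotype effects, a calibrated per-tissue test
of the genotype contrast, and a way to detect the new read-through RNA
species (*Ghostair*, long *AntiHotair*) that appear when termination
signals are removed with the locus.

`hoxcis` implements that analysis as a reusable pipeline and pairs it with
a synthetic-data generator so that every stage can be validated against
planted truth without any external download.

## Quantification model

**Flattened gene models.** The counting unit of a gene is the disjoint
union of exon intervals from its retained isoforms. For protein-coding
genes only transcripts of class `protein_coding` contribute; isoforms
flagged `retained_intron` or `nonsense_mediated_decay` are discarded
because their exons cover intronic sequence and would inflate the
denominator of expression estimates. Hox genes are a special case: their
annotations carry read-through isoforms spanning neighbouring transcription
units, so a canonical-isoform override restricts them to one named
transcript. Non-coding genes keep all isoforms.

**Read filters.** A read is assigned to a gene iff it maps uniquely,
carries at most 2 mismatches, contains no small indel, overlaps the
flattened exons by at least one aligned base on the matching strand, and
matches exactly one gene on that strand. Reads touching two same-strand
overlapping genes are discarded for both, because their origin is
ambiguous. Under the dUTP/TruSeq stranded protocol the sequenced strand is
the antisense of the transcript, so the transcript strand is the flip of
the alignment strand; this is a tri-state option (`antisense`, `sense`,
`unstranded`) because public datasets vary.

**RPKM and normalization.** RPKM(g, s) = count / (exonic kb) / (millions of
nuclear mapped reads); mitochondrial reads are excluded from the totals
because mitochondrial content varies with tissue and dissection. RPKM
values are then put on a common scale with a median-scaling step: the
standard set is the 100 genes with the least expression-*rank* variation
across samples among genes whose median RPKM falls in the central 25–75%
band. Rank variation is measured as the standard deviation across samples
of the gene's within-sample rank (average ranks on ties; ties in the score
broken by gene identifier so the selection is reproducible). Each sample
is rescaled so the median RPKM of the standard set is equal everywhere;
the common reference is the across-sample median of those medians. Any
fixed reference would differ only by a global constant, so this choice is
free; the across-sample median keeps the factors centred on 1.

## Differential expression

For each tissue separately, each gene's counts are modelled with a
log-link negative-binomial GLM with `log(size factor)` offsets:

* full model: `log mu = b0 + b1 * genotype`
* null model: `log mu = b0`

and the genotype effect is tested with the likelihood-ratio statistic
`2(ll_full − ll_null)` against chi-square with 1 df. `log2FC = b1 / ln 2`.
Size factors are median-of-ratios. A Wald test on `b1` is available as a
control. P-values from all tissues are pooled into a single
Benjamini–Hochberg correction, so a gene's FDR in one tissue depends on the
evidence in the others; genes that cannot be tested (all-zero counts) are
excluded from the BH denominator. Calls use strict thresholds: `up` means
FDR < 0.05 (0.10 for the targeted gene-set analyses) *and* fold change
strictly above 1.5.

**Dispersion.** The NB dispersion is estimated by the method of moments on
size-factor-normalized counts, using the pooled within-genotype variance so
planted or real genotype effects do not inflate it. With two replicates per
group the per-gene estimate has two degrees of freedom, and plugging it
into the chi-square reference makes the LRT strongly anticonservative:
whenever the within-group variance is accidentally small the statistic
explodes. The default therefore shares one common dispersion across genes —
the mean of the positive per-gene moment estimates — which is exactly
identified from hundreds of genes and restores nominal behaviour, in the
same spirit as the common-dispersion estimators used for small-replicate
RNA-seq designs. `dispersion_method = "per_gene"` switches to the per-gene
estimates (floored at 1e-8) for users with deeper replication. The LRT is
evaluated from the NB log-likelihood at the fitted means rather than from
the family deviance, because the deviance loses precision to cancellation
when the dispersion approaches the Poisson limit.

This simplified GLM deliberately omits fold-change shrinkage, independent
filtering and outlier handling: the testable content of the analysis is
the model contrast, the LRT and the joint BH step, not the internals of
any particular DE package.

## Polycomb target calling

Promoters are defined as the 2 kb upstream of the TSS (the 5' end of the
flattened model on the gene's strand; per-transcript promoters with
any-promoter-passes aggregation are available since gene-level TSS
aggregation is a modelling choice), or as 4 kb windows centred on the TSS
as a robustness mode. Mean per-base H3K27me3 and input coverages over the
promoter are each normalized per million mapped reads; a gene is a
putative Polycomb target iff chip/input ≥ 5 **and** normalized chip ≥ 0.1
(both inclusive, "at least") and no satellite repeat intersects the
promoter — satellites show artifactual H3K27me3 enrichment. A pseudocount
of 0.01 on the normalized input mean keeps the ratio finite and monotone on
zero-input promoters. Coverage tracks are assumed deduplicated upstream.

## Locus regions and read-through detection

Four named strand-specific windows quantify the locus:

* `Hotair` — the annotated antisense gene body;
* `AHotair` — from the CpG-island promoter on the Hox strand to the
  deletion boundary (the wild-type short transcript);
* `LAHotair` — from the deletion boundary to the *Hoxc11* TSS (the long
  product that appears when the termination site is deleted);
* `Ghostair` — between the annotated *Hotair* termination site and the
  *Hoxc12* termination site on the *Hotair* strand (the read-through
  product of the surviving *Hotair* start sites, absent from wild type).

Region RPKM uses the gene formula with region length, strand-matched reads,
and the same totals and scale factors as the gene-level tables.

Read-through across the breakpoint is detected on per-base coverage in
*deletion-allele coordinates*: `collapse_deletion()` removes the deleted
window and fuses the flanks, then `segment_transcribed()` finds maximal
runs with coverage ≥ `min_cov` (default 0.05), bridging internal gaps
shorter than `max_gap` (default 50 bases — about half a read length, so
sampling gaps are bridged but real termination is not). A segment is
read-through iff it *strictly contains* the fused breakpoint coordinate:
wild-type transcription that ends exactly at the boundary merely touches
it, so the strict containment rule separates the two cases without any
tolerance parameter.

## Exploratory statistics

PCA uses `log2(RPKM + 1)` for genes with RPKM > 1 in at least one sample,
centred per gene (mean zero) and not scaled, via SVD. The `+1` offset is
the conventional way to admit the zeros that the filter still allows.
Sample clustering uses Euclidean distances on the same transform with
complete linkage (the linkage is configurable; no canonical choice exists
for this analysis). The GO background list contains every gene sequenced
at least as deeply (summed over the relevant samples) as the least-covered
DE gene, inclusive at the threshold. Contingency tables (the vertebral
phenotype table, the DE-direction-by-target-status table) are tested with
Pearson's chi-square without continuity correction; a plain hypergeometric
over-representation helper is included as generic plumbing, not as a
replacement for any dedicated GO tool.

## What the synthetic data emulate — and what they do not

`generate_annotation()` builds a single toy chromosome with a compact
Hox-like cluster whose geometry encodes the biology under study: *Hoxc12*
and *Hoxc11* on the Hox strand, *Hotair* antisense between them with three
start sites of which two survive outside the deleted segment, an
*AntiHotair* CpG promoter whose termination signal sits inside the deleted
segment, and the deleted window strictly between the two Hox genes. The
annotation also plants the awkward cases the filters exist for: a
`retained_intron` isoform, a same-strand overlapping gene pair, and a
satellite repeat on a target promoter.

Counts are negative-binomial with a log-normal baseline per gene, a smooth
two-axis tissue program (anterior–posterior gradient and limb-versus-trunk
axis, echoing how embryonic dissection series actually separate), planted
genotype log2 fold changes, and log-normal library sizes. Locus units
follow fixed activity masks — *Hotair* silent in forelimb and the anterior
trunk — so the tissue-restriction of the read-through products is part of
the planted truth. Alignments place 100 nt single-end reads uniformly along
transcripts (junction reads become `M N M` records), flip the alignment
strand under the dUTP convention, and inject the contaminant classes the
filters discard. In deletion samples a configurable fraction (default 0.8)
of *Hotair*/*AntiHotair* transcripts extends across the former deleted
segment. ChIP/input tracks plant targets with at least twice the calling
margins on quasi-isolated promoters, plus satellite enrichment.

Deliberate non-goals: no base-level sequences or quality scores, no
paired-end reads, no sequencing-error model beyond the integer mismatch
tag, no splice-graph realism beyond exon-block placement, no PCR-duplicate
structure in the ChIP tracks. Passing tests on these data therefore
demonstrate the correctness of the bookkeeping, filters and statistics
under the stated model — not robustness to alignment artefacts, GC bias or
other properties of real libraries that the generator does not model.

## Parameter defaults and problem sizes

| Parameter | Default | Why |
|---|---|---|
| tissues × genotypes × replicates | 6 × 2 × 2 | the embryonic dissection design the analysis assumes |
| read length | 100 nt | standard stranded single-end sequencing |
| `nb_dispersion` | 0.05 | typical biological-replicate dispersion for bulk RNA-seq |
| `readthrough_rate` | 0.8 | most transcripts lose termination when the signal is deleted |
| contamination rates | 0.02 each | enough ambiguous/high-mismatch reads to exercise filters without distorting totals |
| chromosome / background genes | 600 kb / 200 | ~3 kb spacing, so 2 kb promoters are resolvable and planted ChIP margins cannot leak into neighbouring promoters |
| `library_size_mean` | 2e4 | desk-scale for per-read simulation; count-level experiments (normalization recovery, PCA) use 2e6–3e7 reads, the realistic depth at which mid-expressed genes are measured to ~1% and adjacent trunk segments separate |

The validation experiments run at the sizes stated in the test suite: 2000
genes for normalization-factor recovery, 500 null plus 100 planted genes at
baseline 500 and dispersion 0.05 for LRT calibration (2 vs 2), 100 random
annotations for the flattening oracle, and the full 24-sample design for
read-through and PCA checks.

## Known limitations

* The NB GLM is a minimal implementation: no shrinkage, no outlier
  refitting; with very low counts and `per_gene` dispersion the test is
  miscalibrated — that is why `common` is the default.
* The published direction-test p-value for Polycomb targets (0.18) is not
  exactly recoverable from the printed rounded counts; the table bundled
  here gives chi-square p = 0.152, and both numbers are reported rather
  than forced to agree.
* Region endpoints for the locus windows are annotation-derived in the
  generator but must be user-supplied for real assemblies, where the
  precise alternative start sites are only known approximately.
* The coverage-segmentation stand-in for transcript assembly recovers
  contiguous transcribed intervals, not isoform structure.
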