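test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(library_size_mean = 0), "invalid configuration")
  expect_error(sim_config(readthrough_rate = 1.5), "invalid configuration")
  expect_error(sim_config(tissues = c("A", "A")), "invalid configuration")
  expect_error(sim_config(planted_effects = data.frame(
    gene_id = "x", tissue = "XX", log2fc = 1)), "unknown tissues")
  expect_error(generate_annotation(sim_config(n_background_genes = 500,
                                              chrom_length = 300000)),
               "too short")
})

test_that("locus geometry respects the deletion-allele constraints", {
  ann <- generate_annotation(sim_config(seed = 2, n_background_genes = 30))
  lay <- ann$layout
  del <- lay$deleted
  # deleted segment strictly between Hoxc12 and Hoxc11
  expect_gt(start(del), max(end(lay$hoxc12_exons)))
  expect_lt(end(del), min(start(lay$hoxc11_exons)))
  # deletion removes the annotated Hotair exons and its termination site
  expect_true(all(start(lay$hotair_annotated_exons) >= start(del) &
                    end(lay$hotair_annotated_exons) <= end(del)))
  # the AntiHotair wild-type termination site is inside the deletion
  expect_true(end(lay$ahotair_exon) <= end(del) && end(lay$ahotair_exon) >= start(del))
  # at least one alternative Hotair start site survives outside the deletion
  surviving <- lay$hotair_tss[lay$hotair_tss > end(del)]
  expect_gte(length(surviving), 1)
  # the annotated promoter region (>=2.4 kb upstream extension exists)
  expect_gte(max(lay$hotair_tss) - lay$hotair_tss[["TSS1"]], 2400)
  # named regions sit where the definitions say
  rg <- ann$regions
  expect_equal(start(rg["Ghostair"]), max(end(lay$hoxc12_exons)) + 1L)
  expect_equal(end(rg["Ghostair"]), start(del) - 1L)
  expect_equal(as.character(strand(rg["Ghostair"])), "-")
  expect_equal(start(rg["LAHotair"]), end(del) + 1L)
  expect_equal(end(rg["LAHotair"]), min(start(lay$hoxc11_exons)) - 1L)
  expect_equal(start(rg["AHotair"]), start(lay$ahotair_exon))
  expect_equal(end(rg["AHotair"]), start(del) - 1L)
  # all intervals within chromosome bounds
  expect_true(all(ann$exons$start >= 1 & ann$exons$end <= ann$chrom_lengths))
})

test_that("annotation contains the filter-exercising cases", {
  ann <- generate_annotation(sim_config(seed = 3, n_background_genes = 30))
  ex <- ann$exons
  expect_true(any(ex$transcript_class == "retained_intron"))
  # two same-strand overlapping genes
  ga <- ex[ex$gene_id == "bgOvlA", ]
  gb <- ex[ex$gene_id == "bgOvlB", ]
  expect_equal(ga$strand[1], gb$strand[1])
  expect_true(max(ga$end) >= min(gb$start))
  # a satellite repeat overlaps the planted target's promoter
  sat <- ann$repeats[grepl("Satellite", ann$repeats$class)]
  fm <- flatten_gene_models(ann, canonical_overrides = ann$canonical)
  pr <- define_promoters(fm, chrom_lengths = ann$chrom_lengths)
  hit <- pr[pr$gene_id == ann$satellite_promoter_gene]
  expect_true(any(overlapsAny(hit, sat, ignore.strand = TRUE)))
  expect_true(ann$satellite_promoter_gene %in% ann$default_chip_targets)
})

test_that("a background-free annotation holds exactly the locus genes", {
  ann <- generate_annotation(sim_config(seed = 1, n_background_genes = 0))
  expect_setequal(unique(ann$exons$gene_id),
                  c("Hoxc12", "Hoxc11", "Hotair", "AHotair"))
})

test_that("generator outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, n_background_genes = 25, library_size_mean = 1500)
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  write_annotation_gtf(a1, f1); write_annotation_gtf(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s1 <- simulate_counts(a1, cfg); s2 <- simulate_counts(a2, cfg)
  expect_identical(s1$counts, s2$counts)
  al1 <- simulate_alignments(s1, a1, cfg); al2 <- simulate_alignments(s2, a2, cfg)
  expect_identical(al1$alignments, al2$alignments)
  c1 <- simulate_chip(a1, config = cfg); c2 <- simulate_chip(a2, config = cfg)
  expect_identical(c1$chip, c2$chip)
  expect_identical(c1$input, c2$input)
})

test_that("null genes are unbiased and planted fold changes are recovered", {
  pe <- data.frame(gene_id = sprintf("bg%03d", 1:100), tissue = "T3",
                   log2fc = 2)
  cfg <- sim_config(seed = 9, n_background_genes = 300, chrom_length = 600000,
                    tissues = "T3", replicates_per_group = 20,
                    nb_dispersion = 0.05, planted_effects = pe,
                    library_size_mean = 4e5, library_size_sdlog = 0)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  wt <- sim$samples$sample_id[sim$samples$genotype == "wt"]
  del <- sim$samples$sample_id[sim$samples$genotype == "del"]
  m_wt <- rowMeans(sim$counts[, wt]); m_del <- rowMeans(sim$counts[, del])
  null_genes <- setdiff(grep("^bg", rownames(sim$counts), value = TRUE),
                        pe$gene_id)
  null_genes <- null_genes[m_wt[null_genes] > 5]
  expect_gte(length(null_genes), 150)
  # null ratio -> 1 within Monte-Carlo error
  expect_lt(abs(mean(log2(m_del[null_genes] / m_wt[null_genes]))), 0.05)
  # planted log2 ratio within +/- 0.3 of 2, averaged over 100 genes
  expect_lt(abs(mean(log2(m_del[pe$gene_id] / m_wt[pe$gene_id])) - 2), 0.3)
})

test_that("simulated counts match negative-binomial moments", {
  cfg <- sim_config(seed = 13, n_background_genes = 1000, chrom_length = 1200000,
                    tissues = "T3", replicates_per_group = 25,
                    nb_dispersion = 0.05, planted_effects = NULL,
                    library_size_mean = 2e6, library_size_sdlog = 0)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  wt <- sim$samples$sample_id[sim$samples$genotype == "wt"]
  y <- sim$counts[grep("^bg", rownames(sim$counts)), wt]
  m <- rowMeans(y); v <- apply(y, 1, var)
  keep <- m > 50
  expect_gte(sum(keep), 900)
  # across genes, var ~ mean + phi mean^2 within 10% relative error
  phi_hat <- mean(((v - m) / m^2)[keep])
  expect_lt(abs(phi_hat - 0.05) / 0.05, 0.10)
  # Poisson limit: dispersion -> 0 gives variance ~ mean
  cfg0 <- cfg; cfg0$nb_dispersion <- 0; cfg0$seed <- 14L
  sim0 <- simulate_counts(generate_annotation(cfg0), cfg0)
  y0 <- sim0$counts[grep("^bg", rownames(sim0$counts)), wt]
  m0 <- rowMeans(y0); v0 <- apply(y0, 1, var)
  k0 <- m0 > 50
  expect_lt(abs(sum(v0[k0]) / sum(m0[k0]) - 1), 0.05)
})

test_that("clean reads reconcile with the count table and contaminants are injected", {
  s <- small_sim(seed = 5, n_bg = 40, lib = 2500)
  aln <- simulate_alignments(s$sim, s$ann, s$cfg)
  expect_equal(unname(aln$clean_totals),
               unname(as.integer(colSums(s$sim$counts)[names(aln$clean_totals)])))
  expect_true(all(aln$totals >= aln$clean_totals))
  one <- aln$alignments[[1]]
  expect_true(any(one$nm > 2))
  expect_true(any(grepl("I", one$cigar)))
  expect_true(any(grepl(":ovl:", one$read_id)))
  # unknown genes in the count table are a data error
  bad <- s$sim
  rownames(bad$counts)[1] <- "ghost_gene"
  expect_error(simulate_alignments(bad, s$ann, s$cfg), "unknown genes")
})

test_that("wild-type samples have no anti-Hox coverage in the Ghostair window", {
  s <- small_sim(seed = 6, n_bg = 30, lib = 2500)
  aln <- simulate_alignments(s$sim, s$ann, s$cfg)
  gh <- s$ann$regions["Ghostair"]
  for (sid in s$sim$samples$sample_id) {
    # anti-Hox transcript strand "-" aligns to "+" under the dUTP convention
    cov <- aln$coverage[[sid]]$plus[[as.character(seqnames(gh))]]
    w <- sum(window(cov, start(gh), end(gh)))
    geno <- s$sim$samples$genotype[s$sim$samples$sample_id == sid]
    tis <- s$sim$samples$tissue[s$sim$samples$sample_id == sid]
    if (geno == "wt" || !(tis %in% s$ann$layout$activity$Hotair)) {
      expect_equal(w, 0)
    }
  }
  # deletion samples in active tissues do cover the windows on both strands
  # around the former deleted segment (AntiHotair is posterior-trunk only,
  # so the Hox-strand gain is checked in T3)
  expect_gt(sum(window(aln$coverage[["del_GT_1"]]$plus[[1]],
                       start(gh), end(gh))), 0)
  lah <- s$ann$regions["LAHotair"]
  expect_gt(sum(window(aln$coverage[["del_T3_1"]]$minus[[1]],
                       start(lah), end(lah))), 0)
})

test_that("flipping the library strandedness swaps the coverage tracks exactly", {
  s <- small_sim(seed = 7, n_bg = 25, lib = 1500)
  a_anti <- simulate_alignments(s$sim, s$ann, s$cfg)
  cfg_sense <- s$cfg
  cfg_sense$library_strandedness <- "sense"
  a_sense <- simulate_alignments(s$sim, s$ann, cfg_sense)
  for (sid in head(s$sim$samples$sample_id, 4)) {
    expect_identical(a_anti$coverage[[sid]]$plus, a_sense$coverage[[sid]]$minus)
    expect_identical(a_anti$coverage[[sid]]$minus, a_sense$coverage[[sid]]$plus)
  }
})

test_that("planted ChIP targets clear the calling margins by construction", {
  cfg <- sim_config(seed = 8, n_background_genes = 50)
  ann <- generate_annotation(cfg)
  chip <- simulate_chip(ann, config = cfg)
  sc <- score_promoters(chip$chip, chip$input, chip$promoters, ann$repeats,
                        chip$chip_total_reads, chip$input_total_reads)
  planted <- sc$gene_id %in% chip$target_genes
  expect_true(all(sc$ratio[planted] >= 8))
  expect_true(all(sc$chip_mean[planted] >= 0.2))
  sat_free_nontarget <- !planted & !sc$satellite_overlap
  expect_true(all(sc$ratio[sat_free_nontarget] <= 2))
})
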