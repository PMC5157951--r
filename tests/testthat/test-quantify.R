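test_that("flattening merges exons and honours isoform retention rules", {
  # single isoform: intervals unchanged
  ex <- toy_exons("g1", "g1-t1", c(101, 301), c(200, 400))
  fm <- flatten_gene_models(ex)
  expect_equal(fm$info["g1", "exonic_length"], 200L)
  expect_equal(start(fm$exons[["g1"]]), c(101, 301))

  # overlapping isoforms merge: [101,200] + [151,250] -> [101,250]
  ex2 <- rbind(toy_exons("g1", "t1", 101, 200), toy_exons("g1", "t2", 151, 250))
  fm2 <- flatten_gene_models(ex2)
  expect_equal(fm2$info["g1", "exonic_length"], 150L)

  # retained_intron isoforms of coding genes are discarded
  ex3 <- rbind(toy_exons("g1", "t1", c(101, 301), c(200, 400)),
               toy_exons("g1", "t2", 101, 400, tclass = "retained_intron"))
  fm3 <- flatten_gene_models(ex3)
  expect_equal(fm3$info["g1", "exonic_length"], 200L)

  # non-coding genes keep all isoforms
  ex4 <- rbind(toy_exons("nc1", "t1", 101, 200, biotype = "lncRNA", tclass = "lncRNA"),
               toy_exons("nc1", "t2", 151, 300, biotype = "lncRNA", tclass = "processed"))
  fm4 <- flatten_gene_models(ex4)
  expect_equal(fm4$info["nc1", "exonic_length"], 200L)

  # canonical override restricts to the named isoform; absent isoform errors
  ex5 <- rbind(toy_exons("hx", "hx-201", c(101, 301), c(200, 400)),
               toy_exons("hx", "hx-202", 101, 600))
  fm5 <- flatten_gene_models(ex5, canonical_overrides = c(hx = "hx-201"))
  expect_equal(fm5$info["hx", "exonic_length"], 200L)
  expect_error(flatten_gene_models(ex5, canonical_overrides = c(hx = "nope")),
               "absent transcript")

  # a coding gene with no coding isoform is excluded with a message
  ex6 <- toy_exons("g9", "t1", 101, 200, tclass = "retained_intron")
  expect_message(fm6 <- flatten_gene_models(rbind(ex2, ex6)), "excluded")
  expect_false("g9" %in% fm6$info$gene_id)
})

test_that("flattening is idempotent and matches the per-base union oracle", {
  set.seed(401)
  for (rep in 1:100) {
    n_tx <- sample(1:4, 1)
    rows <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
      n_ex <- sample(1:4, 1)
      st <- sort(sample(1:5000, n_ex))
      en <- st + sample(50:400, n_ex, replace = TRUE)
      toy_exons("g", sprintf("t%d", t), st, en)
    }))
    fm <- flatten_gene_models(rows)
    expect_equal(fm$info["g", "exonic_length"],
                 union_size(rows$start, rows$end))
    # idempotence: re-flattening the flattened exons changes nothing
    flat <- fm$exons[["g"]]
    again <- flatten_gene_models(toy_exons("g", "t1", start(flat), end(flat)))
    expect_identical(again$exons[["g"]], flat)
    expect_true(all(start(flat)[-1] > end(flat)[-length(flat)]))
  }
})

test_that("read counting applies the uniqueness, mismatch, indel and strand filters", {
  # layout: gA [1000,1999]+ ; gB [1500,2499]+ overlapping gA; gC [1000,1999]-
  # gD [5000,5999]+ isolated; gE [8000,8999]+ isolated
  models <- flatten_gene_models(rbind(
    toy_exons("gA", "tA", 1000, 1999),
    toy_exons("gB", "tB", 1500, 2499),
    toy_exons("gC", "tC", 1000, 1999, strand = "-"),
    toy_exons("gD", "tD", 5000, 5999),
    toy_exons("gE", "tE", 8000, 8999)))
  # under antisense strandedness a "-" alignment is a "+" transcript
  aln <- rbind(
    toy_aln(5100, strand = "-"),                    # clean -> gD
    toy_aln(5100, strand = "-", nm = 3L),           # >2 mismatches
    toy_aln(5200, cigar = "50M1D50M", strand = "-"),# indel
    toy_aln(5300, strand = "-", nh = 2L),           # multi-mapper
    toy_aln(5400, strand = "+"),                    # wrong strand (tx "-")
    toy_aln(1600, strand = "-"),                    # overlaps gA+gB same strand
    toy_aln(1000, strand = "-"),                    # gA only (before gB start)
    toy_aln(1000, strand = "+"))                    # tx "-" -> gC only
  ct <- count_unique_reads(aln, models, strandedness = "antisense")
  expect_equal(ct$counts[, 1],
               c(gA = 1L, gB = 0L, gC = 1L, gD = 1L, gE = 0L))
  expect_equal(unname(ct$totals), 8)

  # sense mode flips the assignment; unstranded counts both strands as one
  ct_sense <- count_unique_reads(aln[8, , drop = FALSE], models,
                                 strandedness = "sense")
  expect_equal(unname(ct_sense$counts["gA", 1]), 1L)
  # unstranded: a read over gA(+) and gC(-) hits two genes -> discarded
  ct_un <- count_unique_reads(aln[7, , drop = FALSE], models,
                              strandedness = "unstranded")
  expect_equal(sum(ct_un$counts), 0L)

  # mitochondrial reads are dropped from totals; unknown chromosomes error
  aln_m <- rbind(toy_aln(5100, strand = "-"), toy_aln(10, chrom = "chrM"))
  ct_m <- count_unique_reads(aln_m, models)
  expect_equal(unname(ct_m$totals), 1)
  expect_error(count_unique_reads(toy_aln(10, chrom = "chrZ"), models),
               "unknown chromosome")
})

test_that("counting matches exhaustive overlap enumeration on a toy layout", {
  models <- flatten_gene_models(rbind(
    toy_exons("g1", "t1", 1000, 1999),
    toy_exons("g2", "t2", 1800, 2799),
    toy_exons("g3", "t3", 2600, 3599, strand = "-"),
    toy_exons("g4", "t4", 5000, 5999),
    toy_exons("g5", "t5", 5900, 6899, strand = "-")))
  set.seed(77)
  starts <- sample(500:7000, 300, replace = TRUE)
  strands <- sample(c("+", "-"), 300, replace = TRUE)
  aln <- toy_aln(starts, strand = strands)
  ct <- count_unique_reads(aln, models, strandedness = "antisense")
  # oracle: enumerate overlaps per read by brute force
  genes <- data.frame(id = c("g1", "g2", "g3", "g4", "g5"),
                      st = c(1000, 1800, 2600, 5000, 5900),
                      en = c(1999, 2799, 3599, 5999, 6899),
                      strand = c("+", "+", "-", "+", "-"))
  expected <- setNames(integer(5), genes$id)
  for (k in seq_len(300)) {
    tx <- ifelse(strands[k] == "+", "-", "+")
    hit <- genes$id[genes$strand == tx &
                      pmin(genes$en, starts[k] + 99) >= pmax(genes$st, starts[k])]
    if (length(hit) == 1) expected[hit] <- expected[hit] + 1L
  }
  expect_equal(ct$counts[genes$id, 1], expected)
})

test_that("RPKM follows the unit formula and its invariances", {
  models <- flatten_gene_models(rbind(
    toy_exons("g1", "t1", 1, 1000),
    toy_exons("g2", "t2", 2001, 4500),
    toy_exons("g3", "t3", 6001, 6500)))
  counts <- matrix(c(1000L, 50L, 0L), ncol = 1,
                   dimnames = list(c("g1", "g2", "g3"), "s1"))
  r1 <- compute_rpkm(counts, models, totals = c(s1 = 1e6))
  expect_equal(unname(r1["g1", 1]), 1000)   # 1000 reads / 1 kb / 1 M
  r2 <- compute_rpkm(counts, models, totals = c(s1 = 1e7))
  expect_equal(unname(r2["g2", 1]), 2.0)    # 50 / 2.5 kb / 10 M
  expect_equal(unname(r1["g3", 1]), 0)
  # scale invariance: multiplying counts and totals by the same constant
  r3 <- compute_rpkm(counts * 7L, models, totals = c(s1 = 7e6))
  expect_equal(r3, r1)
  expect_error(compute_rpkm(counts, models, totals = c(s1 = 0)), "positive")
})

test_that("standard-gene selection matches brute-force enumeration", {
  # deterministic zero-variation case: mid-expressed genes with identical
  # ranks everywhere are selected with score 0
  set.seed(55)
  base <- 2^seq(0, 8, length.out = 40)
  expr <- outer(base, c(1, 1.01, 0.99))
  rownames(expr) <- sprintf("g%02d", 1:40)
  colnames(expr) <- c("a", "b", "c")
  sel <- select_standard_genes(expr, n_standard = 10)
  expect_length(sel$gene_ids, 10)
  expect_true(all(sel$scores$rank_sd[match(sel$gene_ids, sel$scores$gene_id)] == 0))

  # noisy 10-gene, 3-sample toy against exhaustive computation
  expr2 <- matrix(rlnorm(30, log(10), 1), 10, 3,
                  dimnames = list(sprintf("g%d", 1:10), c("a", "b", "c")))
  sel2 <- select_standard_genes(expr2, n_standard = 3)
  med <- apply(expr2, 1, median)
  qs <- quantile(med, c(0.25, 0.75))
  elig <- names(med)[med >= qs[1] & med <= qs[2]]
  rk <- apply(expr2, 2, rank)
  sds <- apply(rk, 1, sd)[elig]
  ordered <- elig[order(sds, elig)]
  expect_equal(sel2$gene_ids, ordered[1:3])
  expect_error(select_standard_genes(expr2, n_standard = 9), "shortfall")
})

test_that("median scaling equalises the standard-gene median across samples", {
  set.seed(66)
  base <- rlnorm(200, log(20), 1)
  expr <- outer(base, rep(1, 4)) * (1 + matrix(rnorm(800, 0, 0.02), 200, 4))
  rownames(expr) <- sprintf("g%03d", 1:200)
  colnames(expr) <- paste0("s", 1:4)
  # identity: identical samples give unit factors
  same <- outer(base, rep(1, 3))
  dimnames(same) <- list(rownames(expr), c("x", "y", "z"))
  sel0 <- select_standard_genes(same, 50)
  nrm0 <- median_scale_normalize(same, sel0)
  expect_equal(unname(nrm0$scale_factors), rep(1, 3))
  expect_equal(nrm0$normalized, same)
  # doubling one sample halves its factor; medians equalise exactly
  expr2 <- expr
  expr2[, 2] <- expr2[, 2] * 2
  sel <- select_standard_genes(expr2, 60)
  nrm <- median_scale_normalize(expr2, sel)
  meds <- apply(nrm$normalized[sel$gene_ids, ], 2, median)
  expect_equal(unname(meds), rep(nrm$reference, 4))
  expect_equal(unname(nrm$scale_factors[1] / nrm$scale_factors[2]), 2,
               tolerance = 0.05)
  # permuting samples permutes the factors identically
  perm <- c(3, 1, 4, 2)
  nrm_p <- median_scale_normalize(expr2[, perm], sel)
  expect_equal(nrm_p$scale_factors, nrm$scale_factors[perm])
  # zero standard median errors
  zero <- expr2; zero[, 1] <- 0
  expect_error(median_scale_normalize(zero, sel), "zero")
})

test_that("planted library scale factors are recovered from simulated counts", {
  cfg <- sim_config(seed = 11, n_background_genes = 400, chrom_length = 600000,
                    tissues = "T3", replicates_per_group = 3,
                    nb_dispersion = 0, planted_effects = NULL,
                    library_size_mean = 6e6, library_size_sdlog = 0)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  f_true <- c(0.5, 1, 2, 0.8, 1.25, 1)
  expr <- sweep(sim$counts, 2, f_true, "*")
  sel <- select_standard_genes(expr, 100)
  nrm <- median_scale_normalize(expr, sel)
  r <- nrm$scale_factors * f_true
  expect_lt(max(abs(r / median(r) - 1)), 0.02)
})

test_that("contaminant reads never change a clean gene's count", {
  s <- small_sim(seed = 12, n_bg = 25, lib = 1200)
  aln <- simulate_alignments(s$sim, s$ann, s$cfg)
  fm <- flatten_gene_models(s$ann, canonical_overrides = s$ann$canonical)
  one <- aln$alignments[[2]]
  with_ctm <- count_unique_reads(one, fm)
  clean_only <- one[!grepl(":(ovl|mm):", one$read_id), , drop = FALSE]
  without <- count_unique_reads(clean_only, fm)
  keep <- setdiff(rownames(with_ctm$counts), c("bgOvlA", "bgOvlB"))
  expect_equal(with_ctm$counts[keep, 1], without$counts[keep, 1])
})
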