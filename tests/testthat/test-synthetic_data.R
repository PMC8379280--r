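test_that("config validation rejects inconsistent fractions", {
  expect_error(sim_config(biotype_fractions = c(protein_coding = 0.5,
                                                lincRNA = 0.4)),
               "sum to 1")
  expect_error(sim_config(peak_class_props = c(D0 = 0.5, D14 = 0.2)),
               "sum to 1")
  expect_error(sim_config(coupling_rho = 1.2))
})

test_that("annotation generation is deterministic and respects structure", {
  cfg <- sim_config(seed = 101, n_genes = 400L)
  a1 <- gen_annotation(cfg)
  a2 <- gen_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_identical(as.character(a1$promoters), as.character(a2$promoters))

  g <- a1$genes
  ## biotype fractions exact under largest-remainder allocation
  expect_equal(sum(g$biotype == "antisense"), round(0.06 * 400))
  ## antisense/sense_intronic lncRNAs have coding targets
  asg <- g[g$biotype %in% c("antisense", "sense_intronic"), ]
  expect_true(all(!is.na(asg$target_gene_id)))
  expect_true(all(g[asg$target_gene_id, "biotype"] == "protein_coding"))
  ## >= 10 kb spacing between neighbours on each chromosome
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] - gg$end[-nrow(gg)] >= 10000))
    }
  }
  ## promoters centered on the TSS with the configured length
  expect_true(all(Biostrings::width(a1$promoters) == cfg$promoter_len))
})

test_that("null genes are flat and archetypes move in the planted direction", {
  cfg <- sim_config(seed = 102, n_genes = 1200L, de_fraction = 0.5)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  tp <- ct$cm$meta$time_point
  m0 <- rowMeans(ct$cm$counts[, tp == "D0"])
  m28 <- rowMeans(ct$cm$counts[, tp == "D28"])
  lfc <- log2((m28 + 0.5) / (m0 + 0.5))
  null_ids <- ct$truth$is_null
  expect_lt(abs(median(lfc[null_ids])), 0.1)
  ## cluster-6 genes (up at D28) increase in nearly all cases
  c6 <- !is.na(ct$truth$cluster) & ct$truth$cluster == 6
  expect_gte(mean(m28[c6] > m0[c6]), 0.95)
  ## planted log2FCs recorded in the truth table
  expect_equal(unname(ct$truth$lfc_D0vsD28[c6][1]), log2(cfg$archetype_fc))
})

test_that("peak classes hit their configured proportions exactly", {
  cfg <- sim_config(seed = 103, n_genes = 300L, n_peaks = 3000L)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  pk <- gen_peaks(cfg, ann$genes, ct$truth)
  tab <- table(pk$peaks$class)
  expected <- round(3000 * cfg$peak_class_props)
  for (cl in names(cfg$peak_class_props)) {
    expect_equal(unname(tab[[cl]]), unname(expected[[cl]]), tolerance = 1,
                 info = cl)
  }
  ## presence flags agree with the class label
  expect_true(all(pk$peaks$D0 == grepl("D0", pk$peaks$class)))
})

test_that("planted accessibility-expression coupling has the configured rho", {
  cfg <- sim_config(seed = 104, n_genes = 8000L, n_peaks = 18000L,
                    coupling_rho = 0.5)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  pk <- gen_peaks(cfg, ann$genes, ct$truth)
  cp <- pk$peaks[pk$peaks$coupled, ]
  expect_gte(nrow(cp), 1500)
  e <- ct$truth$lfc_D0vsD28[match(cp$gene_id, ct$truth$gene_id)]
  expect_lt(abs(cor(cp$acc_lfc, e) - 0.5), 0.07)

  cfg0 <- sim_config(seed = 105, n_genes = 12000L, n_peaks = 26000L,
                     coupling_rho = 0)
  ann0 <- gen_annotation(cfg0)
  ct0 <- gen_counts(cfg0, ann0$genes)
  pk0 <- gen_peaks(cfg0, ann0$genes, ct0$truth)
  cp0 <- pk0$peaks[pk0$peaks$coupled, ]
  e0 <- ct0$truth$lfc_D0vsD28[match(cp0$gene_id, ct0$truth$gene_id)]
  expect_lt(abs(cor(cp0$acc_lfc, e0)), 0.05)
})

test_that("fragments respect the size mixture and stay inside open peaks", {
  cfg <- sim_config(seed = 106, n_genes = 300L, n_peaks = 1000L,
                    n_fragments = 30000L)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  pk <- gen_peaks(cfg, ann$genes, ct$truth)
  fr <- gen_fragments(cfg, pk, timepoints = "D14")
  expect_equal(nrow(fr), 30000L)
  expect_lt(abs(mean(fr$end - fr$start < 100) - 0.55), 0.03)
  ## fragment midpoints outside any D14-open peak stay near background rate
  open <- pk$peaks[pk$peaks$D14, ]
  mids <- (fr$start + fr$end) %/% 2L
  mgr <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mids + 1L, mids + 1L))
  inpk <- GenomicRanges::countOverlaps(mgr, as_granges(open)) > 0
  expect_lt(mean(!inpk), cfg$background_rate + 0.02)
})

test_that("motif planting obeys the per-cluster rate and truth table", {
  pwm <- mk_cons_pwm("ACGTACGTAC", "M1", "TF1")
  cfg <- sim_config(seed = 107, n_genes = 200L, de_fraction = 0.6)
  ann <- gen_annotation(cfg)
  clusters <- setNames(ann$genes$cluster, ann$genes$gene_id)

  none <- gen_motif_plant(cfg, list(pwm), ann$promoters, clusters,
                          rates = matrix(0, 6, 1,
                                         dimnames = list(1:6, "M1")))
  expect_equal(nrow(none$truth), 0)
  expect_identical(as.character(none$promoters), as.character(ann$promoters))

  r6 <- matrix(0, 6, 1, dimnames = list(1:6, "M1")); r6["6", 1] <- 1
  full <- gen_motif_plant(cfg, list(pwm), ann$promoters, clusters, rates = r6)
  c6 <- names(clusters)[!is.na(clusters) & clusters == 6]
  expect_setequal(unique(full$truth$gene_id), c6)
  ## the planted subsequence is present at the recorded offset
  for (i in seq_len(min(5, nrow(full$truth)))) {
    tr <- full$truth[i, ]
    s <- as.character(full$promoters[[tr$gene_id]])
    ins <- substr(s, tr$offset + 1, tr$offset + nchar(tr$site))
    expected <- if (tr$strand == "+") tr$site else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tr$site)))
    expect_equal(ins, expected)
  }
})

test_that("enhancer coverage fraction and SNP placement follow the config", {
  cfg <- sim_config(seed = 108, n_genes = 300L, n_peaks = 3000L,
                    enhancer_fraction = 0.6, snp_odds = 1)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  pk <- gen_peaks(cfg, ann$genes, ct$truth)
  es <- gen_enhancer_db_and_snps(cfg, pk)
  d0 <- pk$peaks[pk$peaks$class == "D0", c("chrom", "start", "end")]
  ov <- overlap_fraction(d0, es$enhancers)
  expect_lt(abs(ov$fraction - 0.6), 0.03)
  ## all SNPs inside some peak
  sgr <- GenomicRanges::GRanges(es$snps$chrom,
                                IRanges::IRanges(es$snps$pos + 1L, es$snps$pos + 1L))
  expect_true(all(GenomicRanges::countOverlaps(
    sgr, as_granges(pk$peaks[, c("chrom", "start", "end")])) > 0))
})

test_that("strong SNP enrichment odds are detected in most replicates", {
  hit <- vapply(1:10, function(sd) {
    cfg <- sim_config(seed = sd + 300, n_genes = 300L, n_peaks = 2000L,
                      n_snps = 500L, snp_odds = 10)
    ann <- gen_annotation(cfg)
    ct <- gen_counts(cfg, ann$genes)
    pk <- gen_peaks(cfg, ann$genes, ct$truth)
    es <- gen_enhancer_db_and_snps(cfg, pk)
    target <- pk$peaks[pk$peaks$class == "D28" & !pk$peaks$coupled,
                       c("chrom", "start", "end")]
    p <- snp_overlap_test(list(D28 = target), es$snps,
                          pk$peaks[, c("chrom", "start", "end")])$p
    p < 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.8)
})
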