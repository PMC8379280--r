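test_that("Tn5 offsets shift cut sites +4/-5 and refuse double application", {
  fr <- data.frame(chrom = "chr1", start = 100L, end = 200L, strand = "+")
  sh <- tn5_shift(fr)
  expect_equal(sh$start, 104L)
  expect_equal(sh$end, 195L)
  expect_error(tn5_shift(sh), "twice")

  nos <- data.frame(chrom = "chr1", start = 10L, end = 60L)
  expect_warning(un <- tn5_shift(nos), "strand")
  expect_equal(un$start, 10L)
})

test_that("size histogram detects the configured nucleosome modes", {
  cfg <- sim_config(seed = 5)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  pk <- gen_peaks(cfg, ann$genes, ct$truth)
  fr <- gen_fragments(cfg, pk, timepoints = "D0")
  h <- size_histogram(fr)
  nuc <- h$modes[h$modes >= 150]
  expect_equal(round(nuc[1] / 10) * 10, 200)
  expect_equal(round(nuc[nuc > 300][1] / 10) * 10, 440)

  ## sub-100 bp mass matches the configured weight within 3%
  expect_lt(abs(mean(fr$end - fr$start < 100) -
                  cfg$fragment_mix$w[["sub100"]]), 0.03)

  ## unimodal input has a single mode
  uni <- data.frame(start = 0L, end = as.integer(pmax(round(rnorm(5000, 200, 20)), 50)))
  expect_equal(length(size_histogram(uni)$modes), 1L)
})

test_that("consensus merging joins peaks with gaps up to 100 bp inclusive", {
  ps <- list(
    D0 = data.frame(chrom = "c1", start = 100L, end = 200L),
    D14 = data.frame(chrom = "c1", start = 250L, end = 300L)
  )
  m <- merge_consensus(ps)
  expect_equal(nrow(m), 1)  # gap 50 merges
  expect_equal(m$start, 100)
  expect_equal(m$end, 300)
  expect_equal(m$present_in, "D0,D14")

  far <- list(D0 = data.frame(chrom = "c1", start = 100L, end = 200L),
              D14 = data.frame(chrom = "c1", start = 350L, end = 400L))
  expect_equal(nrow(merge_consensus(far)), 2)  # gap 150 stays apart

  edge <- list(D0 = data.frame(chrom = "c1", start = 100L, end = 200L),
               D14 = data.frame(chrom = "c1", start = 300L, end = 400L))
  expect_equal(nrow(merge_consensus(edge)), 1)  # gap exactly 100 merges

  chr <- list(D0 = data.frame(chrom = c("c1", "c2"),
                              start = c(100L, 150L), end = c(200L, 220L)))
  expect_equal(nrow(merge_consensus(chr)), 2)  # never across chromosomes
})

test_that("consensus merging is order-invariant and idempotent", {
  set.seed(33)
  mk <- function() {
    n <- 50
    st <- sort(sample(seq(0, 20000, by = 10), n))
    data.frame(chrom = "c1", start = st, end = st + sample(50:300, n, TRUE))
  }
  sets <- list(D0 = mk(), D14 = mk(), D28 = mk())
  m1 <- merge_consensus(sets)
  shuf <- lapply(sets, function(p) p[sample.int(nrow(p)), ])
  m2 <- merge_consensus(shuf)
  expect_equal(m1[, c("chrom", "start", "end", "present_in")],
               m2[, c("chrom", "start", "end", "present_in")])
  again <- merge_consensus(list(D0 = m1[, c("chrom", "start", "end")]))
  expect_equal(again[, c("start", "end")], m1[, c("start", "end")])
})

test_that("Venn categories count presence subsets and percentages", {
  ps <- list(
    D0 = data.frame(chrom = "c1", start = 0L, end = 100L),
    D14 = data.frame(chrom = "c1", start = 5000L, end = 5100L),
    D28 = data.frame(chrom = "c1", start = 9000L, end = 9100L)
  )
  v <- venn_categories(merge_consensus(ps))
  expect_equal(v$count[v$subset %in% c("D0", "D14", "D28")], c(1L, 1L, 1L))
  expect_equal(sum(v$count), attr(v, "total"))
  expect_equal(v$count[v$subset == "D0,D14,D28"], 0L)

  same <- list(D0 = ps$D0, D14 = ps$D0, D28 = ps$D0)
  v2 <- venn_categories(merge_consensus(same))
  expect_equal(v2$count[v2$subset == "D0,D14,D28"], 1L)
  expect_equal(sum(v2$count), 1L)
})

test_that("peak annotation uses midpoint, promoter window and priority", {
  genes <- data.frame(
    gene_id = c("gp", "gm"), name = c("gp", "gm"), chrom = "c1",
    strand = c("+", "-"), start = c(10000L, 50000L), end = c(20000L, 60000L),
    tss = c(10000L, 60000L), biotype = "protein_coding",
    target_gene_id = NA, length_bp = 10000L, stringsAsFactors = FALSE
  )
  genes$exons <- list(cbind(start = c(10000L, 15000L), end = c(12000L, 20000L)),
                      cbind(start = 50000L, end = 60000L))
  peaks <- data.frame(
    peak_id = paste0("p", 1:5), chrom = "c1",
    start = c(9400L, 13000L, 11000L, 200000L, 60400L),
    end = c(9600L, 13200L, 11200L, 200200L, 60600L),
    stringsAsFactors = FALSE
  )
  a <- annotate_peaks(peaks, genes)
  expect_equal(a$category,
               c("promoter-TSS",  # 500 bp upstream of + TSS
                 "intron",        # midpoint 13100 between exons, 3.1 kb from TSS
                 "exon",          # inside first exon
                 "intergenic",    # far from everything
                 "promoter-TSS")) # 500 bp upstream of - TSS (to the right)
  expect_equal(a$nearest_gene[1], "gp")
  expect_equal(a$dist_to_tss[1], -500L)
  expect_equal(a$dist_to_tss[5], -500L)  # oriented: upstream is negative

  expect_warning(b <- annotate_peaks(peaks, genes[0, ]), "empty annotation")
  expect_true(all(b$category == "intergenic"))
})

test_that("annotation categories partition every peak exactly once", {
  cfg <- sim_config(seed = 9, n_genes = 300L, n_peaks = 800L)
  ann <- gen_annotation(cfg)
  ct <- gen_counts(cfg, ann$genes)
  pk <- gen_peaks(cfg, ann$genes, ct$truth)
  a <- annotate_peaks(pk$peaks, ann$genes)
  cats <- c("promoter-TSS", "TTS", "5UTR", "3UTR", "exon", "intron",
            "intergenic")
  expect_true(all(a$category %in% cats))
  expect_equal(length(a$category), nrow(pk$peaks))
})

test_that("differential accessibility applies the strict |lfc| and raw-p rule", {
  set.seed(55)
  n <- 2000
  counts <- cbind(A = rnbinom(n, mu = 300, size = 100),
                  B = rnbinom(n, mu = 300, size = 100))
  de <- 1:150
  counts[de, "B"] <- rnbinom(length(de), mu = 2400, size = 100)
  rownames(counts) <- paste0("p", 1:n)
  res <- diff_accessibility(counts, c("A", "B"), comparison = "D0vsD28")
  expect_gte(mean(res$significant[match(paste0("p", de), res$gene_id)]), 0.9)
  expect_lt(mean(res$significant[-de], na.rm = TRUE), 0.02)
  expect_true(all(res$low_confidence))

  ## boundary: |log2FC| must strictly exceed the threshold
  fake <- res[1, ]; fake$log2fc <- 1.5; fake$p <- 1e-9
  expect_false(abs(fake$log2fc) > 1.5 & fake$p < 0.05)

  same <- cbind(A = rep(100L, 10), B = rep(100L, 10))
  rownames(same) <- paste0("q", 1:10)
  expect_equal(sum(diff_accessibility(same, c("A", "B"))$significant), 0)
})

test_that("overlap fractions report numerator and denominator", {
  q <- data.frame(chrom = "c1", start = c(0L, 1000L, 2000L, 3000L),
                  end = c(100L, 1100L, 2100L, 3100L))
  db <- data.frame(chrom = "c1", start = c(50L, 1050L), end = c(60L, 1060L))
  r <- overlap_fraction(q, db)
  expect_equal(r$fraction, 0.5)
  expect_equal(r$label, "50% (2/4)")
  expect_equal(overlap_fraction(q, db[0, ])$fraction, 0)
})

test_that("SNP overlap test matches enumeration on a toy universe", {
  universe <- data.frame(chrom = "c1", start = seq(0L, 1100L, by = 100L),
                         end = seq(50L, 1150L, by = 100L))  # 12 peaks
  snps <- data.frame(chrom = "c1", pos = c(10L, 110L, 210L, 310L))  # in peaks 1-4
  cls <- list(first3 = universe[1:3, ], last6 = universe[7:12, ])
  res <- snp_overlap_test(cls, snps, universe)
  expect_equal(res$x, c(3L, 0L))
  expect_equal(res$K, c(4L, 4L))
  expect_equal(res$p[1], hyper_oracle(3, 4, 3, 12), tolerance = 1e-12)
  expect_equal(res$p[2], hyper_oracle(0, 4, 6, 12), tolerance = 1e-12)

  none <- snp_overlap_test(cls, snps[0, ], universe)
  expect_true(all(none$p == 1))
})

test_that("locus Mann-Whitney matches rank-assignment enumeration", {
  r <- locus_mw_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$p, 0.1)  # 2/20 assignments as extreme, two-sided
  expect_equal(r$method, "exact")

  tied <- locus_mw_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(tied$p, 1)

  ## equal scaling of both totals leaves p unchanged
  a <- c(3, 9, 27, 81); b <- c(4, 8, 40, 100)
  p1 <- locus_mw_test(a, b, total_a = 1e6, total_b = 1e6)$p
  p2 <- locus_mw_test(a, b, total_a = 2e6, total_b = 2e6)$p
  expect_equal(p1, p2)

  expect_error(locus_mw_test(c(1, 2), c(3, 4)), "3 OCRs")
})
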