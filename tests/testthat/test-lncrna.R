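mk_de_table <- function(n_lnc = 20, n_coding = 80, seed = 3) {
  set.seed(seed)
  n <- n_lnc + n_coding
  data.frame(
    gene_id = sprintf("g%03d", 1:n), comparison = "D0vsD14",
    base_mean = 100, log2fc = rnorm(n, 0, 3), se = 1, stat = 1,
    p = runif(n, 0, 0.01), q = runif(n, 0, 0.04),
    dispersion = 0.1, low_confidence = FALSE,
    max_fpkm = 5, is_deg = TRUE,
    biotype = rep(c("lincRNA", "protein_coding"), c(n_lnc, n_coding)),
    stringsAsFactors = FALSE
  )
}

test_that("top-N ranking is by |linear FC| with deterministic tie-breaks", {
  d <- mk_de_table()
  d$log2fc <- rep(0.1, nrow(d))
  d$log2fc[1:3] <- c(5, 5, 4)   # tie between rows 1 and 2
  d$q[1:2] <- c(0.02, 0.01)
  r <- rank_degs(d)
  expect_equal(r$gene_id[1:2], c("g002", "g001"))  # smaller q first on tie
  expect_true(all(diff(abs(r$log2fc)) <= 1e-12))
})

test_that("top-N biotype hypergeometric matches the exact tail", {
  d <- mk_de_table(n_lnc = 20, n_coding = 80)
  ## force 6 lncRNAs into the top 10 by giving them the largest |FC|
  d$log2fc <- 0.1
  d$log2fc[1:6] <- 10         # lncRNAs
  d$log2fc[21:24] <- 9        # coding
  tt <- topn_biotype_test(d, 10)
  expect_equal(tt$n_lnc, 6)
  expect_equal(tt$n_coding, 4)
  p_exp <- sum(dhyper(6:10, 20, 80, 10))  # 0.003933: exact upper tail
  expect_equal(tt$p_lnc, p_exp, tolerance = 1e-12)
  expect_true(tt$lnc_more_significant)

  ## top N all coding with no DE lncRNA at all -> p_lnc = 1
  d2 <- mk_de_table(n_lnc = 0, n_coding = 50)
  t2 <- topn_biotype_test(d2, 10)
  expect_equal(t2$p_lnc, 1)

  ## N = M -> x = K and p = 1 for both biotypes
  d3 <- mk_de_table(n_lnc = 5, n_coding = 10)
  t3 <- topn_biotype_test(d3, 15)
  expect_equal(t3$n_lnc, 5)
  expect_equal(t3$p_lnc, 1)
  expect_equal(t3$p_coding, 1)
})

test_that("top-N hypergeometric equals brute-force enumeration for M <= 15", {
  d <- mk_de_table(n_lnc = 4, n_coding = 8, seed = 11)
  for (N in c(3, 5, 8)) {
    tt <- topn_biotype_test(d, N)
    expect_equal(tt$p_lnc, hyper_oracle(tt$n_lnc, 4, N, 12), tolerance = 1e-12)
  }
})

test_that("lncRNA class enrichment uses the annotated lncRNA population", {
  ann <- data.frame(
    gene_id = sprintf("L%02d", 1:40),
    biotype = rep(c("lincRNA", "antisense"), each = 20),
    stringsAsFactors = FALSE
  )
  ## all DE lncRNAs lincRNA, 50% of annotation is lincRNA, n = 20
  res <- lnc_class_enrichment(sprintf("L%02d", 1:20), ann)
  expect_lt(res$p[res$class == "lincRNA"], 1e-5)
  expect_equal(res$p[res$class == "antisense"], 1)
  ## no DE lncRNAs -> all p = 1
  res0 <- lnc_class_enrichment(character(), ann)
  expect_true(all(res0$p == 1))
})

test_that("pair correlation handles exact, negated and constant series", {
  fp <- rbind(l1 = 2^(1:8) - 1, t1 = 2^(1:8) - 1,
              l2 = 2^(1:8) - 1, t2 = 2^(8:1) - 1,
              l3 = rep(3, 8), t3 = 2^(1:8) - 1)
  pairs <- data.frame(lncrna_id = c("l1", "l2", "l3"),
                      target_id = c("t1", "t2", "t3"))
  res <- lnc_target_correlation(fp, pairs)
  expect_equal(res$r[1], 1)
  expect_equal(res$direction[1], "positive")
  expect_equal(res$r[2], -1)
  expect_equal(res$direction[2], "negative")
  expect_true(res$constant[3])
  expect_true(is.na(res$r[3]))
})

test_that("planted r = 0.8 pairs are detected in most replicates", {
  hit <- vapply(1:20, function(sd) {
    set.seed(sd + 600)
    z <- rnorm(10)
    a <- 0.8 * z + sqrt(1 - 0.64) * rnorm(10)
    fp <- rbind(l = 2^(3 + z) - 1, t = 2^(3 + a) - 1)
    res <- lnc_target_correlation(fp, data.frame(lncrna_id = "l",
                                                 target_id = "t"))
    res$significant[1]
  }, TRUE)
  expect_gte(mean(hit), 0.7)
})

test_that("pair-correlation summary computes the printed percentages", {
  tab <- data.frame(significant = rep(c(TRUE, FALSE), c(54, 42)),
                    direction = c(rep("positive", 49), rep("negative", 5),
                                  rep("positive", 42)))
  s <- summarize_pair_correlations(tab)
  expect_equal(s$pct_significant, 56)
  expect_equal(s$pct_positive, 91)
  expect_equal(s$label_significant, "56% (54/96)")
  expect_equal(s$label_positive, "91% (49/54)")
})

test_that("fold-change concordance classifies sign combinations", {
  de <- data.frame(gene_id = c("l1", "t1", "l2", "t2"),
                   log2fc = c(3, 3, 3, -3),
                   is_deg = c(TRUE, TRUE, TRUE, FALSE))
  pairs <- data.frame(lncrna_id = c("l1", "l2"), target_id = c("t1", "t2"))
  res <- fc_concordance(pairs, list(D0vsD14 = de))
  expect_equal(res$class, c("both_up", "discordant"))
  expect_equal(res$both_de, c(TRUE, FALSE))
  de2 <- de; de2$log2fc <- c(-1, -2, -1, -2)
  res2 <- fc_concordance(pairs, list(D0vsD28 = de2))
  expect_equal(res2$class, c("both_down", "both_down"))
})
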