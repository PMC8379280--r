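uniform_pwm <- function(L = 3) {
  list(motif_id = "U", tf_name = "U",
       probs = matrix(0.25, L, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
       background = rep(0.25, 4))
}

test_that("log-odds scores follow the floored log-ratio definition", {
  u <- uniform_pwm()
  expect_true(all(abs(log_odds(u)) < 1e-9))

  p <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pw <- list(motif_id = "C", tf_name = "C", probs = p,
             background = rep(0.25, 4))
  s <- log_odds(pw)
  expect_equal(unname(s[1, "A"]), 2, tolerance = 1e-3)    # ~log2(4)
  expect_true(all(is.finite(s)))                  # floor keeps p=0 finite
})

test_that("score p-values equal brute-force word enumeration", {
  set.seed(81)
  for (L in c(2, 4, 6, 8)) {
    probs <- matrix(rexp(4 * L), L, 4)
    probs <- probs / rowSums(probs)
    colnames(probs) <- c("A", "C", "G", "T")
    pwm <- list(motif_id = "R", tf_name = "R", probs = probs,
                background = rep(0.25, 4))
    g <- round(log_odds(pwm) * 1000)
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    wsc <- rowSums(matrix(g[cbind(rep(1:L, each = nrow(words)),
                                  as.vector(words))], ncol = L))
    for (s in unique(quantile(wsc, c(0, 0.25, 0.5, 0.9, 1), type = 1))) {
      expect_equal(score_pvalue(pwm, s / 1000, background = rep(0.25, 4)),
                   mean(wsc >= s), tolerance = 1e-12)
    }
  }
})

test_that("a length-4 consensus PWM has max-score p of 1/256 and min-score p 1", {
  pwm <- mk_cons_pwm("ACGT", "C4", consensus_weight = 1 - 3e-12)
  g <- round(log_odds(pwm) * 1000)
  smax <- sum(apply(g, 1, max)) / 1000
  smin <- sum(apply(g, 1, min)) / 1000
  expect_equal(score_pvalue(pwm, smax, background = rep(0.25, 4)), 1 / 256)
  expect_equal(score_pvalue(pwm, smin, background = rep(0.25, 4)), 1)
})

test_that("scanning finds planted sites at the right offset and strand", {
  set.seed(82)
  pwm <- mk_cons_pwm("ACGTACGTAC", "M10", "TF10")
  seqs <- rand_seqs(40, 400)
  substr(seqs[["s7"]], 101, 110) <- "ACGTACGTAC"
  hits <- scan_pwms(list(pwm), seqs, background = "uniform")
  h7 <- hits[hits$sequence_id == "s7", ]
  expect_equal(h7$offset, 100L)
  expect_equal(h7$strand, "+")
  expect_true(all(hits$q < 0.1))

  ## reverse-complementing every sequence flips the strand, keeps the hit
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  names(rc) <- names(seqs)
  hrc <- scan_pwms(list(pwm), rc, background = "uniform")
  h7rc <- hrc[hrc$sequence_id == "s7", ]
  expect_equal(h7rc$strand, "-")
  expect_equal(h7rc$offset, 400L - 110L)  # same site, forward offset of RC
  expect_equal(h7rc$score, h7$score)

  ## sequences shorter than the motif give no hits and no error
  expect_equal(nrow(scan_pwms(list(pwm), c(tiny = "ACGT"))), 0)
})

test_that("pure background sequences rarely retain hits at q < 0.1", {
  pwm <- mk_cons_pwm("ACGTACGTAC", "M10")
  n_retained <- vapply(1:20, function(sd) {
    set.seed(sd + 900)
    nrow(scan_pwms(list(pwm), rand_seqs(30, 300, prefix = "b"),
                   background = "uniform"))
  }, 1L)
  ## BH at q < 0.1 under the full null bounds the chance of any discovery
  expect_lte(mean(n_retained > 0), 0.35)
  expect_lt(sum(n_retained) / (20 * 30 * 291 * 2), 0.001)
})

test_that("cluster motif matrix counts gene hits and applies both filters", {
  clusters <- setNames(rep(1:6, each = 10), paste0("g", 1:60))
  ## TF_X hits every cluster-6 gene plus a varied nonzero background
  bg <- paste0("g", c(1, 2, 11, 21, 22, 31, 41))
  hits <- data.frame(motif_id = "MX",
                     sequence_id = c(names(clusters)[clusters == 6], bg))
  motif_tf <- c(MX = "TF_X")
  m <- cluster_motif_matrix(hits, clusters, motif_tf)
  expect_equal(unname(m["TF_X", "6"]), 100)
  expect_equal(unname(m["TF_X", "1"]), 20)
  expect_equal(unname(m["TF_X", "5"]), 10)

  ## unexpressed TF dropped
  m2 <- cluster_motif_matrix(hits, clusters, motif_tf,
                             tf_fpkm = c(TF_X = 0.5))
  expect_false("TF_X" %in% rownames(m2))

  ## constant-frequency TF dropped by the MAD filter
  hits3 <- data.frame(motif_id = "MY", sequence_id = names(clusters))
  m3 <- cluster_motif_matrix(hits3, clusters, c(MY = "TF_Y"))
  expect_false("TF_Y" %in% rownames(m3))
})

test_that("promoter/enhancer frequencies pick each TF's best motif", {
  annp <- data.frame(peak_id = paste0("pk", 1:20),
                     category = rep(c("promoter-TSS", "intron"), each = 10))
  hits <- rbind(
    data.frame(motif_id = "A1", sequence_id = paste0("pk", 1:6)),
    data.frame(motif_id = "A2", sequence_id = paste0("pk", 1:2)),
    data.frame(motif_id = "B1", sequence_id = paste0("pk", 11:14))
  )
  motif_tf <- c(A1 = "TFA", A2 = "TFA", B1 = "TFB")
  out <- promoter_enhancer_frequency(hits, annp, motif_tf)
  expect_equal(out$motif_id[out$tf == "TFA"], "A1")  # higher summed frequency
  expect_equal(out$freq_promoter[out$tf == "TFA"], 60)
  expect_equal(out$freq_enhancer[out$tf == "TFA"], 0)
  expect_equal(out$freq_enhancer[out$tf == "TFB"], 40)

  ## restriction to DE TFs with a named exception
  only <- promoter_enhancer_frequency(hits, annp, motif_tf, de_tfs = "TFB",
                                      include = character())
  expect_equal(only$tf, "TFB")
  both <- promoter_enhancer_frequency(hits, annp, motif_tf, de_tfs = "TFB",
                                      include = "TFA")
  expect_setequal(both$tf, c("TFA", "TFB"))
})

test_that("TF-DEG correlation is exact for self-pairs and calibrated for noise", {
  set.seed(83)
  fp <- matrix(2^rnorm(300 * 10, 4), 300, 10,
               dimnames = list(paste0("g", 1:300), paste0("s", 1:10)))
  res <- tf_deg_correlation(fp, tfs = "g1", degs = c("g1", "g2"))
  expect_equal(res$records$r[res$records$gene_id == "g1"], 1)

  ## independent genes: significant fraction small at FDR < 0.05
  res2 <- tf_deg_correlation(fp, tfs = "g1", degs = paste0("g", 2:300))
  expect_lte(mean(res2$records$significant), 0.07)

  ## planted co-regulated block is mostly recovered
  hitrate <- vapply(1:10, function(sd) {
    set.seed(sd + 950)
    z <- rnorm(10)
    block <- t(sapply(1:30, function(i) 2^(4 + 2 * z + rnorm(10, 0, 0.5)) - 1))
    rownames(block) <- paste0("b", 1:30)
    colnames(block) <- paste0("s", 1:10)
    fp2 <- rbind(TF = 2^(4 + 2 * z) - 1, block)
    r <- tf_deg_correlation(fp2, tfs = "TF", degs = paste0("b", 1:30))
    mean(r$records$significant & r$records$r > 0)
  }, 1.0)
  expect_gte(mean(hitrate), 0.8)
})
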