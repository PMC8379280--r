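## Differential expression: median-of-ratios normalization, FPKM, a
## negative-binomial Wald test with trend-shrunk method-of-moments
## dispersions, BH correction, and the compound DEG-calling rule
## (FPKM >= 1 in any replicate of the comparison, linear |FC| > 4, FDR < 0.05).

#' Median-of-ratios size factors
#'
#' For each sample j the factor is the median over genes of
#' count_ij / geometric-mean_i(counts), where genes with any zero count are
#' excluded from the median (they have no finite log geometric mean).
#'
#' @param counts integer matrix (genes x samples) or a `count_matrix`.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) {
    stop("no gene has nonzero counts in every sample; ",
         "consider a pseudo-reference fallback")
  }
  lc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lc)  # log geometric mean per gene
  sf <- apply(lc, 2, function(x) exp(median(x - ref)))
  stopifnot(all(sf > 0))
  sf
}

#' Fragments per kilobase per million mapped reads
#'
#' fpkm_ij = count_ij / (length_i / 1e3 * total_j / 1e6).
#'
#' @param counts matrix (genes x samples) or `count_matrix`.
#' @param gene_lengths numeric vector of exonic lengths in bp, matched to rows.
#' @param totals per-sample mapped totals; default column sums.
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, gene_lengths, totals = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("zero library total")
  sweep(counts / (gene_lengths / 1e3), 2, totals / 1e6, "/")
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
#' NaN/NA p-values propagate with a warning.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NA allowed).
#' @return vector of q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals)) warning("NA/NaN p-values propagated through BH adjustment")
  p.adjust(pvals, method = "BH")
}

## Method-of-moments variance decomposition per row of normalized counts,
## using within-group variability only: total squared CV, its expected
## shot-noise (counting) component, and the implied NB dispersion.
mom_dispersion <- function(norm, group_idx, sf) {
  n_used <- 0
  ssq <- rep(0, nrow(norm))
  shot <- rep(0, nrow(norm))  # expected counting variance on normalized scale
  mu <- rowMeans(norm)
  for (g in group_idx) {
    if (length(g) < 2L) next
    sub <- norm[, g, drop = FALSE]
    m <- rowMeans(sub)
    ssq <- ssq + rowSums((sub - m)^2)
    shot <- shot + (length(g) - 1L) * m * mean(1 / sf[g])
    n_used <- n_used + length(g) - 1L
  }
  if (n_used == 0L) {
    na <- rep(NA_real_, nrow(norm))
    return(list(alpha = na, cv2 = na, shot_cv2 = na, mu = mu, df = 0L))
  }
  s2 <- ssq / n_used
  cv2 <- ifelse(mu > 0, s2 / mu^2, NA_real_)
  shot_cv2 <- ifelse(mu > 0, (shot / n_used) / mu^2, NA_real_)
  alpha <- cv2 - shot_cv2
  alpha[!is.na(alpha) & alpha <= 0] <- NA_real_  # no excess over counting noise
  list(alpha = alpha, cv2 = cv2, shot_cv2 = shot_cv2, mu = mu, df = n_used)
}

## Mean-dispersion trend. Within log-mean bins, takes the `prob` quantile of
## the total squared CV, inverts the scaled chi-square sampling distribution
## of a variance estimate with `df` degrees of freedom (exact for the full,
## untruncated distribution), subtracts the bin's median shot-noise CV^2,
## and connects bins by log-log interpolation, held flat beyond the ends.
## A low `prob` resists upward contamination by rows with genuine
## between-group signal.
fit_dispersion_trend <- function(mom, df, prob = 0.5) {
  ok <- is.finite(mom$cv2) & mom$mu > 0
  if (sum(ok) < 10L) {
    fb <- max(stats::median(mom$alpha, na.rm = TRUE), 0.01, na.rm = TRUE)
    if (!is.finite(fb)) fb <- 0.01
    return(function(m) rep(fb, length(m)))
  }
  qfac <- stats::qchisq(prob, df) / df
  bins <- cut(log(mom$mu[ok]), breaks = 8)
  bm <- as.numeric(tapply(mom$mu[ok], bins, median))
  bcv <- as.numeric(tapply(mom$cv2[ok], bins, quantile, probs = prob,
                           na.rm = TRUE)) / qfac
  bshot <- as.numeric(tapply(mom$shot_cv2[ok], bins, median, na.rm = TRUE))
  bd <- pmax(bcv - bshot, 1e-6)
  use <- is.finite(bm) & is.finite(bd) & bd > 0
  bm <- bm[use]; bd <- bd[use]
  if (length(bm) < 2L) {
    fb <- max(bd, 1e-4)
    return(function(m) rep(fb, length(m)))
  }
  function(m) {
    exp(stats::approx(log(bm), log(bd), xout = log(pmax(m, 1e-8)),
                      rule = 2)$y)
  }
}

#' Negative-binomial Wald test for one two-group comparison
#'
#' Counts are normalized by size factors; per-gene dispersions are estimated
#' by method of moments from within-group variability, then shrunk toward a
#' parametric mean-dispersion trend (weighted geometric interpolation,
#' floored at 1e-8); genes whose raw estimate exceeds four times the trend
#' are treated as dispersion outliers and keep their raw value. The log2
#' fold-change uses a pseudo-count of 0.5 on
#' normalized group means and is tested with a two-sided normal Wald
#' statistic. Groups with a single sample take the trend dispersion alone
#' and the result carries `low_confidence = TRUE`.
#'
#' @param counts matrix (genes x samples) or `count_matrix`.
#' @param groups factor/vector of length ncol with exactly two levels;
#'   fold-changes are second level relative to first.
#' @param sf size factors; computed by [size_factors()] if NULL.
#' @param comparison label stored in the result (e.g. "D0vsD14").
#' @param shrink_weight weight of the trend in log-dispersion interpolation.
#' @return data.frame with gene_id, comparison, base_mean, log2fc, se, stat,
#'   p, q, dispersion, low_confidence.
#' @export
nb_test <- function(counts, groups, sf = NULL, comparison = "AvsB",
                    shrink_weight = 1) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  groups <- as.factor(as.character(groups))
  stopifnot(nlevels(groups) == 2L, ncol(counts) == length(groups))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  single <- length(ia) < 2L || length(ib) < 2L

  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  base_mean <- rowMeans(norm)
  ps <- 0.5
  lfc <- log2((mu_b + ps) / (mu_a + ps))

  if (single) {
    ## no within-group replication: estimate the trend from the subset of
    ## rows with small observed fold-change (noise-dominated), pooling all
    ## samples as replicates of a common mean; the low trend quantile
    ## resists contamination by rows with genuine between-group signal
    mom <- mom_dispersion(norm, list(c(ia, ib)), sf)
    quiet <- abs(lfc) < 1 & base_mean > 0
    momq <- lapply(mom[c("alpha", "cv2", "shot_cv2", "mu")], `[`, quiet)
    trend <- fit_dispersion_trend(momq, mom$df, prob = 0.25)
    disp <- pmax(trend(base_mean), 1e-8)
  } else {
    mom <- mom_dispersion(norm, list(ia, ib), sf)
    trend <- fit_dispersion_trend(mom, mom$df)
    tr <- pmax(trend(base_mean), 1e-8)
    gene <- pmax(ifelse(is.finite(mom$alpha), mom$alpha, tr), 1e-8)
    disp <- exp(shrink_weight * log(tr) + (1 - shrink_weight) * log(gene))
    outlier <- gene > 4 * tr  # keep genuinely over-dispersed genes unshrunk
    disp[outlier] <- gene[outlier]
  }

  ## delta-method SE of log2 of the (pseudo-counted) group means
  vgrp <- function(mu, idx) {
    n <- length(idx)
    v <- (mu * sum(1 / sf[idx]) + n * disp * mu^2) / n^2
    v / ((mu + ps)^2 * log(2)^2)
  }
  se <- sqrt(vgrp(mu_a, ia) + vgrp(mu_b, ib))
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(stat))

  zero <- mu_a == 0 & mu_b == 0
  lfc[zero] <- 0; p[zero] <- 1; stat[zero] <- 0

  out <- data.frame(
    gene_id = rownames(counts), comparison = comparison,
    base_mean = base_mean, log2fc = lfc, se = se, stat = stat,
    p = p, q = bh_fdr(p), dispersion = disp,
    low_confidence = single, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Apply the three-way DEG rule and compile the DEG list
#'
#' A gene is differentially expressed in a comparison when its BH FDR is
#' below `fdr`, its linear fold-change exceeds `fc` in either direction
#' (|log2FC| > log2(fc)), and at least one replicate of the comparison has
#' FPKM at or above `fpkm_min`. The union of DEGs across comparisons is the
#' compiled DEG list.
#'
#' @param de_results data.frame from [nb_test()] (one or several comparisons
#'   row-bound together).
#' @param fpkm_matrix FPKM matrix, rows matching gene_id.
#' @param sample_groups named list comparison -> character vector of sample
#'   columns involved in that comparison; NULL uses all columns.
#' @param fc linear fold-change threshold (default 4).
#' @param fdr FDR threshold (default 0.05).
#' @param fpkm_min expression floor (default 1).
#' @param biotypes optional named character vector gene_id -> biotype.
#' @return `de_results` with columns max_fpkm, is_deg (and biotype, is_lncrna
#'   when biotypes given); attribute "deg_ids" holds the compiled union.
#' @export
call_degs <- function(de_results, fpkm_matrix, sample_groups = NULL,
                      fc = 4, fdr = 0.05, fpkm_min = 1, biotypes = NULL) {
  missing <- setdiff(de_results$gene_id, rownames(fpkm_matrix))
  if (length(missing)) {
    warning(length(missing), " gene(s) missing FPKM excluded from DEG calling")
    de_results <- de_results[!de_results$gene_id %in% missing, , drop = FALSE]
  }
  max_fpkm <- numeric(nrow(de_results))
  for (cmp in unique(de_results$comparison)) {
    cols <- if (!is.null(sample_groups) && cmp %in% names(sample_groups)) {
      sample_groups[[cmp]]
    } else colnames(fpkm_matrix)
    idx <- de_results$comparison == cmp
    max_fpkm[idx] <- apply(
      fpkm_matrix[de_results$gene_id[idx], cols, drop = FALSE], 1, max)
  }
  de_results$max_fpkm <- max_fpkm
  de_results$is_deg <- de_results$q < fdr &
    abs(de_results$log2fc) > log2(fc) &
    de_results$max_fpkm >= fpkm_min
  if (!is.null(biotypes)) {
    de_results$biotype <- unname(biotypes[de_results$gene_id])
    de_results$is_lncrna <- is_lncrna(de_results$biotype)
  }
  attr(de_results, "deg_ids") <-
    sort(unique(de_results$gene_id[de_results$is_deg]))
  de_results
}

#' Optional per-batch centering of log counts
#'
#' Removes a multiplicative batch effect by dividing each sample's counts by
#' its batch's geometric-mean deviation per gene, then rounding back to
#' integers. Off by default in the pipeline.
#'
#' @param cm a `count_matrix` whose metadata has a `batch` column.
#' @return a `count_matrix` with adjusted counts.
#' @export
adjust_batch <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"), "batch" %in% names(cm$meta))
  lc <- log1p(cm$counts)
  center <- rowMeans(lc)
  adj <- lc
  for (b in unique(cm$meta$batch)) {
    j <- cm$meta$batch == b
    dev <- rowMeans(lc[, j, drop = FALSE]) - center
    adj[, j] <- lc[, j, drop = FALSE] - dev
  }
  counts <- matrix(as.integer(round(pmax(expm1(adj), 0))), nrow = nrow(adj),
                   dimnames = dimnames(cm$counts))
  count_matrix(counts, cm$meta)
}
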