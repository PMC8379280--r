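## PWM motif analysis: log-odds scoring, exact score p-values by dynamic
## programming over the background model, FDR-filtered scanning of both
## strands, motif-frequency matrices by expression cluster, promoter vs
## enhancer frequency comparison, and TF-DEG expression correlation.

SCORE_GRID <- 1000L  # scores discretized to 1e-3 bits

#' Log-odds score matrix of a PWM
#'
#' Entries are log2((p + eps) / (b + eps)) with a pseudo-probability floor
#' eps = 1e-4 keeping scores finite at p = 0.
#'
#' @param pwm a PWM (list with probs and background).
#' @param background optional length-4 background overriding the PWM's own.
#' @return L x 4 matrix of log2 odds scores.
#' @export
log_odds <- function(pwm, background = NULL) {
  eps <- 1e-4
  b <- if (is.null(background)) pwm$background else background
  s <- log2(sweep(pwm$probs + eps, 2, as.numeric(b) + eps, "/"))
  dimnames(s) <- dimnames(pwm$probs)
  s
}

## Integer-grid PSSM and the exact null score distribution: a dynamic
## programming convolution of per-position score distributions under the
## background model. Returns the grid matrix and a tail function.
pssm_null <- function(pwm, background = NULL) {
  b <- as.numeric(if (is.null(background)) pwm$background else background)
  s <- log_odds(pwm, background)
  g <- matrix(as.integer(round(s * SCORE_GRID)), nrow(s), 4,
              dimnames = dimnames(s))
  lo <- sum(apply(g, 1, min)); hi <- sum(apply(g, 1, max))
  dist <- c(1)  # prob vector over offsets lo_cur..hi_cur, starts at score 0
  lo_cur <- 0L; hi_cur <- 0L
  for (i in seq_len(nrow(g))) {
    nlo <- lo_cur + min(g[i, ]); nhi <- hi_cur + max(g[i, ])
    new <- numeric(nhi - nlo + 1L)
    for (base in 1:4) {
      off <- lo_cur + g[i, base] - nlo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + b[base] * dist
    }
    dist <- new; lo_cur <- nlo; hi_cur <- nhi
  }
  tail <- rev(cumsum(rev(dist)))  # P(S >= lo_cur + k - 1)
  tail <- pmin(tail, 1)
  list(grid = g, lo = lo_cur, hi = hi_cur, dist = dist, tail = tail)
}

#' Exact p-value of a PWM score under the background model
#'
#' P(score >= s) for a random word drawn from the 0-order background,
#' computed exactly on the 1e-3-bit score grid by dynamic programming.
#' Scores above the maximum achievable get the smallest positive grid mass.
#'
#' @param pwm a PWM.
#' @param score log2-odds score (bits).
#' @param background optional background override.
#' @return exact tail probability in (0, 1].
#' @export
score_pvalue <- function(pwm, score, background = NULL) {
  nd <- pssm_null(pwm, background)
  score_pvalue_grid(nd, as.integer(round(score * SCORE_GRID)))
}

score_pvalue_grid <- function(nd, gscore) {
  k <- gscore - nd$lo + 1L
  n <- length(nd$tail)
  p <- numeric(length(k))
  p[k <= 0L] <- 1
  inr <- k >= 1L & k <= n
  p[inr] <- nd$tail[k[inr]]
  above <- k > n
  if (any(above)) {
    pos <- nd$dist[nd$dist > 0]
    p[above] <- min(pos)  # 0-adjacent smallest grid mass
  }
  pmax(p, .Machine$double.xmin)
}

base_codes <- function(seqs) {
  lapply(as.character(seqs), function(s) {
    as.integer(strsplit(chartr("ACGTN", "12345", s), "")[[1]])
  })
}

#' Scan sequences for PWM occurrences with FDR control
#'
#' Both strands of every sequence are scored at every offset on the
#' 1e-3-bit grid; exact p-values come from the dynamic-programming null and
#' BH is applied per motif across all positions x sequences x strands. Hits
#' with q below `q_threshold` are retained. N bases contribute a score of 0.
#' By default the 0-order background is estimated from the scanned
#' sequences; `background = "uniform"` uses 1/4 per base.
#'
#' @param pwms list of PWMs.
#' @param sequences named DNAStringSet or character vector over ACGTN.
#' @param q_threshold per-motif BH FDR threshold (default 0.1).
#' @param background "sequences" (default) or "uniform" or a length-4
#'   probability vector.
#' @return data.frame motif_id, sequence_id, offset (0-based), strand,
#'   score, p, q.
#' @export
scan_pwms <- function(pwms, sequences, q_threshold = 0.1,
                      background = "sequences") {
  seqs <- if (is.character(sequences)) sequences else as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (identical(background, "sequences")) {
    tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                        levels = c("A", "C", "G", "T")))
    bg <- as.numeric(tab) / sum(tab)
  } else if (identical(background, "uniform")) {
    bg <- rep(0.25, 4)
  } else bg <- as.numeric(background)

  codes <- base_codes(seqs)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  codes_rc <- base_codes(rc)

  out <- list()
  for (m in seq_along(pwms)) {
    nd <- pssm_null(pwms[[m]], bg)
    L <- nrow(nd$grid)
    gN <- cbind(nd$grid, 0L)  # N scores 0
    hit_seq <- character(); hit_off <- integer(); hit_strand <- character()
    hit_score <- integer()
    for (si in seq_along(seqs)) {
      for (str in c("+", "-")) {
        cv <- if (str == "+") codes[[si]] else codes_rc[[si]]
        n <- length(cv)
        if (n < L) next
        npos <- n - L + 1L
        sc <- integer(npos)
        for (l in seq_len(L)) {
          sc <- sc + gN[l, cv[l:(l + npos - 1L)]]
        }
        hit_seq <- c(hit_seq, rep(names(seqs)[si], npos))
        off <- 0:(npos - 1L)
        if (str == "-") off <- (n - L) - off  # forward-strand offset of site
        hit_off <- c(hit_off, off)
        hit_strand <- c(hit_strand, rep(str, npos))
        hit_score <- c(hit_score, sc)
      }
    }
    if (!length(hit_score)) next
    p <- score_pvalue_grid(nd, hit_score)
    q <- bh_fdr(p)
    keep <- q < q_threshold
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      motif_id = pwms[[m]]$motif_id, sequence_id = hit_seq[keep],
      offset = hit_off[keep], strand = hit_strand[keep],
      score = hit_score[keep] / SCORE_GRID, p = p[keep], q = q[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(motif_id = character(), sequence_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p = numeric(), q = numeric()))
  }
  do.call(rbind, out)
}

#' TF motif-frequency matrix by expression cluster
#'
#' For each TF and cluster, the percentage of the cluster's genes whose
#' promoter carries at least one retained hit of any of the TF's motifs.
#' TFs that are not expressed (max FPKM < `fpkm_min`) or whose frequencies
#' are essentially constant across clusters (MAD of the frequency values
#' below `mad_min`, same scale as the values) are dropped. Rows are ordered
#' by hierarchical clustering.
#'
#' @param hits scan results (motif_id, sequence_id) where sequence ids are
#'   gene ids of promoters.
#' @param clusters named vector gene -> cluster.
#' @param motif_tf named vector motif_id -> TF name.
#' @param tf_fpkm named vector TF -> max FPKM (TFs absent are kept).
#' @param fpkm_min expression floor (default 1).
#' @param mad_min MAD floor on the frequency scale (default 0.05): only
#'   near-constant rows fall below it.
#' @return matrix TFs x clusters of percentages (0-100).
#' @export
cluster_motif_matrix <- function(hits, clusters, motif_tf, tf_fpkm = NULL,
                                 fpkm_min = 1, mad_min = 0.05) {
  cl <- clusters[!is.na(clusters)]
  ks <- sort(unique(cl))
  hits$tf <- unname(motif_tf[hits$motif_id])
  tfs <- sort(unique(hits$tf))
  m <- matrix(0, length(tfs), length(ks),
              dimnames = list(tfs, as.character(ks)))
  for (tf in tfs) {
    hg <- unique(hits$sequence_id[hits$tf == tf])
    for (k in seq_along(ks)) {
      genes_k <- names(cl)[cl == ks[k]]
      m[tf, k] <- 100 * mean(genes_k %in% hg)
    }
  }
  if (!is.null(tf_fpkm)) {
    expressed <- tfs[!(tfs %in% names(tf_fpkm)) | tf_fpkm[tfs] >= fpkm_min]
    m <- m[rownames(m) %in% expressed, , drop = FALSE]
  }
  mads <- apply(m, 1, mad)
  m <- m[mads >= mad_min, , drop = FALSE]
  if (nrow(m) > 2) m <- m[hclust(dist(m))$order, , drop = FALSE]
  m
}

#' Motif frequency in promoter vs enhancer peaks
#'
#' For each motif, the percentage of promoter-TSS peaks and of enhancer
#' peaks (intergenic, intron, exon, 3UTR, 5UTR) containing at least one
#' retained hit; per TF only the motif with the highest summed frequency is
#' reported. Output is restricted to DE TFs plus any named exceptions.
#'
#' @param hits scan results over peak sequences (sequence_id = peak_id).
#' @param peak_annotations annotated peaks (peak_id, category).
#' @param motif_tf named vector motif_id -> TF name.
#' @param de_tfs character vector of differentially expressed TF names.
#' @param include character vector of extra TFs to keep regardless.
#' @return data.frame tf, motif_id, freq_promoter, freq_enhancer (percent).
#' @export
promoter_enhancer_frequency <- function(hits, peak_annotations, motif_tf,
                                        de_tfs = NULL, include = character()) {
  prom <- peak_annotations$peak_id[peak_annotations$category == "promoter-TSS"]
  enh_cat <- c("intergenic", "intron", "exon", "3UTR", "5UTR")
  enh <- peak_annotations$peak_id[peak_annotations$category %in% enh_cat]
  motifs <- union(unique(hits$motif_id), names(motif_tf))  # no hits -> (0, 0)
  rows <- lapply(motifs, function(mid) {
    pk <- unique(hits$sequence_id[hits$motif_id == mid])
    data.frame(
      tf = unname(motif_tf[mid]), motif_id = mid,
      freq_promoter = if (length(prom)) 100 * mean(prom %in% pk) else 0,
      freq_enhancer = if (length(enh)) 100 * mean(enh %in% pk) else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(tf = character(), motif_id = character(),
                      freq_promoter = numeric(), freq_enhancer = numeric()))
  }
  ## most enriched motif per TF = max summed class frequency
  out <- out[order(out$tf, -(out$freq_promoter + out$freq_enhancer),
                   out$motif_id), ]
  out <- out[!duplicated(out$tf), , drop = FALSE]
  if (!is.null(de_tfs)) {
    out <- out[out$tf %in% c(de_tfs, include), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' TF-DEG expression correlation
#'
#' Pearson correlation of log2(FPKM+1) across all samples between each TF
#' and each DEG, with BH per TF across DEGs. The summary gives the percent
#' of DEGs significantly positively/negatively correlated per TF.
#'
#' @param fpkm_matrix FPKM matrix (genes x samples).
#' @param tfs character vector of TF gene ids (rows of fpkm_matrix).
#' @param degs character vector of DEG ids.
#' @param fdr significance threshold (default 0.05).
#' @return list with `records` (tf, gene_id, r, p, q, significant) and
#'   `summary` (tf, pct_positive, pct_negative).
#' @export
tf_deg_correlation <- function(fpkm_matrix, tfs, degs, fdr = 0.05) {
  le <- log2(fpkm_matrix + 1)
  rows <- list()
  for (tf in tfs) {
    a <- le[tf, ]
    rs <- ps <- numeric(length(degs))
    for (i in seq_along(degs)) {
      b <- le[degs[i], ]
      if (sd(a) == 0 || sd(b) == 0) { rs[i] <- NA; ps[i] <- NA; next }
      ct <- cor.test(a, b)
      rs[i] <- unname(ct$estimate); ps[i] <- ct$p.value
    }
    q <- bh_fdr(ps)
    rows[[tf]] <- data.frame(tf = tf, gene_id = degs, r = rs, p = ps, q = q,
                             significant = !is.na(q) & q < fdr,
                             stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  summ <- do.call(rbind, lapply(tfs, function(tf) {
    d <- rec[rec$tf == tf, ]
    data.frame(tf = tf,
               pct_positive = 100 * mean(d$significant & d$r > 0),
               pct_negative = 100 * mean(d$significant & d$r < 0),
               stringsAsFactors = FALSE)
  }))
  list(records = rec, summary = summ)
}
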