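## lncRNA-focused statistics: biotype composition of the top-ranked DEGs,
## lncRNA class enrichment, lncRNA-target co-expression, and fold-change
## concordance between lncRNAs and their annotated targets.

#' Rank a comparison's DEGs by absolute linear fold-change
#'
#' Ties in |FC| are broken by smaller q, then lexicographic gene id, so the
#' ordering is fully deterministic.
#'
#' @param de_table DEG-flagged results of one comparison (from [call_degs()]).
#' @return the DEG rows sorted by descending |log2fc|.
#' @export
rank_degs <- function(de_table) {
  d <- de_table[de_table$is_deg, , drop = FALSE]
  d[order(-abs(d$log2fc), d$q, d$gene_id), , drop = FALSE]
}

#' Biotype composition test of the top-N DEGs
#'
#' Among the top N DEGs by absolute linear fold-change, counts lncRNAs and
#' coding genes and tests each for over-representation by the exact
#' hypergeometric upper tail. The population is all DEGs of the comparison
#' (M), marked items are the DE lncRNAs (resp. coding), the draw is the top
#' N.
#'
#' @param de_table one comparison's results with is_deg and biotype columns.
#' @param N top-list size (paper uses 10, 20, 30, 40, 50).
#' @return one-row data.frame: comparison, N, n_lnc, n_coding, p_lnc,
#'   p_coding, lnc_more_significant.
#' @export
topn_biotype_test <- function(de_table, N) {
  d <- rank_degs(de_table)
  M <- nrow(d)
  stopifnot(N >= 1, M >= 1)
  N <- min(N, M)
  lnc <- is_lncrna(d$biotype)
  top <- seq_len(N)
  x_l <- sum(lnc[top]); x_c <- sum(!lnc[top])
  K_l <- sum(lnc); K_c <- sum(!lnc)
  p_l <- hypergeom_tail(x_l, K_l, N, M)
  p_c <- hypergeom_tail(x_c, K_c, N, M)
  data.frame(comparison = d$comparison[1], N = N,
             n_lnc = x_l, n_coding = x_c,
             p_lnc = p_l, p_coding = p_c,
             lnc_more_significant = p_l < p_c,
             stringsAsFactors = FALSE)
}

#' Per-class enrichment of DE lncRNAs
#'
#' For each lncRNA class, tests whether DE lncRNAs over-represent that class
#' relative to the annotated lncRNA population: M = annotated lncRNAs, K =
#' annotated in the class, n = DE lncRNAs, x = DE in the class.
#'
#' @param de_lncrnas character vector of DE lncRNA gene ids.
#' @param annotation gene-model data.frame (for biotypes).
#' @return data.frame class, x, K, n, M, p (classes absent from the
#'   annotation are skipped with a message).
#' @export
lnc_class_enrichment <- function(de_lncrnas, annotation) {
  ann_lnc <- annotation[is_lncrna(annotation$biotype), , drop = FALSE]
  M <- nrow(ann_lnc)
  de <- intersect(de_lncrnas, ann_lnc$gene_id)
  n <- length(de)
  out <- lapply(LNC_BIOTYPES, function(cl) {
    K <- sum(ann_lnc$biotype == cl)
    if (K == 0L) {
      message("lncRNA class absent from annotation, skipped: ", cl)
      return(NULL)
    }
    x <- sum(ann_lnc$biotype[match(de, ann_lnc$gene_id)] == cl)
    data.frame(class = cl, x = x, K = K, n = n, M = M,
               p = if (n == 0L) 1 else hypergeom_tail(x, K, n, M),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' lncRNA-target expression correlation
#'
#' Pearson correlation of log2(FPKM+1) across every sample of all time
#' points, one test per (lncRNA, target) pair. Pairs with a constant series
#' are flagged and get NA correlation.
#'
#' @param fpkm_matrix FPKM matrix (genes x all samples).
#' @param pairs data.frame with columns lncrna_id, target_id.
#' @param alpha per-pair significance level on the correlation p (default
#'   0.05).
#' @return data.frame lncrna_id, target_id, r, p, direction, significant,
#'   constant; the summary of [summarize_pair_correlations()] is attached as
#'   attribute "summary".
#' @export
lnc_target_correlation <- function(fpkm_matrix, pairs, alpha = 0.05) {
  le <- log2(fpkm_matrix + 1)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- le[pairs$lncrna_id[i], ]; b <- le[pairs$target_id[i], ]
    if (sd(a) == 0 || sd(b) == 0) {
      return(data.frame(lncrna_id = pairs$lncrna_id[i],
                        target_id = pairs$target_id[i],
                        r = NA_real_, p = NA_real_,
                        direction = NA_character_, significant = FALSE,
                        constant = TRUE, stringsAsFactors = FALSE))
    }
    ct <- cor.test(a, b, method = "pearson")
    data.frame(lncrna_id = pairs$lncrna_id[i], target_id = pairs$target_id[i],
               r = unname(ct$estimate), p = ct$p.value,
               direction = if (ct$estimate >= 0) "positive" else "negative",
               significant = ct$p.value < alpha, constant = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_pair_correlations(out)
  out
}

#' Summarize a pair-correlation table
#'
#' Reports how many pairs were tested, how many are significant, the share
#' of tested pairs that are significant, and the share of significant pairs
#' with positive correlation — the quantities the study prints as "56% (54
#' out of 96)" and "91% (49 out of 54)"-style statements.
#'
#' @param pair_table data.frame with `significant` and `direction` columns.
#' @return list with n_pairs, n_significant, n_positive, pct_significant,
#'   pct_positive (integer-rounded percentages) and printable labels.
#' @export
summarize_pair_correlations <- function(pair_table) {
  n <- nrow(pair_table)
  sig <- pair_table$significant %in% TRUE
  ns <- sum(sig)
  np <- sum(sig & pair_table$direction %in% "positive")
  list(
    n_pairs = n, n_significant = ns, n_positive = np,
    pct_significant = if (n > 0) fraction_report(ns, n)$percent else NA_real_,
    pct_positive = if (ns > 0) fraction_report(np, ns)$percent else NA_real_,
    label_significant = if (n > 0) fraction_report(ns, n)$label else NA_character_,
    label_positive = if (ns > 0) fraction_report(np, ns)$label else NA_character_
  )
}

#' Fold-change concordance of lncRNA-target pairs
#'
#' Classifies each pair per comparison as both_up, both_down or discordant
#' by the signs of the two members' log2 fold-changes, and flags pairs where
#' both members pass the DEG rule.
#'
#' @param pairs data.frame with lncrna_id, target_id.
#' @param de_tables named list comparison -> DEG-flagged results.
#' @return data.frame lncrna_id, target_id, comparison, class, both_de.
#' @export
fc_concordance <- function(pairs, de_tables) {
  out <- lapply(names(de_tables), function(cmp) {
    d <- de_tables[[cmp]]
    rownames(d) <- d$gene_id
    l <- d[pairs$lncrna_id, ]; t <- d[pairs$target_id, ]
    cls <- ifelse(sign(l$log2fc) != sign(t$log2fc), "discordant",
                  ifelse(l$log2fc > 0, "both_up", "both_down"))
    data.frame(lncrna_id = pairs$lncrna_id, target_id = pairs$target_id,
               comparison = cmp, class = cls,
               both_de = l$is_deg & t$is_deg, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
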