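## Stage 4 — lncRNA composition and co-expression. For each comparison:
## biotype counts among the top 10/20/30/40/50 DEGs ranked by |linear FC|
## with exact hypergeometric tests; enrichment of lncRNA classes among DE
## lncRNAs; Pearson correlation between DE lncRNAs and their annotated
## target genes over all samples; and fold-change concordance per pair.

source("analysis/00_common.R")

genes <- read_gene_models(file.path(SIM_DIR, "annotation.gtf"))
fp_tab <- utils::read.delim(file.path(RESULTS, "fpkm.tsv"), check.names = FALSE)
fp <- as.matrix(fp_tab[, -1]); rownames(fp) <- fp_tab$gene_id

labs <- c("D0vsD14", "D14vsD28", "D0vsD28")
de_tables <- lapply(labs, function(l)
  utils::read.delim(file.path(RESULTS, paste0("de_", l, ".tsv"))))
names(de_tables) <- labs

topn <- do.call(rbind, lapply(de_tables, function(d)
  do.call(rbind, lapply(c(10, 20, 30, 40, 50), function(N)
    topn_biotype_test(d, N)))))
write_tsv(topn, "topn_biotype_tests.tsv")
for (l in labs) {
  t10 <- topn[topn$comparison == l & topn$N == 10, ]
  message(sprintf("%s top 10: %d lncRNA (p=%.3g), %d coding (p=%.3g)%s",
                  l, t10$n_lnc, t10$p_lnc, t10$n_coding, t10$p_coding,
                  if (t10$lnc_more_significant) " *lncRNA more significant*" else ""))
}

de_lnc <- unique(unlist(lapply(de_tables, function(d)
  d$gene_id[d$is_deg & d$is_lncrna])))
cls <- lnc_class_enrichment(de_lnc, genes)
write_tsv(cls, "lnc_class_enrichment.tsv")

## pairs from the annotation's lncRNA -> target links, lncRNA DE
pairs <- data.frame(lncrna_id = genes$gene_id, target_id = genes$target_gene_id)
pairs <- pairs[!is.na(pairs$target_id) & pairs$lncrna_id %in% de_lnc, ]
if (nrow(pairs)) {
  pc <- lnc_target_correlation(fp, pairs, alpha = 0.05)
  write_tsv(pc, "lnc_target_correlation.tsv")
  s <- attr(pc, "summary")
  message(sprintf("significant pairs: %s; positive among significant: %s",
                  s$label_significant, s$label_positive))
  conc <- fc_concordance(pairs, de_tables)
  write_tsv(conc, "lnc_target_concordance.tsv")
} else {
  message("no DE lncRNA with an annotated target in this simulation")
}
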