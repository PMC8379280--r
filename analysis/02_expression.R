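## Stage 2 — differential expression. Median-of-ratios normalization, FPKM,
## a negative-binomial Wald test per pairwise time-point comparison, and the
## study's DEG rule: FPKM >= 1 in at least one replicate of the comparison,
## linear fold-change > 4, BH FDR < 0.05. The union over the three
## comparisons is the compiled DEG list used by every later stage.

source("analysis/00_common.R")

genes <- read_gene_models(file.path(SIM_DIR, "annotation.gtf"))
cm <- read_counts(file.path(SIM_DIR, "counts.tsv"),
                  file.path(SIM_DIR, "samples.tsv"))

sf <- size_factors(cm$counts)
fp <- fpkm(cm$counts, genes[rownames(cm$counts), "length_bp"])
write_tsv(data.frame(gene_id = rownames(fp), round(fp, 4)), "fpkm.tsv")

tp <- cm$meta$time_point
biotypes <- setNames(genes$biotype, genes$gene_id)
comparisons <- list(c("D0", "D14"), c("D14", "D28"), c("D0", "D28"))
de_tables <- list()
for (cmp in comparisons) {
  lab <- paste0(cmp[1], "vs", cmp[2])
  sel <- tp %in% cmp
  res <- nb_test(cm$counts[, sel], factor(tp[sel], levels = cmp),
                 sf = sf[sel], comparison = lab)
  res <- call_degs(res, fp,
                   sample_groups = setNames(list(colnames(cm$counts)[sel]), lab),
                   fc = THRESH$deg_fc, fdr = THRESH$deg_fdr,
                   fpkm_min = THRESH$fpkm_min, biotypes = biotypes)
  de_tables[[lab]] <- res
  n_lnc <- sum(res$is_deg & res$is_lncrna)
  message(sprintf("%s: %d DEGs (%d coding, %d lncRNA)", lab,
                  sum(res$is_deg), sum(res$is_deg) - n_lnc, n_lnc))
  write_tsv(res, paste0("de_", lab, ".tsv"))
}

degs <- sort(unique(unlist(lapply(de_tables, attr, "deg_ids"))))
deg_tab <- data.frame(gene_id = degs, biotype = biotypes[degs],
                      is_lncrna = is_lncrna(biotypes[degs]))
write_tsv(deg_tab, "compiled_degs.tsv")
message(sprintf("compiled DEG list: %d genes (%d coding, %d lncRNA)",
                nrow(deg_tab), sum(!deg_tab$is_lncrna),
                sum(deg_tab$is_lncrna)))
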