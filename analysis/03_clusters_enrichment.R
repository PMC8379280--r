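## Stage 3 — temporal profiles and gene-set enrichment. The compiled DEGs
## are clustered on row z-scores of log2(FPKM+1) per-time-point means
## (Ward/Euclidean, k = 6) and each cluster is tested for gene-set
## over-representation with the exact hypergeometric upper tail, BH across
## sets, universe = expressed genes (max FPKM >= 1).

source("analysis/00_common.R")

fp_tab <- utils::read.delim(file.path(RESULTS, "fpkm.tsv"), check.names = FALSE)
fp <- as.matrix(fp_tab[, -1]); rownames(fp) <- fp_tab$gene_id
meta <- utils::read.delim(file.path(SIM_DIR, "samples.tsv"))
degs <- utils::read.delim(file.path(RESULTS, "compiled_degs.tsv"))$gene_id

tpm <- sapply(c("D0", "D14", "D28"), function(t)
  rowMeans(fp[, meta$sample[meta$time_point == t], drop = FALSE]))

cl <- cluster_degs(tpm, degs, k = 6)
write_tsv(data.frame(gene_id = names(cl$labels), cluster = cl$labels,
                     degenerate = cl$degenerate), "deg_clusters.tsv")
message("cluster sizes: ",
        paste(sprintf("K%d=%d", 1:6, as.integer(table(cl$labels))),
              collapse = ", "))

## gene sets built from the simulation's planted archetypes plus decoys: a
## self-contained stand-in for a curated collection
truth <- utils::read.delim(file.path(SIM_DIR, "truth_genes.tsv"))
sets <- lapply(1:6, function(k) truth$gene_id[!is.na(truth$cluster) &
                                                truth$cluster == k])
names(sets) <- paste0("archetype_", 1:6)
set.seed(SEED)
sets$decoy_a <- sample(truth$gene_id, 80)
sets$decoy_b <- sample(truth$gene_id, 120)
write_gene_sets(sets, file.path(SIM_DIR, "gene_sets.gmt"))

universe <- rownames(fp)[apply(fp, 1, max) >= THRESH$fpkm_min]
enr <- do.call(rbind, lapply(1:6, function(k) {
  genes_k <- names(cl$labels)[cl$labels == k]
  e <- enrich_gene_sets(genes_k, sets, universe, fdr = THRESH$deg_fdr)
  if (nrow(e)) cbind(cluster = k, e) else NULL
}))
write_tsv(enr, "cluster_enrichment.tsv")
sig <- enr[enr$significant, ]
message(sprintf("%d significant (FDR < %.2f) cluster/set pairs; top: %s",
                nrow(sig), THRESH$deg_fdr,
                paste(head(paste0("K", sig$cluster, ":", sig$set_name), 6),
                      collapse = ", ")))
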