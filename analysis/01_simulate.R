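## Stage 1 — generate every pipeline input with the study's statistical
## structure: a gene annotation over four synthetic chromosomes, promoter
## sequences with planted motif sites, RNA counts for 3/4/3 replicates at
## D0/D14/D28 following six temporal archetypes, per-time-point ATAC peak
## sets with a planted promoter-accessibility/expression coupling, fragment
## records with the nucleosome size mixture, and an enhancer database plus
## SNP table. Everything is written in the exact formats the readers parse,
## along with machine-readable truth tables.

source("analysis/00_common.R")

message("simulating with seed ", SEED)
ann <- gen_annotation(CFG)
ct <- gen_counts(CFG, ann$genes)
pk <- gen_peaks(CFG, ann$genes, ct$truth)
fr <- gen_fragments(CFG, pk)
es <- gen_enhancer_db_and_snps(CFG, pk)

pwms <- pwm_collection()
clusters <- setNames(ann$genes$cluster, ann$genes$gene_id)
## cluster-structured planting: each TF prefers one archetype, CTCF is flat
rates <- matrix(0.05, 6, length(pwms), dimnames = list(1:6, names(pwms)))
rates["3", "M_TF_NANOG"] <- 0.8
rates["1", "M_TF_ESRRA"] <- 0.8
rates["6", "M_TF_EBF1"] <- 0.8
rates[, "M_TF_CTCF"] <- 0.3
plant <- gen_motif_plant(CFG, pwms, ann$promoters, clusters, rates = rates)

write_gene_models(ann$genes, file.path(SIM_DIR, "annotation.gtf"))
Biostrings::writeXStringSet(plant$promoters,
                            file.path(SIM_DIR, "promoters.fa"))
write_counts(ct$cm, file.path(SIM_DIR, "counts.tsv"),
             file.path(SIM_DIR, "samples.tsv"))
for (tp in names(pk$peak_sets)) {
  write_intervals(pk$peak_sets[[tp]],
                  file.path(SIM_DIR, paste0("peaks_", tp, ".bed")))
}
utils::write.table(data.frame(peak_id = rownames(pk$counts), pk$counts),
                   file.path(SIM_DIR, "peak_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_intervals(data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                           name = fr$sample, score = 0L, strand = fr$strand),
                file.path(SIM_DIR, "fragments.bed"))
write_intervals(es$enhancers, file.path(SIM_DIR, "enhancers.bed"))
utils::write.table(es$snps, file.path(SIM_DIR, "snps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_pwms(pwms, file.path(SIM_DIR, "motifs.meme"))

write_tsv(ct$truth, "truth_genes.tsv", SIM_DIR)
write_tsv(pk$peaks[, c("peak_id", "chrom", "start", "end", "class",
                       "gene_id", "acc_lfc", "coupled")],
          "truth_peaks.tsv", SIM_DIR)
write_tsv(plant$truth, "truth_motifs.tsv", SIM_DIR)

message(sprintf("genes: %d (%d archetype, %d null); peaks: %d (%d coupled)",
                nrow(ann$genes), sum(!ann$genes$is_null),
                sum(ann$genes$is_null), nrow(pk$peaks),
                sum(pk$peaks$coupled)))
message(sprintf("fragments: %d across %d samples", nrow(fr),
                length(unique(fr$sample))))
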