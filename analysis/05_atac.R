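## Stage 5 — chromatin accessibility. Tn5 cut-site offsetting, the
## fragment-size histogram with nucleosome-mode detection, consensus peak
## construction (gap <= 100 bp), Venn categories across time points,
## midpoint annotation against the gene models, differential accessibility
## (|log2FC| > 1.5 and raw p < 0.05), enhancer-database overlap fractions,
## SNP-overlap hypergeometrics, and a locus-level Mann-Whitney example.

source("analysis/00_common.R")

genes <- read_gene_models(file.path(SIM_DIR, "annotation.gtf"))
frags <- utils::read.delim(file.path(SIM_DIR, "fragments.bed"), header = FALSE,
                           col.names = c("chrom", "start", "end", "sample",
                                         "score", "strand"))
frags <- tn5_shift(frags)

h <- size_histogram(frags[frags$sample == "D0", ])
nuc <- h$modes[h$modes >= 150]
message("fragment-size modes (bp): ", paste(round(h$modes), collapse = ", "),
        " -> nucleosome modes ", paste(round(nuc / 10) * 10, collapse = "/"))

peak_sets <- lapply(c(D0 = "D0", D14 = "D14", D28 = "D28"), function(tp)
  read_intervals(file.path(SIM_DIR, paste0("peaks_", tp, ".bed"))))
cons <- merge_consensus(peak_sets, gap = THRESH$merge_gap)
venn <- venn_categories(cons)
write_tsv(venn, "consensus_venn.tsv")
message(sprintf("consensus peaks: %d; shared by all three time points: %s",
                attr(venn, "total"),
                fraction_report(venn$count[venn$subset == "D0,D14,D28"],
                                attr(venn, "total"))$label))

cons <- annotate_peaks(cons, genes, promoter_up = THRESH$promoter_up,
                       promoter_down = THRESH$promoter_down)
write_tsv(cons[, setdiff(names(cons), c("D0", "D14", "D28"))],
          "consensus_annotated.tsv")
message("annotation categories: ",
        paste(names(table(cons$category)), table(cons$category),
              collapse = ", ", sep = "="))

## differential accessibility on the generator's per-peak counts
pc_tab <- utils::read.delim(file.path(SIM_DIR, "peak_counts.tsv"))
pcounts <- as.matrix(pc_tab[, -1]); rownames(pcounts) <- pc_tab$peak_id
for (cmp in list(c("D0", "D14"), c("D14", "D28"), c("D0", "D28"))) {
  lab <- paste0(cmp[1], "vs", cmp[2])
  da <- diff_accessibility(pcounts[, paste0("A_", cmp)], cmp,
                           lfc = THRESH$atac_abs_log2fc,
                           alpha = THRESH$atac_p, comparison = lab)
  write_tsv(da, paste0("da_", lab, ".tsv"))
  message(sprintf("%s: %d differentially accessible peaks of %d", lab,
                  sum(da$significant), nrow(da)))
}

## enhancer-database overlap of time-point-specific peaks
enh <- read_intervals(file.path(SIM_DIR, "enhancers.bed"))
truthp <- utils::read.delim(file.path(SIM_DIR, "truth_peaks.tsv"))
for (tp in c("D0", "D14", "D28")) {
  spec <- truthp[truthp$class == tp, c("chrom", "start", "end")]
  message(sprintf("%s-specific peaks overlapping the enhancer DB: %s", tp,
                  overlap_fraction(spec, enh)$label))
}

## SNP overlap per presence class x annotation category
snps <- utils::read.delim(file.path(SIM_DIR, "snps.tsv"))
acons <- cons
by_class <- split(acons[, c("chrom", "start", "end")],
                  paste(acons$present_in, acons$category, sep = "/"))
by_class <- by_class[vapply(by_class, nrow, 1L) >= 20]
snp_res <- snp_overlap_test(by_class, snps, cons[, c("chrom", "start", "end")])
snp_res <- snp_res[order(snp_res$p), ]
write_tsv(snp_res, "snp_overlap_tests.tsv")
message("most SNP-enriched class: ", snp_res$class[1],
        sprintf(" (p = %.3g, q = %.3g)", snp_res$p[1], snp_res$q[1]))

## locus-level Mann-Whitney on a gene locus with several OCRs
locus_gene <- genes[which.max(genes$end - genes$start), ]
win <- data.frame(chrom = locus_gene$chrom,
                  start = locus_gene$start - 20000L,
                  end = locus_gene$end + 20000L)
in_locus <- GenomicRanges::countOverlaps(as_granges(cons), as_granges(win)) > 0
ocrs <- cons[in_locus, ]
if (nrow(ocrs) >= 3) {
  cnt <- function(sample_tp) {
    fr <- frags[frags$sample == sample_tp, ]
    mids <- (fr$start + fr$end) %/% 2L
    mgr <- GenomicRanges::GRanges(fr$chrom,
                                  IRanges::IRanges(mids + 1L, mids + 1L))
    GenomicRanges::countOverlaps(as_granges(ocrs), mgr)
  }
  mw <- locus_mw_test(cnt("D0"), cnt("D28"),
                      total_a = sum(frags$sample == "D0"),
                      total_b = sum(frags$sample == "D28"))
  message(sprintf("locus %s (%d OCRs): Mann-Whitney D0 vs D28 p = %.3g (%s)",
                  locus_gene$gene_id, mw$n_ocr, mw$p, mw$method))
} else {
  message("largest gene locus has fewer than 3 OCRs; Mann-Whitney skipped")
}
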