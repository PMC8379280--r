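## Stage 7 — TF binding motifs. Promoters of clustered DEGs are scanned
## with the PWM collection (exact score p-values, BH per motif, q < 0.1);
## the per-cluster motif-frequency matrix is built with the expression and
## MAD filters; promoter vs enhancer peak frequencies are compared on
## synthetic peak sequences; and the top TF is correlated with all DEGs.

source("analysis/00_common.R")

pwms <- read_pwms(file.path(SIM_DIR, "motifs.meme"))
proms <- Biostrings::readDNAStringSet(file.path(SIM_DIR, "promoters.fa"))
cl_tab <- utils::read.delim(file.path(RESULTS, "deg_clusters.tsv"))
clusters <- setNames(cl_tab$cluster, cl_tab$gene_id)
fp_tab <- utils::read.delim(file.path(RESULTS, "fpkm.tsv"), check.names = FALSE)
fp <- as.matrix(fp_tab[, -1]); rownames(fp) <- fp_tab$gene_id

## scan only clustered DEG promoters, trimmed to TSS +/- scan_halfwin
half <- (Biostrings::width(proms)[1] - 1) %/% 2
lo <- half - THRESH$scan_halfwin + 1
scan_seqs <- Biostrings::subseq(proms[names(proms) %in% names(clusters)],
                                lo, lo + 2 * THRESH$scan_halfwin)
hits <- scan_pwms(pwms, scan_seqs, q_threshold = THRESH$motif_q)
write_tsv(hits, "promoter_motif_hits.tsv")
message(sprintf("%d retained promoter hits (q < %.1f) across %d motifs",
                nrow(hits), THRESH$motif_q, length(unique(hits$motif_id))))

## recovery against the planted truth
truth_m <- utils::read.delim(file.path(SIM_DIR, "truth_motifs.tsv"))
truth_m <- truth_m[truth_m$gene_id %in% names(clusters), ]
found <- paste(hits$sequence_id, hits$motif_id)
planted <- paste(truth_m$gene_id, truth_m$motif_id)
message(sprintf("planted sites recovered: %s",
                fraction_report(sum(unique(planted) %in% found),
                                length(unique(planted)))$label))

motif_tf <- setNames(vapply(pwms, `[[`, "", "tf_name"), names(pwms))
tf_fpkm <- setNames(rep(5, length(pwms)), motif_tf)  # synthetic TFs expressed
mm <- cluster_motif_matrix(hits, clusters, motif_tf, tf_fpkm = tf_fpkm,
                           fpkm_min = THRESH$fpkm_min)
write_tsv(data.frame(tf = rownames(mm), mm, check.names = FALSE),
          "cluster_motif_matrix.tsv")
message("cluster motif matrix: ", nrow(mm), " TFs x ", ncol(mm), " clusters")

## promoter vs enhancer frequency on synthetic peak sequences: random
## sequences per annotated peak with the first motif planted in
## promoter-class peaks (synthetic stand-in for peak genome sequence)
cons <- utils::read.delim(file.path(RESULTS, "consensus_annotated.tsv"))
set.seed(SEED + 7L)
sub <- cons[sample.int(nrow(cons), min(400, nrow(cons))), ]
peak_seqs <- vapply(seq_len(nrow(sub)), function(i)
  paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""), "")
names(peak_seqs) <- sub$peak_id
promoter_class <- sub$category == "promoter-TSS"
site <- "ACGTACGTAC"
for (i in which(promoter_class)) {
  substr(peak_seqs[[i]], 101, 100 + nchar(site)) <- site
}
phits <- scan_pwms(pwms, peak_seqs, q_threshold = THRESH$motif_q)
pe <- promoter_enhancer_frequency(phits, sub, motif_tf,
                                  de_tfs = unname(motif_tf),
                                  include = "TF_CTCF")
write_tsv(pe, "promoter_enhancer_frequency.tsv")
print(pe)

## TF-DEG expression correlation for the most promoter-enriched TF, using a
## cluster-6 gene as that TF's expression proxy in the synthetic annotation
degs <- utils::read.delim(file.path(RESULTS, "compiled_degs.tsv"))$gene_id
tf_proxy <- names(clusters)[clusters == 6][1]
tc <- tf_deg_correlation(fp, tfs = tf_proxy, degs = setdiff(degs, tf_proxy),
                         fdr = THRESH$corr_fdr)
write_tsv(tc$records, "tf_deg_correlation.tsv")
message(sprintf("TF proxy %s: %.0f%% of DEGs positively, %.0f%% negatively correlated (FDR < %.2f)",
                tf_proxy, tc$summary$pct_positive, tc$summary$pct_negative,
                THRESH$corr_fdr))
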