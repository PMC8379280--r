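## Shared setup for the numbered analysis drivers. Each driver can be run as
##   Rscript analysis/NN_*.R [--seed N]
## from the repository root; outputs accumulate under results/.

suppressMessages(library(ocrtime))

.args <- commandArgs(trailingOnly = TRUE)
.seed_i <- which(.args == "--seed")
SEED <- if (length(.seed_i) && .seed_i < length(.args)) {
  as.integer(.args[.seed_i + 1])
} else 1L

RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "sim")
dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)

## analysis thresholds, as used throughout the study
THRESH <- list(
  deg_fc = 4, deg_fdr = 0.05, fpkm_min = 1,
  atac_abs_log2fc = 1.5, atac_p = 0.05,
  motif_q = 0.1, corr_fdr = 0.05,
  merge_gap = 100, promoter_up = 1000, promoter_down = 100,
  scan_halfwin = 1000
)

CFG <- sim_config(seed = SEED)

write_tsv <- function(x, name, dir = RESULTS) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}

## small PWM collection used across the motif stages: near-consensus motifs
## for a handful of synthetic TFs (one CTCF-like deliberately included)
pwm_collection <- function() {
  words <- c(TF_NANOG = "ACGTACGTAC", TF_ESRRA = "TGACCTTGAC",
             TF_EBF1 = "TCCCTGGGAA", TF_CTCF = "CCGCGAGGTGGCAG")
  pwms <- lapply(seq_along(words), function(i) {
    w <- words[i]
    L <- nchar(w)
    base <- c(A = 1, C = 2, G = 3, T = 4)
    p <- matrix(0.02, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    for (k in seq_len(L)) p[k, base[[substr(w, k, k)]]] <- 0.94
    list(motif_id = paste0("M_", names(words)[i]),
         tf_name = names(words)[i],
         probs = p / rowSums(p), background = rep(0.25, 4))
  })
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  pwms
}
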