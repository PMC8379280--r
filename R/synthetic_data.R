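## Deterministic synthetic-data generator emulating the statistical
## structure of a three-time-point (D0/D14/D28) dopaminergic-differentiation
## study: 3/4/3 RNA replicates, six temporal expression archetypes over
## coding and lncRNA biotypes, negative-binomial counts, an ATAC
## fragment-size mixture (sub-100 bp open-chromatin mass plus nucleosome
## modes at 200/440/600 bp), time-point-specific vs shared peaks, a planted
## correlation between promoter-accessibility and expression fold-changes,
## and promoters with planted motif occurrences. Every generator derives all
## randomness from the config seed and emits a truth table.

#' Simulation configuration
#'
#' Defaults encode the study conditions: three time points with 3, 4 and 3
#' RNA replicates, six temporal archetypes with 8-fold swings, a coupling of
#' 0.45 between promoter-accessibility and expression log2 fold-changes, and
#' a fragment-size mixture with 55% sub-100 bp open-chromatin mass and
#' Gaussian nucleosome modes at 200/440/600 bp (sd 25/40/50).
#'
#' @param seed integer master seed; all generator randomness flows from it.
#' @param n_genes number of genes (>= 100).
#' @param biotype_fractions named fractions over the 7 biotypes (sum to 1).
#' @param replicates named per-time-point RNA replicate counts.
#' @param de_fraction fraction of genes assigned a temporal archetype; the
#'   rest are flat null genes.
#' @param archetype_fc linear fold-change magnitude of archetype swings.
#' @param base_mean_log mean of log-normal baseline expression (log scale).
#' @param base_mean_sd sd of log-normal baseline expression (log scale).
#' @param nb_dispersion_mean,nb_dispersion_sdlog per-gene NB dispersion
#'   log-normal parameters.
#' @param coupling_rho planted correlation between promoter-accessibility
#'   and expression log2FC (D0 vs D28), in [0, 1].
#' @param n_peaks number of ATAC peaks.
#' @param peak_class_props named proportions of consensus-peak presence
#'   classes (must sum to 1).
#' @param peak_open_mean,peak_closed_mean NB mean of open/closed peak counts.
#' @param atac_dispersion NB dispersion of peak counts (technical noise
#'   only; the design has one ATAC sample per time point).
#' @param d0_access_boost factor by which the in-peak fragment fraction is
#'   raised at D0 (global accessibility is highest in pluripotent cells);
#'   realised in [gen_fragments()] as a reduced D0 background rate.
#' @param n_fragments fragments per ATAC sample.
#' @param fragment_mix list with weights w (sub100, mono, di, tri), Gaussian
#'   centers mu and sds sd for the nucleosome modes, and min/scale of the
#'   truncated-exponential sub-100 component.
#' @param background_rate fraction of fragments placed uniformly outside
#'   peaks.
#' @param promoter_len promoter sequence length (odd; centered on the TSS).
#' @param motif_plant_rate default per-(cluster, motif) planting probability.
#' @param enhancer_fraction fraction of D0-specific peaks covered by the
#'   synthetic enhancer database.
#' @param n_snps number of SNPs.
#' @param snp_odds odds of placing a SNP in a D28-specific distal peak
#'   relative to any other peak (1 = uniform null).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       biotype_fractions = c(protein_coding = 0.80,
                                             lincRNA = 0.07, antisense = 0.06,
                                             processed_transcript = 0.03,
                                             sense_intronic = 0.02,
                                             sense_overlapping = 0.01,
                                             TEC = 0.01),
                       replicates = c(D0 = 3L, D14 = 4L, D28 = 3L),
                       de_fraction = 0.3,
                       archetype_fc = 8,
                       base_mean_log = log(200), base_mean_sd = 1,
                       nb_dispersion_mean = 0.05, nb_dispersion_sdlog = 0.4,
                       coupling_rho = 0.45,
                       n_peaks = 10000L,
                       peak_class_props = c(D0 = 0.22, D14 = 0.32, D28 = 0.19,
                                            `D0,D14` = 0.16 / 3,
                                            `D0,D28` = 0.16 / 3,
                                            `D14,D28` = 0.16 / 3,
                                            `D0,D14,D28` = 0.11),
                       peak_open_mean = 500, peak_closed_mean = 5,
                       atac_dispersion = 0.005,
                       d0_access_boost = 1.5,
                       n_fragments = 200000L,
                       fragment_mix = list(
                         w = c(sub100 = 0.55, mono = 0.25, di = 0.12,
                               tri = 0.08),
                         mu = c(200, 440, 600), sd = c(25, 40, 50),
                         min = 38, scale = 30),
                       background_rate = 0.1,
                       promoter_len = 2001L,
                       motif_plant_rate = 0.5,
                       enhancer_fraction = 0.6,
                       n_snps = 500L,
                       snp_odds = 10) {
  stopifnot(n_genes >= 100L, length(replicates) == 3L,
            coupling_rho >= 0, coupling_rho <= 1,
            promoter_len %% 2L == 1L)
  if (abs(sum(biotype_fractions) - 1) > 1e-8) {
    stop("biotype fractions must sum to 1")
  }
  if (abs(sum(peak_class_props) - 1) > 1e-8) {
    stop("peak class proportions must sum to 1")
  }
  if (abs(sum(fragment_mix$w) - 1) > 1e-8) {
    stop("fragment mixture weights must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

## Deterministic integer allocation by largest remainder, so configured
## proportions are recovered exactly from the labels.
allocate_counts <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    add <- order(-frac)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a synthetic gene annotation and promoter sequences
#'
#' Genes are tiled over four synthetic chromosomes with at least 10 kb
#' between neighbours. Biotypes follow the configured fractions exactly
#' (largest-remainder allocation). Every antisense or sense_intronic lncRNA
#' is assigned the nearest coding gene on its chromosome as its regulatory
#' target. Genes selected as differentially expressed (de_fraction) receive
#' one of six temporal archetype clusters; the rest are flat nulls. Coding
#' genes carry 150 bp UTR intervals at each transcript end. Promoters are
#' `promoter_len` random bases centered on the TSS.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (gene-model data.frame including cluster and
#'   is_null columns) and `promoters` (named DNAStringSet).
#' @export
gen_annotation <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  counts <- allocate_counts(n, cfg$biotype_fractions)
  biotype <- sample(rep(names(counts), counts))
  chrom <- paste0("chrS", rep_len(1:4, n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- as.integer(round(runif(n, 2000, 20000)))
  gap <- as.integer(10000 + round(rexp(n, 1 / 5000)))
  start <- integer(n)
  pos <- stats::setNames(rep(1e6L, 4), paste0("chrS", 1:4))
  for (i in seq_len(n)) {
    start[i] <- pos[chrom[i]]
    pos[chrom[i]] <- pos[chrom[i]] + len[i] + gap[i]
  }
  end <- start + len
  tss <- ifelse(strand == "+", start, end)
  gene_id <- sprintf("G%04d", seq_len(n))

  exons <- vector("list", n)
  utr5 <- vector("list", n)
  utr3 <- vector("list", n)
  length_bp <- integer(n)
  for (i in seq_len(n)) {
    k <- sample(2:5, 1)
    cuts <- sort(sample(seq(start[i] + 200L, end[i] - 200L, by = 50L),
                        2L * (k - 1L)))
    s <- c(start[i], cuts[seq(2, length(cuts), by = 2)])
    e <- c(cuts[seq(1, length(cuts), by = 2)], end[i])
    exons[[i]] <- cbind(start = as.integer(s), end = as.integer(e))
    length_bp[i] <- sum(e - s)
    if (biotype[i] == "protein_coding") {
      if (strand[i] == "+") {
        utr5[[i]] <- cbind(start = s[1], end = min(s[1] + 150L, e[1]))
        utr3[[i]] <- cbind(start = max(e[k] - 150L, s[k]), end = e[k])
      } else {
        utr5[[i]] <- cbind(start = max(e[k] - 150L, s[k]), end = e[k])
        utr3[[i]] <- cbind(start = s[1], end = min(s[1] + 150L, e[1]))
      }
    }
  }

  ## lncRNA regulatory targets: nearest coding gene on the same chromosome
  target <- rep(NA_character_, n)
  coding_idx <- which(biotype == "protein_coding")
  for (i in which(biotype %in% c("antisense", "sense_intronic"))) {
    cand <- coding_idx[chrom[coding_idx] == chrom[i]]
    if (!length(cand)) cand <- coding_idx
    target[i] <- gene_id[cand[which.min(abs(tss[cand] - tss[i]))]]
  }

  ## archetype assignment
  n_de <- round(cfg$de_fraction * n)
  de_idx <- sample.int(n, n_de)
  cluster <- rep(NA_integer_, n)
  cluster[de_idx] <- rep_len(1:6, n_de)[sample.int(n_de)]

  genes <- data.frame(gene_id = gene_id, name = gene_id, chrom = chrom,
                      strand = strand, start = start, end = end, tss = tss,
                      biotype = biotype, target_gene_id = target,
                      length_bp = length_bp,
                      is_null = is.na(cluster), cluster = cluster,
                      stringsAsFactors = FALSE)
  genes$exons <- exons
  genes$utr5 <- utr5
  genes$utr3 <- utr3
  rownames(genes) <- gene_id

  half <- (cfg$promoter_len - 1L) %/% 2L
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$promoter_len, replace = TRUE),
          collapse = "")
  }, "")
  promoters <- Biostrings::DNAStringSet(seqs)
  names(promoters) <- gene_id
  attr(promoters, "half_window") <- half
  list(genes = genes, promoters = promoters)
}

## log2 archetype profiles over (D0, D14, D28), in units of log2(archetype_fc)
archetype_profiles <- function(fc) {
  L <- log2(fc)
  m <- rbind(
    c(L,       L / 2, 0),     # 1: monotone down
    c(L,       0,     L),     # 2: down then up
    c(L,       L,     0),     # 3: high-high-down
    c(L / 2,   L,     0),     # 4: up at D14 then down
    c(0,       L,     0),     # 5: D14 peak
    c(0,       0,     L)      # 6: up at D28
  )
  colnames(m) <- c("D0", "D14", "D28")
  m
}

#' Generate the RNA count matrix with planted temporal archetypes
#'
#' Each archetype gene's time-point means follow its cluster's log2 profile
#' (centered to keep the geometric mean at the gene's baseline); null genes
#' are flat. Counts are negative binomial with per-gene dispersion and mild
#' per-sample library-size variation.
#'
#' @param cfg a [sim_config()].
#' @param genes gene table from [gen_annotation()].
#' @return list with `cm` (a `count_matrix`), `truth` (per-gene cluster,
#'   is_null, true log2FC per comparison) and `mu` (true per-time-point
#'   means).
#' @export
gen_counts <- function(cfg, genes) {
  set.seed(cfg$seed + 2L)
  n <- nrow(genes)
  prof <- archetype_profiles(cfg$archetype_fc)
  base <- exp(rnorm(n, cfg$base_mean_log, cfg$base_mean_sd))
  disp <- exp(rnorm(n, log(cfg$nb_dispersion_mean), cfg$nb_dispersion_sdlog))
  lp <- matrix(0, n, 3, dimnames = list(genes$gene_id, colnames(prof)))
  de <- !genes$is_null
  lp[de, ] <- prof[genes$cluster[de], , drop = FALSE]
  lp <- lp - rowMeans(lp)
  mu <- base * 2^lp

  tps <- names(cfg$replicates)
  samples <- unlist(lapply(tps, function(tp)
    paste0(tp, "_r", seq_len(cfg$replicates[[tp]]))))
  tp_of <- rep(tps, times = unlist(cfg$replicates))
  libf <- runif(length(samples), 0.8, 1.2)
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    counts[, j] <- rnbinom(n, mu = libf[j] * mu[, tp_of[j]], size = 1 / disp)
  }
  meta <- data.frame(sample = samples, time_point = tp_of,
                     replicate = as.integer(sub(".*_r", "", samples)),
                     batch = "b1", stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = genes$gene_id, cluster = genes$cluster, is_null = genes$is_null,
    dispersion = disp, base_mean = base,
    lfc_D0vsD14 = lp[, "D14"] - lp[, "D0"],
    lfc_D14vsD28 = lp[, "D28"] - lp[, "D14"],
    lfc_D0vsD28 = lp[, "D28"] - lp[, "D0"],
    stringsAsFactors = FALSE
  )
  list(cm = count_matrix(counts, meta), truth = truth, mu = mu)
}

#' Generate ATAC peaks, presence classes and per-peak counts
#'
#' Peaks are partitioned into the seven presence classes at the configured
#' proportions (exactly, by largest-remainder allocation). Coding archetype
#' genes receive a promoter peak (present at all time points) whose D0-vs-D28
#' accessibility log2FC shares a latent variable with the gene's expression
#' log2FC so that their correlation is `coupling_rho`; remaining peaks are
#' distal and intergenic (enhancer-like). One ATAC sample per time point is
#' drawn as negative-binomial counts.
#'
#' @param cfg a [sim_config()].
#' @param genes gene table from [gen_annotation()].
#' @param counts_truth truth table from [gen_counts()] (for expression FCs).
#' @return list with `peak_sets` (per-time-point interval data.frames),
#'   `peaks` (truth: class, coupled gene, true accessibility log2FC),
#'   `counts` (peaks x 3 matrix) and `meta`.
#' @export
gen_peaks <- function(cfg, genes, counts_truth) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_peaks
  tps <- c("D0", "D14", "D28")

  ## promoter-coupled peaks: coding archetype genes, all-shared presence
  cand <- which(genes$biotype == "protein_coding" & !genes$is_null)
  n_coupled <- min(length(cand), floor(cfg$peak_class_props[["D0,D14,D28"]] * n))
  coupled_gene <- genes$gene_id[sort(sample(cand, n_coupled))]
  gi <- match(coupled_gene, genes$gene_id)

  e_lfc <- counts_truth$lfc_D0vsD28[match(coupled_gene, counts_truth$gene_id)]
  z_e <- (e_lfc - mean(e_lfc)) / sd(e_lfc)
  rho <- cfg$coupling_rho
  acc_sd <- sd(e_lfc)
  a_lfc <- acc_sd * (rho * z_e + sqrt(1 - rho^2) * rnorm(n_coupled))

  width_c <- as.integer(round(runif(n_coupled, 400, 700)))
  p_start <- as.integer(ifelse(genes$strand[gi] == "+",
                               genes$tss[gi] - width_c + 100L,
                               genes$tss[gi] - 100L))
  coupled <- data.frame(
    chrom = genes$chrom[gi], start = p_start, end = p_start + width_c,
    class = "D0,D14,D28", gene_id = coupled_gene, acc_lfc = a_lfc,
    coupled = TRUE, stringsAsFactors = FALSE
  )

  ## distal peaks fill the remaining class allocation
  alloc <- allocate_counts(n, cfg$peak_class_props)
  alloc[["D0,D14,D28"]] <- alloc[["D0,D14,D28"]] - n_coupled
  stopifnot(alloc[["D0,D14,D28"]] >= 0)
  n_distal <- n - n_coupled
  class_d <- sample(rep(names(alloc), alloc))
  chrom_len <- max(genes$end) + 2e6
  width_d <- as.integer(round(runif(n_distal, 300, 800)))
  ## distal peaks are intergenic by construction (enhancer-like OCRs):
  ## rejection-sample positions clear of any gene span +/- 1.2 kb
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(genes$start - 1200L, 1L),
                                                 genes$end + 1200L))
  chrom_d <- character(0); start_d <- integer(0)
  need <- n_distal
  while (need > 0) {
    m <- need * 2L
    ch <- paste0("chrS", sample.int(4, m, replace = TRUE))
    st <- as.integer(round(runif(m, 1e5, chrom_len)))
    cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st + 1L, st + 800L))
    free <- GenomicRanges::countOverlaps(cand, ggr) == 0
    take <- which(free)[seq_len(min(sum(free), need))]
    chrom_d <- c(chrom_d, ch[take]); start_d <- c(start_d, st[take])
    need <- n_distal - length(start_d)
  }
  distal <- data.frame(
    chrom = chrom_d, start = start_d, end = start_d + width_d,
    class = class_d, gene_id = NA_character_, acc_lfc = 0,
    coupled = FALSE, stringsAsFactors = FALSE
  )

  peaks <- rbind(coupled, distal)
  ord <- order(peaks$chrom, peaks$start)
  peaks <- peaks[ord, ]
  peaks$peak_id <- sprintf("sim_peak_%05d", seq_len(nrow(peaks)))
  rownames(peaks) <- peaks$peak_id
  for (tp in tps) {
    peaks[[tp]] <- vapply(strsplit(peaks$class, ","), function(s) tp %in% s, TRUE)
  }

  ## per-time-point NB counts; coupled peaks realise their planted log2FC
  ## between D0 and D28 (geometric midpoint at D14)
  mu <- matrix(cfg$peak_closed_mean, nrow(peaks), 3,
               dimnames = list(peaks$peak_id, tps))
  for (tp in tps) {
    open <- peaks[[tp]]
    mu[open, tp] <- cfg$peak_open_mean
  }
  cp <- peaks$coupled
  mu[cp, "D0"] <- cfg$peak_open_mean * 2^(-peaks$acc_lfc[cp] / 2)
  mu[cp, "D28"] <- cfg$peak_open_mean * 2^(peaks$acc_lfc[cp] / 2)
  mu[cp, "D14"] <- cfg$peak_open_mean

  counts <- matrix(0L, nrow(peaks), 3,
                   dimnames = list(peaks$peak_id, paste0("A_", tps)))
  for (j in seq_len(3)) {
    counts[, j] <- rnbinom(nrow(peaks), mu = mu[, j],
                           size = 1 / cfg$atac_dispersion)
  }
  meta <- data.frame(sample = colnames(counts), time_point = tps,
                     stringsAsFactors = FALSE)
  peak_sets <- lapply(tps, function(tp) {
    p <- peaks[peaks[[tp]], c("chrom", "start", "end", "peak_id")]
    names(p)[4] <- "name"
    rownames(p) <- NULL
    p
  })
  names(peak_sets) <- tps
  list(peak_sets = peak_sets, peaks = peaks, counts = counts, meta = meta,
       mu = mu)
}

## truncated-exponential + Gaussian-mode fragment-size sampler
sample_fragment_sizes <- function(cfg, n) {
  mx <- cfg$fragment_mix
  comp <- sample.int(4, n, replace = TRUE, prob = mx$w)
  sizes <- numeric(n)
  k <- sum(comp == 1)
  if (k) {
    cap <- 1 - exp(-(100 - mx$min) / mx$scale)
    u <- runif(k, 0, cap)
    sizes[comp == 1] <- mx$min - mx$scale * log(1 - u)
  }
  for (m in 2:4) {
    k <- sum(comp == m)
    if (k) sizes[comp == m] <- pmax(rnorm(k, mx$mu[m - 1], mx$sd[m - 1]), 10)
  }
  as.integer(round(sizes))
}

#' Generate ATAC fragments for one or more samples
#'
#' A `background_rate` share of fragments is uniform over the synthetic
#' genome (divided by `d0_access_boost` at D0, so the in-peak fraction and
#' hence per-million peak signal is highest in pluripotent cells); the rest
#' have midpoints uniform within a peak open at the sample's time point
#' (peaks chosen with probability proportional to their true signal). Sizes
#' follow the configured sub-100 bp + nucleosome mixture; each fragment
#' carries the strand of its generating read.
#'
#' @param cfg a [sim_config()].
#' @param peak_model output of [gen_peaks()].
#' @param timepoints which samples to draw (default all three).
#' @return data.frame chrom, start, end, strand, sample (0-based half-open).
#' @export
gen_fragments <- function(cfg, peak_model, timepoints = c("D0", "D14", "D28")) {
  set.seed(cfg$seed + 4L)
  peaks <- peak_model$peaks
  chrom_len <- max(peaks$end) + 1e5
  out <- vector("list", length(timepoints))
  for (s in seq_along(timepoints)) {
    tp <- timepoints[s]
    n <- cfg$n_fragments
    sizes <- sample_fragment_sizes(cfg, n)
    bg_rate <- if (tp == "D0") cfg$background_rate / cfg$d0_access_boost else
      cfg$background_rate
    in_peak <- runif(n) >= bg_rate
    mid <- numeric(n)
    nb <- sum(!in_peak)
    chrom <- character(n)
    if (nb) {
      chrom[!in_peak] <- paste0("chrS", sample.int(4, nb, replace = TRUE))
      mid[!in_peak] <- round(runif(nb, 1000, chrom_len))
    }
    np <- sum(in_peak)
    if (np) {
      open <- which(peaks[[tp]])
      w <- peak_model$mu[open, tp]
      pk <- open[sample.int(length(open), np, replace = TRUE, prob = w)]
      chrom[in_peak] <- peaks$chrom[pk]
      mid[in_peak] <- peaks$start[pk] +
        round(runif(np) * (peaks$end[pk] - peaks$start[pk] - 1))
    }
    start <- as.integer(pmax(round(mid - sizes / 2), 0))
    out[[s]] <- data.frame(
      chrom = chrom, start = start, end = start + sizes,
      strand = sample(c("+", "-"), n, replace = TRUE),
      sample = tp, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Plant motif occurrences in promoter sequences
#'
#' For each (cluster, motif) pair with a positive planting rate, each
#' promoter of a gene in that cluster independently receives one site
#' sampled base-by-base from the PWM, inserted at a random offset on a
#' random strand. A truth table records every planted site.
#'
#' @param cfg a [sim_config()].
#' @param pwms list of PWMs (as from [read_pwms()]).
#' @param promoters named DNAStringSet of promoter sequences.
#' @param clusters named integer vector gene -> cluster (NA = no cluster).
#' @param rates matrix clusters x motifs of planting probabilities; default
#'   a constant `cfg$motif_plant_rate` for every pair.
#' @return list with `promoters` (modified DNAStringSet) and `truth`
#'   (data.frame gene_id, motif_id, offset, strand, site).
#' @export
gen_motif_plant <- function(cfg, pwms, promoters, clusters, rates = NULL) {
  set.seed(cfg$seed + 5L)
  motif_ids <- vapply(pwms, `[[`, "", "motif_id")
  if (is.null(rates)) {
    rates <- matrix(cfg$motif_plant_rate, 6, length(pwms),
                    dimnames = list(as.character(1:6), motif_ids))
  }
  seqs <- as.character(promoters)
  truth <- list()
  bases <- c("A", "C", "G", "T")
  for (g in names(seqs)) {
    cl <- if (g %in% names(clusters)) clusters[[g]] else NA
    if (is.na(cl)) next
    for (m in seq_along(pwms)) {
      r <- rates[as.character(cl), motif_ids[m]]
      if (r <= 0 || runif(1) > r) next
      probs <- pwms[[m]]$probs
      site <- paste(vapply(seq_len(nrow(probs)), function(i)
        sample(bases, 1, prob = probs[i, ]), ""), collapse = "")
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") site else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
      L <- nchar(ins)
      off <- sample.int(nchar(seqs[[g]]) - L + 1L, 1) - 1L
      substr(seqs[[g]], off + 1L, off + L) <- ins
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = g, motif_id = motif_ids[m], offset = off, strand = strand,
        site = site, stringsAsFactors = FALSE)
    }
  }
  planted <- Biostrings::DNAStringSet(seqs)
  names(planted) <- names(promoters)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), motif_id = character(),
               offset = integer(), strand = character(), site = character())
  list(promoters = planted, truth = truth)
}

#' Generate a synthetic enhancer database and SNP positions
#'
#' The enhancer table covers `enhancer_fraction` of D0-specific peaks
#' (each extended by 200 bp) plus an equal number of random decoy intervals.
#' SNPs are placed inside peaks with per-bp uniform probability, except that
#' D28-specific distal (non-promoter) peaks are weighted by `snp_odds`;
#' odds of 1 gives the uniform null.
#'
#' @param cfg a [sim_config()].
#' @param peak_model output of [gen_peaks()].
#' @return list with `enhancers` and `snps` data.frames and the index of
#'   covered D0 peaks as attribute "covered".
#' @export
gen_enhancer_db_and_snps <- function(cfg, peak_model) {
  set.seed(cfg$seed + 6L)
  peaks <- peak_model$peaks
  d0spec <- which(peaks$class == "D0")
  n_cov <- round(cfg$enhancer_fraction * length(d0spec))
  covered <- sort(sample(d0spec, n_cov))
  chrom_len <- max(peaks$end) + 1e5
  dec_start <- round(runif(n_cov, 1e5, chrom_len))
  enhancers <- rbind(
    data.frame(chrom = peaks$chrom[covered],
               start = pmax(peaks$start[covered] - 200L, 0L),
               end = peaks$end[covered] + 200L, stringsAsFactors = FALSE),
    data.frame(chrom = paste0("chrS", sample.int(4, n_cov, replace = TRUE)),
               start = as.integer(dec_start),
               end = as.integer(dec_start + 500L), stringsAsFactors = FALSE)
  )

  target <- peaks$class == "D28" & !peaks$coupled
  w <- (peaks$end - peaks$start) * ifelse(target, cfg$snp_odds, 1)
  pk <- sample.int(nrow(peaks), cfg$n_snps, replace = TRUE, prob = w)
  pos <- peaks$start[pk] +
    floor(runif(cfg$n_snps) * (peaks$end[pk] - peaks$start[pk]))
  snps <- data.frame(chrom = peaks$chrom[pk], pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  structure(list(enhancers = enhancers, snps = snps), covered = covered)
}
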