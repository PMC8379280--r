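## ATAC fragment- and peak-level computations: Tn5 cut-site offsetting,
## fragment-size histogram with nucleosome-mode detection, consensus peak
## construction by gap-bounded merging, Venn categorisation across time
## points, midpoint annotation against gene models, differential
## accessibility, database-overlap fractions, SNP-overlap hypergeometrics,
## and locus-level Mann-Whitney tests on normalized per-OCR counts.

#' Tn5 cut-site offset correction
#'
#' Shifts plus-strand cut sites by +4 bp and minus-strand cut sites by -5 bp
#' to center reads on the transposase insertion. For a fragment record the
#' start comes from the plus-strand read and the end from the minus-strand
#' read, so start moves +4 and end moves -5. The shift is recorded in
#' `attr(x, "tn5_shifted")`; applying it twice is an error. Records with a
#' missing strand are left unshifted with a warning.
#'
#' @param fragments data.frame with chrom, start, end and optionally strand.
#' @return shifted fragments.
#' @export
tn5_shift <- function(fragments) {
  if (isTRUE(attr(fragments, "tn5_shifted"))) {
    stop("fragments already Tn5-shifted; refusing to shift twice")
  }
  if (!"strand" %in% names(fragments) || anyNA(fragments$strand)) {
    if (!"strand" %in% names(fragments)) {
      warning("no strand column; fragments left unshifted")
      attr(fragments, "tn5_shifted") <- TRUE
      return(fragments)
    }
    warning(sum(is.na(fragments$strand)), " fragment(s) without strand left unshifted")
  }
  plus <- fragments$strand %in% "+"
  minus <- fragments$strand %in% "-"
  ## paired fragment: both ends are cut sites; start is the +-strand cut,
  ## end the --strand cut
  fragments$start[plus | minus] <- fragments$start[plus | minus] + 4L
  fragments$end[plus | minus] <- fragments$end[plus | minus] - 5L
  attr(fragments, "tn5_shifted") <- TRUE
  fragments
}

#' Fragment-size histogram with nucleosome-mode detection
#'
#' Sizes (end - start) are binned at `bin_width` bp; a 3-bin moving average
#' smooths the counts and local maxima with prominence at least 5% of the
#' smoothed maximum are reported as modes (bin centers, ascending).
#'
#' @param fragments data.frame with start and end.
#' @param bin_width bin width in bp (default 10).
#' @return list with breaks, counts, smoothed, modes (bp), bin_width.
#' @export
size_histogram <- function(fragments, bin_width = 10) {
  sizes <- fragments$end - fragments$start
  stopifnot(all(sizes > 0))
  top <- ceiling(max(sizes) / bin_width) * bin_width
  breaks <- seq(0, top, by = bin_width)
  counts <- tabulate(pmin(floor(sizes / bin_width) + 1L, length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  sm <- smooth3(counts)
  centers <- breaks[-length(breaks)] + bin_width / 2
  modes <- centers[find_modes(sm, min_prominence = 0.05 * max(sm))]
  list(breaks = breaks, counts = counts, smoothed = sm,
       modes = sort(modes), bin_width = bin_width)
}

smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  xp <- c(x[1], x, x[n])
  (xp[1:n] + xp[2:(n + 1)] + xp[3:(n + 2)]) / 3
}

## Local maxima of a series with a simple prominence filter: walk out from
## each candidate until a strictly higher value (or the edge); the key col is
## the higher of the two valley minima and prominence is height above it.
find_modes <- function(s, min_prominence = 0) {
  n <- length(s)
  if (n < 3L) return(integer())
  cand <- which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lmin <- s[i]; j <- i
    while (j > 1 && s[j - 1] <= s[i]) { j <- j - 1; lmin <- min(lmin, s[j]) }
    lmin <- if (j == 1 && s[1] <= s[i]) min(lmin, min(s[1:i])) else lmin
    rmin <- s[i]; j <- i
    while (j < n && s[j + 1] <= s[i]) { j <- j + 1; rmin <- min(rmin, s[j]) }
    keycol <- max(lmin, rmin)
    keep[k] <- (s[i] - keycol) >= min_prominence
  }
  cand[keep]
}

#' Merge per-time-point peak sets into consensus peaks
#'
#' The union of all peaks is merged transitively whenever the gap between
#' intervals on the same chromosome is at most `gap` bp (inclusive, so
#' touching or 100 bp-separated peaks join at the default). Each consensus
#' peak records which time points contributed at least one overlapping
#' source peak.
#'
#' @param peak_sets named list time point -> interval data.frame
#'   (chrom/start/end, 0-based half-open).
#' @param gap maximum merge gap in bp (default 100).
#' @return data.frame peak_id, chrom, start, end, present_in (comma-joined
#'   labels), n_timepoints, and one logical column per time point.
#' @export
merge_consensus <- function(peak_sets, gap = 100) {
  stopifnot(length(peak_sets) >= 1, !is.null(names(peak_sets)))
  all_df <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  gr <- as_granges(all_df)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    stringsAsFactors = FALSE
  )
  for (tp in names(peak_sets)) {
    hits <- GenomicRanges::countOverlaps(merged, as_granges(peak_sets[[tp]]))
    out[[tp]] <- hits > 0
  }
  pres <- as.matrix(out[, names(peak_sets), drop = FALSE])
  stopifnot(all(rowSums(pres) > 0))  # every consensus peak has a source
  out$present_in <- apply(pres, 1, function(r)
    paste(names(peak_sets)[r], collapse = ","))
  out$n_timepoints <- rowSums(pres)
  ord <- order(out$chrom, out$start)
  out <- out[ord, c("chrom", "start", "end", names(peak_sets),
                    "present_in", "n_timepoints")]
  out$peak_id <- sprintf("peak_%06d", seq_len(nrow(out)))
  rownames(out) <- out$peak_id
  out[, c("peak_id", setdiff(names(out), "peak_id"))]
}

#' Venn categories of consensus peaks across time points
#'
#' Counts consensus peaks per presence subset (all 2^T - 1 non-empty
#' subsets) and reports integer percentages of the total.
#'
#' @param consensus output of [merge_consensus()].
#' @param timepoints time-point column names; default the logical columns.
#' @return data.frame subset, count, percent; total as attribute "total".
#' @export
venn_categories <- function(consensus, timepoints = NULL) {
  if (is.null(timepoints)) {
    timepoints <- names(consensus)[vapply(consensus, is.logical, TRUE)]
  }
  tab <- table(factor(consensus$present_in))
  subsets <- unlist(lapply(seq_along(timepoints), function(k)
    combn(timepoints, k, paste, collapse = ",", simplify = FALSE)),
    use.names = FALSE)
  counts <- vapply(subsets, function(s)
    if (s %in% names(tab)) as.integer(tab[[s]]) else 0L, 1L)
  total <- nrow(consensus)
  out <- data.frame(subset = unlist(subsets), count = counts,
                    percent = vapply(counts, function(x)
                      fraction_report(x, total)$percent, 1.0),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Annotate consensus peaks against gene models
#'
#' Category is decided by the peak midpoint with priority
#' promoter-TSS > TTS > 5UTR > 3UTR > exon > intron > intergenic.
#' Promoter-TSS spans 1 kb upstream plus 100 bp downstream of the TSS
#' (strand-aware); TTS is the mirror image around the transcript end. UTR
#' categories require `utr5`/`utr3` list-columns in the gene models (absent
#' ones simply never match). `nearest_gene` and signed `dist_to_tss`
#' (positive downstream of the TSS in the gene's orientation) are always
#' set.
#'
#' @param consensus consensus-peak data.frame.
#' @param genes gene-model data.frame.
#' @param promoter_up,promoter_down promoter extent in bp (defaults 1000/100).
#' @return `consensus` with category, nearest_gene, dist_to_tss columns.
#' @export
annotate_peaks <- function(consensus, genes, promoter_up = 1000,
                           promoter_down = 100) {
  if (nrow(genes) == 0L) {
    warning("empty annotation: all peaks intergenic")
    consensus$category <- "intergenic"
    consensus$nearest_gene <- NA_character_
    consensus$dist_to_tss <- NA_integer_
    return(consensus)
  }
  mid <- (consensus$start + consensus$end) %/% 2L
  n <- nrow(consensus)
  plus <- genes$strand == "+"
  midgr <- GenomicRanges::GRanges(consensus$chrom,
                                  IRanges::IRanges(mid + 1L, mid + 1L))

  ## nearest gene by distance of midpoint to TSS; signed distance is
  ## oriented (positive downstream of the TSS)
  tssgr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  nj <- GenomicRanges::nearest(midgr, tssgr)
  nearest <- ifelse(is.na(nj), NA_character_, genes$gene_id[nj])
  d_raw <- mid - genes$tss[nj]
  dist <- as.integer(ifelse(plus[nj], d_raw, -d_raw))
  dist[is.na(nj)] <- NA_integer_

  hit_any <- function(gr) {
    GenomicRanges::countOverlaps(midgr, gr) > 0
  }
  window_gr <- function(anchor, up, down) {
    ## strand-aware half-open [anchor-up, anchor+down) on "+",
    ## (anchor-down, anchor+up] on "-"
    lo <- ifelse(plus, anchor - up, anchor - down)
    hi <- ifelse(plus, anchor + down, anchor + up)
    GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(lo + 1L, hi))
  }
  list_col_gr <- function(col) {
    if (!col %in% names(genes)) return(GenomicRanges::GRanges())
    ivs <- genes[[col]]
    counts <- vapply(ivs, function(m) if (is.null(m)) 0L else nrow(m), 1L)
    if (sum(counts) == 0L) return(GenomicRanges::GRanges())
    allm <- do.call(rbind, ivs[counts > 0])
    GenomicRanges::GRanges(rep(genes$chrom[counts > 0], counts[counts > 0]),
                           IRanges::IRanges(allm[, 1] + 1L, allm[, 2]))
  }

  tes <- ifelse(plus, genes$end, genes$start)  # transcript end site
  is_prom <- hit_any(window_gr(genes$tss, promoter_up, promoter_down))
  is_tts <- hit_any(window_gr(tes, promoter_down, promoter_up))
  is_u5 <- hit_any(list_col_gr("utr5"))
  is_u3 <- hit_any(list_col_gr("utr3"))
  is_exon <- hit_any(list_col_gr("exons"))
  bodygr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start + 1L, genes$end))
  is_intron <- hit_any(bodygr) & !is_exon

  category <- rep("intergenic", n)

  category[is_intron] <- "intron"
  category[is_exon] <- "exon"
  category[is_u3] <- "3UTR"
  category[is_u5] <- "5UTR"
  category[is_tts] <- "TTS"
  category[is_prom] <- "promoter-TSS"

  consensus$category <- category
  consensus$nearest_gene <- nearest
  consensus$dist_to_tss <- dist
  consensus
}

#' Differential accessibility between two time points
#'
#' Runs the negative-binomial Wald machinery on per-peak counts. Following
#' the study's criterion, a peak is significant when |log2FC| > `lfc` (strict)
#' and the raw p-value is below `alpha` — note this uses the unadjusted p,
#' unlike the RNA DEG rule. With one sample per group the dispersion comes
#' from the mean-dispersion trend alone and results are flagged
#' `low_confidence`.
#'
#' @param counts_in_peaks matrix peaks x samples.
#' @param groups two-level factor over samples.
#' @param sf size factors (computed if NULL).
#' @param lfc absolute log2 fold-change threshold (default 1.5).
#' @param alpha raw p threshold (default 0.05).
#' @param comparison label.
#' @return [nb_test()]-style data.frame with a `significant` column;
#'   all-zero peaks are excluded.
#' @export
diff_accessibility <- function(counts_in_peaks, groups, sf = NULL,
                               lfc = 1.5, alpha = 0.05,
                               comparison = "AvsB") {
  keep <- rowSums(counts_in_peaks) > 0
  counts <- counts_in_peaks[keep, , drop = FALSE]
  res <- nb_test(counts, groups, sf = sf, comparison = comparison)
  res$significant <- abs(res$log2fc) > lfc & res$p < alpha
  res
}

#' Fraction of query peaks overlapping a database of intervals
#'
#' A query counts as overlapping when it shares at least 1 bp with any
#' database interval.
#'
#' @param query_peaks,db_intervals interval data.frames (chrom/start/end).
#' @return [fraction_report()] list plus n_overlap/n_total aliases.
#' @export
overlap_fraction <- function(query_peaks, db_intervals) {
  total <- nrow(query_peaks)
  if (total == 0L) stop("no query peaks")
  if (nrow(db_intervals) == 0L) {
    r <- list(fraction = 0, percent = 0,
              label = sprintf("0%% (0/%d)", total))
  } else {
    hits <- GenomicRanges::countOverlaps(as_granges(query_peaks),
                                         as_granges(db_intervals))
    r <- fraction_report(sum(hits > 0), total)
  }
  r$n_overlap <- round(r$fraction * total)
  r$n_total <- total
  r
}

#' Hypergeometric SNP-overlap test per peak class
#'
#' For each class of peaks (e.g. time-point-specific peaks of one annotation
#' category): M = universe peaks, K = universe peaks containing at least one
#' SNP, n = peaks in the class, x = SNP-containing peaks in the class;
#' upper-tail p with BH across classes. SNPs falling outside every universe
#' peak only reduce K implicitly.
#'
#' @param peaks_by_class named list class -> interval data.frame; each must
#'   be a subset of the universe.
#' @param snps data.frame with chrom and pos (0-based) or chrom/start/end.
#' @param universe interval data.frame of all consensus peaks.
#' @return data.frame class, x, n, K, M, p, q.
#' @export
snp_overlap_test <- function(peaks_by_class, snps, universe) {
  if (!"start" %in% names(snps)) {
    snps <- data.frame(chrom = snps$chrom, start = snps$pos,
                       end = snps$pos + 1L)
  }
  ugr <- as_granges(universe)
  sgr <- as_granges(snps)
  has_snp <- GenomicRanges::countOverlaps(ugr, sgr) > 0
  M <- nrow(universe); K <- sum(has_snp)
  out <- lapply(names(peaks_by_class), function(cl) {
    p <- peaks_by_class[[cl]]
    n <- nrow(p)
    x <- if (n == 0L) 0L else
      sum(GenomicRanges::countOverlaps(as_granges(p), sgr) > 0)
    data.frame(class = cl, x = x, n = n, K = K, M = M,
               p = hypergeom_tail(x, K, n, M), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_fdr(out$p)
  out
}

#' Mann-Whitney test on normalized per-OCR counts at a locus
#'
#' Per-OCR fragment counts for the two samples are scaled to counts per
#' million of each sample's total, then compared by a two-sided Mann-Whitney
#' U test (exact when both sides have at most 8 OCR values and no ties,
#' normal approximation otherwise). With fewer than 3 OCRs the locus is
#' rejected. When every normalized value ties across the two samples the
#' two-sided p is 1 by convention.
#'
#' @param counts_a,counts_b per-OCR fragment counts at the locus for the two
#'   samples (same OCR order).
#' @param total_a,total_b library totals used for per-million scaling;
#'   default 1e6 treats the counts as already normalized.
#' @return list with p, statistic, n_ocr, method.
#' @export
locus_mw_test <- function(counts_a, counts_b, total_a = 1e6,
                          total_b = 1e6) {
  n <- length(counts_a)
  if (n < 3L || length(counts_b) < 3L) {
    stop("fewer than 3 OCRs in locus; insufficient regions for a rank test")
  }
  na <- counts_a / total_a * 1e6
  nb <- counts_b / total_b * 1e6
  if (identical(sort(na), sort(nb))) {
    ## identical normalized samples: fully tied, no evidence either way
    return(list(p = 1, statistic = n * length(nb) / 2, n_ocr = n,
                method = "tied"))
  }
  exact <- n <= 8 && length(nb) <= 8 && !anyDuplicated(c(na, nb))
  wt <- suppressWarnings(stats::wilcox.test(na, nb, alternative = "two.sided",
                                            exact = exact, correct = !exact))
  list(p = wt$p.value, statistic = unname(wt$statistic), n_ocr = n,
       method = if (exact) "exact" else "normal-approximation")
}
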