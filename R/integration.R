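## Accessibility-expression integration: the fold-change/fold-change
## correlation over gene-peak pairs, per-OCR signal matrices with k-means
## row grouping, and per-cluster TSS metaprofiles.

#' Correlate accessibility and expression fold-changes
#'
#' Accessibility records are filtered to raw p < `alpha` and to peaks
#' annotated as promoter-TSS, exon or intron; each qualifying peak is joined
#' to its annotated nearest gene and contributes one (expression log2FC,
#' accessibility log2FC) pair. With `best_peak_per_gene` only the peak with
#' the largest absolute accessibility fold-change per gene is kept. Pearson
#' correlation with a two-sided test is reported over the pairs.
#'
#' @param expr_de expression results (gene_id, log2fc).
#' @param access_de accessibility results (gene_id column = peak id via
#'   `peak_id`, log2fc, p).
#' @param annotations annotated consensus peaks (peak_id, category,
#'   nearest_gene).
#' @param alpha accessibility p filter (default 0.05).
#' @param categories annotation categories retained.
#' @param best_peak_per_gene keep only the strongest peak per gene.
#' @return list with r, p, n and the pair `records` data.frame.
#' @export
fcfc_correlation <- function(expr_de, access_de, annotations, alpha = 0.05,
                             categories = c("promoter-TSS", "exon", "intron"),
                             best_peak_per_gene = FALSE) {
  acc <- access_de[access_de$p < alpha, , drop = FALSE]
  ann <- annotations[annotations$category %in% categories,
                     c("peak_id", "category", "nearest_gene")]
  m <- merge(acc, ann, by.x = "gene_id", by.y = "peak_id")
  names(m)[names(m) == "gene_id"] <- "peak_id"
  ei <- match(m$nearest_gene, expr_de$gene_id)
  rec <- data.frame(
    gene_id = m$nearest_gene, peak_id = m$peak_id,
    expr_log2fc = expr_de$log2fc[ei], access_log2fc = m$log2fc,
    category = m$category, stringsAsFactors = FALSE
  )
  rec <- rec[!is.na(rec$expr_log2fc), , drop = FALSE]
  if (best_peak_per_gene && nrow(rec)) {
    rec <- rec[order(rec$gene_id, -abs(rec$access_log2fc)), ]
    rec <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  }
  if (nrow(rec) < 3L) stop("fewer than 3 gene-peak pairs; cannot correlate")
  ct <- cor.test(rec$expr_log2fc, rec$access_log2fc, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(rec), records = rec)
}

#' Per-OCR binned fragment signal matrix
#'
#' Fragment midpoints are counted in `bin` bp bins over OCR center +/-
#' `half_window`, scaled to counts per million fragments.
#'
#' @param fragments fragment data.frame (chrom, start, end).
#' @param ocrs interval data.frame of OCRs.
#' @param half_window half-width in bp (default 5000).
#' @param bin bin width in bp (default 100).
#' @return matrix OCRs x bins (counts per million), with attribute
#'   "n_fragments".
#' @export
signal_matrix <- function(fragments, ocrs, half_window = 5000, bin = 100) {
  nbins <- as.integer(2 * half_window / bin)
  center <- (ocrs$start + ocrs$end) %/% 2L
  win <- data.frame(chrom = ocrs$chrom, start = center - half_window,
                    end = center + half_window)
  mids <- (fragments$start + fragments$end) %/% 2L
  mgr <- GenomicRanges::GRanges(fragments$chrom,
                                IRanges::IRanges(mids + 1L, mids + 1L))
  wgr <- as_granges(win)
  hits <- GenomicRanges::findOverlaps(mgr, wgr)
  m <- matrix(0, nrow(ocrs), nbins)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    b <- pmin(pmax((mids[qi] - win$start[si]) %/% bin + 1L, 1L), nbins)
    idx <- (b - 1L) * nrow(ocrs) + si  # column-major accumulation
    tab <- table(idx)
    m[as.integer(names(tab))] <- as.integer(tab)
  }
  m <- m / (nrow(fragments) / 1e6)
  rownames(m) <- if ("peak_id" %in% names(ocrs)) ocrs$peak_id else NULL
  attr(m, "n_fragments") <- nrow(fragments)
  m
}

#' k-means row grouping with fixed seed
#'
#' Runs k-means (k-means++-style multiple restarts via `nstart`) under a
#' fixed seed and returns the best-inertia labelling.
#'
#' @param m numeric matrix.
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @param nstart restarts (default 10).
#' @return integer vector of row labels.
#' @export
kmeans_rows <- function(m, k = 3, seed = 1L, nstart = 10) {
  if (k > nrow(m)) stop("k exceeds the number of rows")
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = nstart, iter.max = 50)
  km$cluster
}

#' Per-expression-cluster TSS metaprofiles
#'
#' Mean normalized fragment coverage in TSS +/- `half_window`, binned at
#' `bin` bp, strand-oriented so upstream is always on the left, averaged
#' over the genes of each expression cluster, separately per sample label in
#' the fragment table. Empty clusters give a zero profile with a flag.
#'
#' @param fragments fragment data.frame with a `sample` column.
#' @param genes gene-model data.frame.
#' @param cluster_assignment named vector gene -> cluster.
#' @param half_window,bin window geometry in bp.
#' @return list cluster -> sample -> numeric profile; empty clusters carry
#'   attribute "empty".
#' @export
promoter_metaprofile <- function(fragments, genes, cluster_assignment,
                                 half_window = 5000, bin = 100) {
  nbins <- as.integer(2 * half_window / bin)
  samples <- unique(fragments$sample)
  out <- list()
  for (cl in sort(unique(cluster_assignment[!is.na(cluster_assignment)]))) {
    gids <- names(cluster_assignment)[cluster_assignment %in% cl]
    g <- genes[genes$gene_id %in% gids, , drop = FALSE]
    prof <- list()
    for (s in samples) {
      fr <- fragments[fragments$sample == s, , drop = FALSE]
      v <- numeric(nbins)
      if (nrow(g)) {
        win <- data.frame(chrom = g$chrom, start = g$tss - half_window,
                          end = g$tss + half_window)
        mids <- (fr$start + fr$end) %/% 2L
        mgr <- GenomicRanges::GRanges(fr$chrom,
                                      IRanges::IRanges(mids + 1L, mids + 1L))
        wgr <- as_granges(win)
        hits <- GenomicRanges::findOverlaps(mgr, wgr)
        m <- matrix(0, nrow(g), nbins)
        if (length(hits)) {
          qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
          b <- pmin(pmax((mids[qi] - win$start[si]) %/% bin + 1L, 1L), nbins)
          flip <- g$strand[si] == "-"
          b[flip] <- nbins + 1L - b[flip]  # orient upstream to the left
          idx <- (b - 1L) * nrow(g) + si
          tab <- table(idx)
          m[as.integer(names(tab))] <- as.integer(tab)
        }
        v <- colMeans(m) / (nrow(fr) / 1e6)
      } else {
        attr(v, "empty") <- TRUE
      }
      prof[[s]] <- v
    }
    out[[as.character(cl)]] <- prof
  }
  out
}
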