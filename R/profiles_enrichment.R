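## Temporal clustering of DEGs on row z-scores of log2(FPKM+1) per-time-point
## means, and hypergeometric gene-set enrichment with BH control.

#' Exact upper-tail hypergeometric probability
#'
#' P(X >= x) where X counts marked items in a draw of n from a population of
#' M containing K marked items.
#'
#' @param x observed overlap.
#' @param K marked items in the population.
#' @param n draw size.
#' @param M population size.
#' @return exact upper-tail probability.
#' @export
hypergeom_tail <- function(x, K, n, M) {
  if (any(K > M) || any(n > M) || any(x > n) || any(x < 0) ||
      any(K < 0) || any(n < 0)) {
    stop("impossible hypergeometric arguments")
  }
  phyper(x - 1, K, M - K, n, lower.tail = FALSE)
}

#' Row z-scores
#'
#' Rows are centered and scaled to unit standard deviation; constant rows
#' become all-zero and are flagged in `attr(x, "degenerate")`.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  degenerate <- s == 0 | !is.finite(s)
  s[degenerate] <- 1
  z <- (m - mu) / s
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- degenerate
  z
}

#' Temporal clustering of DEGs
#'
#' Replicate-averaged FPKM per time point is log2(FPKM+1)-transformed and
#' row z-scored, then clustered by agglomerative hierarchical clustering
#' (Euclidean distance, Ward linkage) with the tree cut at k. Cluster labels
#' are renumbered by descending size so label 1 is always the largest.
#'
#' @param fpkm_by_timepoint matrix genes x time points of mean FPKM
#'   (replicates already averaged).
#' @param degs character vector of gene ids to cluster (rows must exist).
#' @param k number of clusters (default 6).
#' @param linkage hclust method (default "ward.D2").
#' @return list with `labels` (named integer vector), `zscores` (matrix),
#'   `degenerate` (logical, constant input rows), `tree` (hclust).
#' @export
cluster_degs <- function(fpkm_by_timepoint, degs, k = 6, linkage = "ward.D2") {
  m <- fpkm_by_timepoint[degs, , drop = FALSE]
  if (k > nrow(m)) stop("k exceeds the number of genes to cluster")
  z <- row_zscore(log2(m + 1))
  tree <- hclust(dist(z), method = linkage)
  raw <- cutree(tree, k = k)
  ## renumber by descending cluster size, ties by original label
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- setNames(seq_len(k), names(sizes)[ord])
  labels <- unname(remap[as.character(raw)])
  names(labels) <- rownames(m)
  list(labels = labels, zscores = z,
       degenerate = attr(z, "degenerate"), tree = tree)
}

#' Hypergeometric gene-set enrichment of a gene cluster
#'
#' Each set is tested for over-representation in `cluster_genes` relative to
#' `universe` by the exact upper-tail hypergeometric probability; BH is
#' applied across sets. Sets with no overlap are not reported.
#'
#' @param cluster_genes character vector of gene ids.
#' @param gene_sets named list of gene-id vectors (e.g. [read_gene_sets()]).
#' @param universe character vector defining the population (commonly all
#'   genes with max FPKM >= 1).
#' @param fdr significance threshold for the `significant` flag.
#' @return data.frame set_name, overlap, set_size, cluster_size,
#'   universe_size, p, q, significant, sorted by q.
#' @export
enrich_gene_sets <- function(cluster_genes, gene_sets, universe, fdr = 0.05) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  cl <- intersect(unique(cluster_genes), universe)
  M <- length(universe); n <- length(cl)
  rec <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    x <- length(intersect(set, cl))
    if (x == 0L) return(NULL)
    data.frame(set_name = nm, overlap = x, set_size = length(set),
               cluster_size = n, universe_size = M,
               p = hypergeom_tail(x, length(set), n, M),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  if (is.null(rec)) {
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), cluster_size = integer(),
                      universe_size = integer(), p = numeric(), q = numeric(),
                      significant = logical()))
  }
  rec$q <- bh_fdr(rec$p)
  rec$significant <- rec$q < fdr
  rec[order(rec$q, rec$p), , drop = FALSE]
}
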