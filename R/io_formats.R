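#' @importFrom stats median p.adjust pnorm cor.test ks.test rnbinom rnorm
#'   runif rexp sd mad var cutree hclust dist kmeans phyper setNames
#'   quantile aggregate
#' @importFrom utils read.delim write.table head
NULL

## Biotype vocabulary: the six GENCODE long non-coding classes plus coding.
LNC_BIOTYPES <- c("lincRNA", "antisense", "sense_intronic",
                  "processed_transcript", "sense_overlapping", "TEC")
KNOWN_BIOTYPES <- c("protein_coding", LNC_BIOTYPES)

#' Is a biotype one of the long non-coding classes?
#'
#' The six GENCODE classes lincRNA, antisense, sense_intronic,
#' processed_transcript, sense_overlapping and TEC are grouped as "lncRNA";
#' everything else is treated as coding/other.
#'
#' @param biotype character vector of biotype labels.
#' @return logical vector.
#' @export
is_lncrna <- function(biotype) biotype %in% LNC_BIOTYPES

## ---------------------------------------------------------------------------
## GTF gene models
## ---------------------------------------------------------------------------

gtf_attr <- function(attrs, key) {
  r <- regexpr(paste0(key, ' "[^"]*"'), attrs)
  out <- rep(NA_character_, length(attrs))
  m <- regmatches(attrs, r)  # matches for matching elements only
  out[r > 0] <- sub('"$', "", sub(paste0(key, ' "'), "", m))
  out
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- c(); oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      outs <- c(outs, ms); oute <- c(oute, me); ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

#' Read gene models from a GTF file
#'
#' Parses a 9-column GTF restricted to the attributes gene_id, gene_name and
#' gene_type. One model is returned per gene_id; exon records are aggregated
#' and merged. GTF 1-based inclusive coordinates are converted to 0-based
#' half-open at this boundary; all downstream arithmetic is half-open.
#' The TSS is the start for "+" genes and the end for "-" genes. Strand "."
#' is treated as "+" with a warning. Biotypes outside the known GENCODE set
#' are retained verbatim but flagged in the `unknown_biotype` column.
#'
#' @param path path to a GTF-like text file.
#' @return data.frame with one row per gene: gene_id, name, chrom, strand,
#'   start, end, tss, biotype, unknown_biotype, target_gene_id, length_bp,
#'   and a list-column `exons` of two-column matrices (0-based half-open).
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 9L)) {
    stop("malformed GTF line (expected 9 tab-separated columns): line ",
         which(nf != 9L)[1])
  }
  tab <- data.frame(
    chrom   = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start   = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,  # to half-open
    end     = as.integer(vapply(fields, `[[`, "", 5L)),
    strand  = vapply(fields, `[[`, "", 7L),
    attrs   = vapply(fields, `[[`, "", 9L),
    stringsAsFactors = FALSE
  )
  if (anyNA(tab$start) || anyNA(tab$end)) {
    stop("malformed GTF line (non-numeric coordinate): line ",
         which(is.na(tab$start) | is.na(tab$end))[1])
  }
  tab$gene_id <- gtf_attr(tab$attrs, "gene_id")
  if (anyNA(tab$gene_id)) {
    stop("malformed GTF line (missing gene_id): line ", which(is.na(tab$gene_id))[1])
  }
  tab$gene_name <- gtf_attr(tab$attrs, "gene_name")
  tab$gene_type <- gtf_attr(tab$attrs, "gene_type")
  tab$target    <- gtf_attr(tab$attrs, "target_gene_id")

  if (any(tab$strand == ".")) {
    warning("strand '.' treated as '+' for TSS computation")
    tab$strand[tab$strand == "."] <- "+"
  }

  ids <- unique(tab$gene_id)
  rows <- lapply(ids, function(id) {
    g <- tab[tab$gene_id == id, , drop = FALSE]
    ex <- g[g$feature == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- g  # gene-only records: whole span is the exon
    exons <- merge_intervals(ex$start, ex$end)
    start <- min(g$start); end <- max(g$end)
    strand <- g$strand[1]
    data.frame(
      gene_id = id,
      name = if (is.na(g$gene_name[1])) id else g$gene_name[1],
      chrom = g$chrom[1], strand = strand,
      start = start, end = end,
      tss = if (strand == "+") start else end,
      biotype = if (is.na(g$gene_type[1])) "protein_coding" else g$gene_type[1],
      target_gene_id = g$target[1],
      length_bp = sum(exons[, "end"] - exons[, "start"]),
      stringsAsFactors = FALSE
    ) -> r
    r$exons <- list(exons)
    r
  })
  out <- do.call(rbind, rows)
  out$unknown_biotype <- !(out$biotype %in% KNOWN_BIOTYPES)
  rownames(out) <- out$gene_id
  out
}

#' Write gene models as GTF
#'
#' Emits one `gene` line and one `exon` line per exon, converting internal
#' 0-based half-open coordinates back to GTF 1-based inclusive.
#'
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    at <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                  g$gene_id, g$name, g$biotype)
    if (!is.na(g$target_gene_id))
      at <- paste0(at, sprintf(' target_gene_id "%s";', g$target_gene_id))
    writeLines(paste(g$chrom, "sim", "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", at, sep = "\t"), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      writeLines(paste(g$chrom, "sim", "exon", ex[j, 1] + 1L, ex[j, 2], ".",
                       g$strand, ".", at, sep = "\t"), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED / narrowPeak intervals
## ---------------------------------------------------------------------------

#' Read genomic intervals from BED or narrowPeak text
#'
#' Coordinates are 0-based half-open and preserved as written. For 10-column
#' narrowPeak input, columns 7-10 are kept as signalValue, pValue, qValue and
#' peak. Records with start >= end are rejected; the number rejected is
#' available as `attr(x, "n_rejected")` and reported in a warning.
#'
#' @param path path to a tab-separated BED3+/narrowPeak file.
#' @return data.frame with chrom, start, end and any optional columns.
#' @export
read_intervals <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) stop("BED record with fewer than 3 columns: line ", which(nf < 3L)[1])
  k <- min(nf)
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end   = as.integer(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (k >= 4L) out$name <- vapply(fields, `[[`, "", 4L)
  if (k >= 5L) out$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  if (k >= 6L) out$strand <- vapply(fields, `[[`, "", 6L)
  if (k >= 10L) {
    out$signalValue <- as.numeric(vapply(fields, `[[`, "", 7L))
    out$pValue <- as.numeric(vapply(fields, `[[`, "", 8L))
    out$qValue <- as.numeric(vapply(fields, `[[`, "", 9L))
    out$peak <- as.integer(vapply(fields, `[[`, "", 10L))
  }
  bad <- out$start >= out$end
  if (any(bad)) warning(sum(bad), " record(s) with start >= end rejected")
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write intervals as BED
#'
#' @param x data.frame with chrom, start, end and optional name/score/strand.
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  order_cols <- c("chrom", "start", "end", "name", "score", "strand",
                  "signalValue", "pValue", "qValue", "peak")
  ## BED columns are positional: stop at the first absent one
  absent <- which(!(order_cols %in% names(x)))
  k <- if (length(absent)) absent[1] - 1L else length(order_cols)
  cols <- order_cols[seq_len(k)]
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert an interval data.frame to GRanges
#'
#' Internal half-open coordinates map to GRanges 1-based closed ranges.
#' @param x data.frame with chrom, start, end (+ optional strand).
#' @return a `GRanges`.
#' @export
as_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if ("strand" %in% names(x)) {
    st <- x$strand
    st[!st %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- st
  }
  gr
}

## ---------------------------------------------------------------------------
## MEME motif format
## ---------------------------------------------------------------------------

#' Read position weight matrices in MEME motif format
#'
#' Expects a MEME text header with alphabet ACGT and one or more MOTIF blocks
#' each followed by a letter-probability matrix. Rows whose sum differs from
#' 1 by at most 1e-3 are renormalized; larger deviations are a format error.
#'
#' @param path path to a MEME motif file.
#' @return list of PWMs; each a list with motif_id, tf_name, probs (L x 4
#'   matrix, columns A,C,G,T) and background (length-4 probability vector).
#' @export
read_pwms <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    v <- as.numeric(toks[c(2, 4, 6, 8)])
    names(v) <- toks[c(1, 3, 5, 7)]
    bg <- v[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks found in ", path)
  pwms <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    toks <- strsplit(trimws(lines[starts[m]]), "\\s+")[[1]]
    motif_id <- toks[2]
    tf_name <- if (length(toks) >= 3) toks[3] else toks[2]
    i <- starts[m] + 1L
    while (i <= length(lines) && !grepl("letter-probability", lines[i])) i <- i + 1L
    if (i > length(lines)) stop("MOTIF ", motif_id, " has no letter-probability matrix")
    rows <- list(); i <- i + 1L
    while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1L
    }
    probs <- do.call(rbind, rows)
    if (is.null(probs) || ncol(probs) != 4L) stop("MOTIF ", motif_id, ": bad probability matrix")
    rs <- rowSums(probs)
    if (any(abs(rs - 1) > 1e-3)) {
      stop("MOTIF ", motif_id, ": probability row sums deviate from 1 by more than 1e-3")
    }
    probs <- probs / rs
    colnames(probs) <- c("A", "C", "G", "T")
    pwms[[m]] <- list(motif_id = motif_id, tf_name = tf_name,
                      probs = probs, background = bg)
  }
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  pwms
}

#' Write PWMs in MEME motif format
#' @param pwms list of PWMs as from [read_pwms()].
#' @param path output path.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$motif_id, p$tf_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", nrow(p$probs)), con)
    for (i in seq_len(nrow(p$probs)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p$probs[i, 1], p$probs[i, 2],
                         p$probs[i, 3], p$probs[i, 4]), con)
    writeLines("", con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## GMT gene sets
## ---------------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Each line is set name, description, then member gene ids. Duplicate genes
#' within a set are deduplicated; duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) stop("GMT line with fewer than 3 fields: line ", which(nf < 3L)[1])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write gene sets as GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Count matrix + sample metadata
## ---------------------------------------------------------------------------

#' Read a count matrix with sample metadata
#'
#' Counts are a TSV with gene ids in the first column and one column per
#' sample; metadata is a TSV with columns sample, time_point, replicate and
#' optionally batch. Counts must be non-negative integers and every sample
#' in the count header must have metadata.
#'
#' @param counts_path path to the count TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return a `count_matrix`: list with `counts` (integer matrix, genes x
#'   samples) and `meta` (data.frame, one row per sample, same order).
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  missing <- setdiff(colnames(m), meta$sample)
  if (length(missing)) stop("sample(s) missing from metadata: ",
                            paste(missing, collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  rownames(meta) <- meta$sample
  count_matrix(m, meta)
}

#' Construct a count_matrix object
#' @param counts integer matrix, genes as rows, samples as columns.
#' @param meta data.frame with columns sample, time_point, replicate
#'   (optionally batch), one row per column of `counts`, same order.
#' @return a `count_matrix` list.
#' @export
count_matrix <- function(counts, meta) {
  stopifnot(ncol(counts) == nrow(meta), all(colnames(counts) == meta$sample))
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' Write a count matrix and its metadata as TSVs
#' @param cm a `count_matrix`.
#' @param counts_path,meta_path output paths.
#' @export
write_counts <- function(cm, counts_path, meta_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

## ---------------------------------------------------------------------------
## Small reporting helpers
## ---------------------------------------------------------------------------

#' Report a count fraction with its printed percentage
#'
#' @param numerator,denominator counts.
#' @param digits decimal places of the percentage (default 0, matching the
#'   integer percentages used in Venn and overlap summaries).
#' @return list with fraction, percent (numeric) and label ("60% (62250/103989)").
#' @export
fraction_report <- function(numerator, denominator, digits = 0) {
  stopifnot(denominator > 0, numerator >= 0, numerator <= denominator)
  frac <- numerator / denominator
  pct <- round(100 * frac, digits)
  list(fraction = frac, percent = pct,
       label = sprintf("%s%% (%d/%d)", format(pct), numerator, denominator))
}
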