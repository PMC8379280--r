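## Shared fixture builders: everything is generated in code at test time.

## near-consensus PWM for a word, 94% weight on the consensus base
mk_cons_pwm <- function(word, id, tf = id, consensus_weight = 0.94) {
  L <- nchar(word)
  base <- c(A = 1, C = 2, G = 3, T = 4)
  p <- matrix((1 - consensus_weight) / 3, L, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(L)) p[i, base[[substr(word, i, i)]]] <- consensus_weight
  list(motif_id = id, tf_name = tf, probs = p / rowSums(p),
       background = rep(0.25, 4))
}

rand_seqs <- function(n, len, prefix = "s") {
  s <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  names(s) <- paste0(prefix, seq_len(n))
  s
}

## minimal GTF text for one or more genes
write_toy_gtf <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    at <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                  r$id, r$name, r$type)
    paste(r$chrom, "src", r$feature, r$start, r$end, ".", r$strand, ".", at,
          sep = "\t")
  }, "")
  writeLines(lines, path)
  path
}

## brute-force BH oracle: direct step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## brute-force hypergeometric upper tail by direct enumeration of draws
hyper_oracle <- function(x, K, n, M) {
  draws <- combn(M, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= x)
}

## adjusted Rand index (contingency-table form)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
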