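# Brute-force oracles, deliberately independent of the package internals:
# everything here works base-by-base or pair-by-pair.

bf_merged_exon_length <- function(starts, ends) {
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

bf_overlaps_any <- function(qs, qe, ss, se) {
  vapply(seq_along(qs), function(i)
    any(qs[i] <= se & qe[i] >= ss), TRUE)
}

# per-base run scan with gap merging
bf_segment <- function(pos_covered, merge_dist) {
  pos <- sort(unique(pos_covered))
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  brk <- which(diff(pos) - 1 >= merge_dist)
  start <- pos[c(1, brk + 1)]
  end <- pos[c(brk, length(pos))]
  data.frame(start = start, end = end)
}

bf_nearest <- function(ls, le, gs, ge, gid) {
  d <- pmax(0, pmax(gs - le - 1, ls - ge - 1))
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[order(gs[best], gid[best])][1]
  list(gene = gid[best], distance = d[best])
}

bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

bf_revcomp <- function(s)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

bf_pwm_hits <- function(seq, mat, bg, thr) {
  L <- ncol(mat)
  n <- nchar(seq)
  S <- log2(mat / bg)
  score1 <- function(s, w) {
    b <- strsplit(w, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(S[cbind(match(b, c("A", "C", "G", "T")), seq_len(L))])
  }
  out <- list()
  for (i in seq_len(max(0, n - L + 1))) {
    w <- substr(seq, i, i + L - 1)
    sf <- score1(S, w)
    sr <- score1(S, bf_revcomp(w))
    if (is.finite(sf) && sf >= thr)
      out[[length(out) + 1]] <- data.frame(pos = i, strand = "+",
                                           score = sf)
    if (is.finite(sr) && sr >= thr)
      out[[length(out) + 1]] <- data.frame(pos = i, strand = "-",
                                           score = sr)
  }
  if (!length(out)) return(data.frame(pos = integer(), strand = character(),
                                      score = numeric()))
  do.call(rbind, out)
}

bf_max_window_count <- function(pos, window) {
  pos <- sort(pos)
  max(vapply(pos, function(p) sum(pos >= p & pos <= p + window - 1), 1L))
}

# tiny annotation: genes given as list(gene_id=, chrom=, strand=, biotype=,
# exons=matrix with start/end columns)
tiny_ann <- function(genes, chrom_sizes = NULL) {
  gdf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               strand = if (is.null(g$strand)) "+" else g$strand,
               biotype = if (is.null(g$biotype)) "protein_coding" else
                 g$biotype, stringsAsFactors = FALSE)))
  edf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = g$exons[, 1], end = g$exons[, 2],
               stringsAsFactors = FALSE)))
  genome_annotation(gdf, edf, chrom_sizes = chrom_sizes)
}

random_gene_models <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1)
    s <- sort(sample(1:2000, k))
    w <- sample(1:300, k, replace = TRUE)
    list(gene_id = sprintf("g%04d", i), chrom = "chr1",
         exons = cbind(s, s + w))
  })
}

random_block_map <- function(seed) {
  set.seed(seed)
  nb <- sample(2:6, 1)
  src_start <- cumsum(sample(50:200, nb)) + (0:(nb - 1)) * 500
  w <- sample(100:400, nb, replace = TRUE)
  ds <- cumsum(sample(1000:2000, nb))
  block_map(data.frame(
    src_chrom = "s1", src_start = src_start, src_end = src_start + w - 1,
    dst_chrom = "d1", dst_start = ds, dst_end = ds + w - 1,
    dst_strand = sample(c("+", "-"), nb, replace = TRUE),
    stringsAsFactors = FALSE), src_genome = "s", dst_genome = "d")
}
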