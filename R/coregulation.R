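#' Nearest protein-coding gene per lncRNA
#'
#' Distance is the minimal gap in bp between the lncRNA interval and the
#' gene-body span (first exon start to last exon end), 0 when they overlap
#' (e.g. intronic lncRNAs and their host). Ties go to the gene with the
#' smaller span start, then lexicographically smaller gene_id. Strand is
#' ignored. lncRNAs on chromosomes without any protein-coding gene are
#' dropped with a warning.
#'
#' @param lnc data.frame chrom, start, end and optionally lnc_id.
#' @param ann `genome_annotation`.
#' @return data.frame lnc_id, gene_id, distance.
#' @export
nearest_gene <- function(lnc, ann) {
  spans <- gene_spans(ann, biotype = "protein_coding")
  ids <- if (!is.null(lnc$lnc_id)) lnc$lnc_id else
    paste0(lnc$chrom, ":", lnc$start, "-", lnc$end)
  res <- vector("list", nrow(lnc))
  dropped <- 0L
  for (i in seq_len(nrow(lnc))) {
    g <- spans[spans$chrom == lnc$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) { dropped <- dropped + 1L; next }
    d <- pmax(0, pmax(g$start - lnc$end[i] - 1, lnc$start[i] - g$end - 1))
    best <- which(d == min(d))
    if (length(best) > 1) {
      best <- best[order(g$start[best], g$gene_id[best])][1]
    }
    res[[i]] <- data.frame(lnc_id = ids[i], gene_id = g$gene_id[best],
                           distance = d[best], stringsAsFactors = FALSE)
  }
  if (dropped)
    warning(dropped, " lncRNA(s) on chromosomes without protein-coding ",
            "genes dropped")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(lnc_id = character(), gene_id = character(),
                      distance = numeric())
  rownames(out) <- NULL
  out
}

#' Beta/alpha expression log-ratios for neighbor pairs
#'
#' Attaches log2((beta RPKM + eps) / (alpha RPKM + eps)) for both members of
#' each lncRNA/nearest-gene pair.
#'
#' @param pairs data.frame from [nearest_gene()].
#' @param lnc_alpha,lnc_beta named replicate-mean RPKM vectors keyed by
#'   lnc_id.
#' @param gene_alpha,gene_beta named replicate-mean RPKM vectors keyed by
#'   gene_id.
#' @param eps RPKM pseudocount (default 0.1).
#' @return `pairs` with `lnc_log_ratio` and `gene_log_ratio` columns.
#' @export
neighbor_log_ratios <- function(pairs, lnc_alpha, lnc_beta, gene_alpha,
                                gene_beta, eps = 0.1) {
  lr <- function(b, a) log2((b + eps) / (a + eps))
  pairs$lnc_log_ratio <- lr(unname(lnc_beta[pairs$lnc_id]),
                            unname(lnc_alpha[pairs$lnc_id]))
  pairs$gene_log_ratio <- lr(unname(gene_beta[pairs$gene_id]),
                             unname(gene_alpha[pairs$gene_id]))
  pairs
}

#' lncRNA / nearest-gene co-regulation
#'
#' Spearman correlation of the beta/alpha log-expression ratios of lncRNAs
#' and their nearest protein-coding genes, with a two-sided p-value.
#'
#' @param pairs data.frame with finite `lnc_log_ratio` and `gene_log_ratio`
#'   (see [neighbor_log_ratios()]); at least 10 such pairs required.
#' @return list rho, p_value, n.
#' @export
coreg_correlation <- function(pairs) {
  ok <- is.finite(pairs$lnc_log_ratio) & is.finite(pairs$gene_log_ratio)
  if (sum(ok) < 10)
    stop("need >= 10 pairs with finite log-ratios (got ", sum(ok), ")")
  ct <- suppressWarnings(stats::cor.test(pairs$lnc_log_ratio[ok],
                                         pairs$gene_log_ratio[ok],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
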