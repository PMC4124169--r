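#' Cross-species calling configuration
#'
#' Thresholds for the common beta-cell transcriptome and the unique/enriched
#' classification: RPKM > 1 defines detectable expression, the species call
#' requires > 10-fold difference together with p < 1e-7 and q < 0.1%.
#'
#' @param rpkm_core_threshold detectable-expression RPKM gate (strict >).
#' @param fold_threshold fold-difference gate (strict >).
#' @param p_threshold,fdr_threshold significance gates.
#' @export
species_call_config <- function(rpkm_core_threshold = 1, fold_threshold = 10,
                                p_threshold = 1e-7, fdr_threshold = 1e-3) {
  stopifnot(rpkm_core_threshold > 0, fold_threshold > 0,
            p_threshold > 0, fdr_threshold > 0)
  structure(list(rpkm_core_threshold = rpkm_core_threshold,
                 fold_threshold = fold_threshold,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold),
            class = "species_call_config")
}

.pair_rpkm <- function(rpkm, ids, what) {
  v <- rpkm[ids]
  if (anyNA(v))
    stop("missing RPKM for ", sum(is.na(v)), " ", what, " gene(s), e.g. ",
         paste(utils::head(ids[is.na(v)], 5), collapse = ", "))
  unname(v)
}

#' Common beta-cell transcriptome across species
#'
#' Ortholog pairs whose replicate-mean beta-cell RPKM exceeds the threshold
#' (strict >) in BOTH species.
#'
#' @param rpkm_sp1,rpkm_sp2 named vectors of replicate-mean beta RPKM keyed
#'   by each species' gene ids (see [mean_rpkm()]).
#' @param pairs one-to-one ortholog table (`src_gene_id` = species 1,
#'   `dst_gene_id` = species 2); see [one_to_one_orthologs()].
#' @param cfg a [species_call_config()].
#' @return data.frame src_gene_id, dst_gene_id, rpkm_sp1, rpkm_sp2 for pairs
#'   in the core; pairs lacking RPKM in either species are excluded with a
#'   message.
#' @export
common_core <- function(rpkm_sp1, rpkm_sp2, pairs,
                        cfg = species_call_config()) {
  known <- pairs$src_gene_id %in% names(rpkm_sp1) &
    pairs$dst_gene_id %in% names(rpkm_sp2)
  if (any(!known))
    message(sum(!known), " ortholog pair(s) without expression data excluded")
  pairs <- pairs[known, , drop = FALSE]
  r1 <- unname(rpkm_sp1[pairs$src_gene_id])
  r2 <- unname(rpkm_sp2[pairs$dst_gene_id])
  keep <- r1 > cfg$rpkm_core_threshold & r2 > cfg$rpkm_core_threshold
  out <- data.frame(src_gene_id = pairs$src_gene_id[keep],
                    dst_gene_id = pairs$dst_gene_id[keep],
                    rpkm_sp1 = r1[keep], rpkm_sp2 = r2[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$src_gene_id, method = "radix"), , drop = FALSE]
}

#' Cross-species differential expression on ortholog pairs
#'
#' Builds a paired count matrix (one row per one-to-one ortholog pair,
#' columns = species-1 beta replicates then species-2 beta replicates) and
#' tests species as the grouping factor with [nb_test()]. Positive log2 folds
#' mean higher in species 1.
#'
#' @param counts_sp1,counts_sp2 beta-cell count matrices keyed by each
#'   species' gene ids.
#' @param pairs one-to-one ortholog table.
#' @param cfg a [de_config()].
#' @return `de_result` whose gene_id column holds the species-1 member of
#'   each pair.
#' @export
xspecies_de <- function(counts_sp1, counts_sp2, pairs, cfg = de_config()) {
  keep <- pairs$src_gene_id %in% rownames(counts_sp1) &
    pairs$dst_gene_id %in% rownames(counts_sp2)
  pairs <- pairs[keep, , drop = FALSE]
  m <- cbind(counts_sp1[pairs$src_gene_id, , drop = FALSE],
             counts_sp2[pairs$dst_gene_id, , drop = FALSE])
  rownames(m) <- pairs$src_gene_id
  groups <- factor(rep(c("sp1", "sp2"),
                       c(ncol(counts_sp1), ncol(counts_sp2))),
                   levels = c("sp1", "sp2"))
  nb_test(m, groups, cfg)
}

#' Classify ortholog pairs as species-unique / species-enriched
#'
#' A pair is on the species-1 side when its fold exceeds `fold_threshold`
#' toward species 1 with p and q below the gates; within a side, "unique"
#' when the other species' beta RPKM is below the detectable threshold,
#' otherwise "enriched". Pairs detectable in both species (RPKM above the
#' threshold on both sides) with no significant difference are "shared";
#' everything else (including significant pairs failing the fold gate) is
#' "ns".
#'
#' @param rpkm_sp1,rpkm_sp2 named replicate-mean beta RPKM vectors.
#' @param de a `de_result` from [xspecies_de()] (gene_id = species-1 member;
#'   positive folds toward species 1).
#' @param pairs one-to-one ortholog table.
#' @param cfg a [species_call_config()].
#' @param species_names length-2 labels used in the call strings.
#' @return data.frame src_gene_id, dst_gene_id, rpkm_sp1, rpkm_sp2,
#'   log2_fold, p_value, q_value, call.
#' @export
classify_specificity <- function(rpkm_sp1, rpkm_sp2, de, pairs,
                                 cfg = species_call_config(),
                                 species_names = c("sp1", "sp2")) {
  i <- match(pairs$src_gene_id, de$gene_id)
  pairs <- pairs[!is.na(i), , drop = FALSE]
  de <- de[i[!is.na(i)], , drop = FALSE]
  r1 <- .pair_rpkm(rpkm_sp1, pairs$src_gene_id, species_names[1])
  r2 <- .pair_rpkm(rpkm_sp2, pairs$dst_gene_id, species_names[2])
  lf_gate <- log2(cfg$fold_threshold)
  sig <- !is.na(de$p_value) & de$p_value < cfg$p_threshold &
    de$q_value < cfg$fdr_threshold
  side1 <- sig & de$log2_fold > lf_gate
  side2 <- sig & de$log2_fold < -lf_gate
  thr <- cfg$rpkm_core_threshold
  call <- rep("ns", nrow(pairs))
  call[side1] <- ifelse(r2[side1] < thr,
                        paste0(species_names[1], "_unique"),
                        paste0(species_names[1], "_enriched"))
  call[side2] <- ifelse(r1[side2] < thr,
                        paste0(species_names[2], "_unique"),
                        paste0(species_names[2], "_enriched"))
  call[!sig & r1 > thr & r2 > thr] <- "shared"
  out <- data.frame(src_gene_id = pairs$src_gene_id,
                    dst_gene_id = pairs$dst_gene_id,
                    rpkm_sp1 = r1, rpkm_sp2 = r2,
                    log2_fold = de$log2_fold, p_value = de$p_value,
                    q_value = de$q_value, call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$src_gene_id, method = "radix"), , drop = FALSE]
}

#' Species-specific TF peaks on a common genome
#'
#' Converts species-2 peaks onto the species-1 genome through a block map,
#' unions all peak intervals into common regions, sums per-million-normalized
#' reads per region for each species, and calls a region species-specific
#' when the normalized read ratio (pseudocount added) is at least
#' `ratio_threshold` (>= 4-fold, boundary inclusive).
#'
#' @param peaks_sp1 data.frame chrom, start, end, reads on the species-1
#'   genome.
#' @param peaks_sp2 same on the species-2 genome.
#' @param map `block_map` from species 2 to species 1.
#' @param ratio_threshold differential-binding ratio (default 4).
#' @param pseudocount added to both normalized totals before the ratio.
#' @param species_names length-2 labels used in call strings.
#' @return list with `regions` (chrom, start, end, reads_sp1, reads_sp2,
#'   ratio, call in sp1_specific/sp2_specific/shared) and `unmapped`
#'   (species-2 peaks that failed conversion).
#' @export
species_specific_peaks <- function(peaks_sp1, peaks_sp2, map,
                                   ratio_threshold = 4, pseudocount = 1,
                                   species_names = c("sp1", "sp2")) {
  norm1 <- peaks_sp1$reads / (sum(peaks_sp1$reads) / 1e6)
  norm2 <- peaks_sp2$reads / (sum(peaks_sp2$reads) / 1e6)
  conv <- convert_intervals(peaks_sp2, map)
  mapped <- conv$mapped
  unmapped <- peaks_sp2[!mapped, , drop = FALSE]
  conv <- conv[mapped, , drop = FALSE]
  norm2_mapped <- norm2[mapped]
  gr1 <- GenomicRanges::GRanges(peaks_sp1$chrom,
                                IRanges::IRanges(peaks_sp1$start,
                                                 peaks_sp1$end))
  gr2 <- GenomicRanges::GRanges(conv$chrom,
                                IRanges::IRanges(conv$start, conv$end))
  regions <- GenomicRanges::reduce(c(gr1, gr2))
  ov1 <- GenomicRanges::findOverlaps(gr1, regions)
  ov2 <- GenomicRanges::findOverlaps(gr2, regions)
  n <- length(regions)
  r1 <- r2 <- rep(0, n)
  a1 <- tapply(norm1[S4Vectors::queryHits(ov1)],
               S4Vectors::subjectHits(ov1), sum)
  r1[as.integer(names(a1))] <- as.numeric(a1)
  a2 <- tapply(norm2_mapped[S4Vectors::queryHits(ov2)],
               S4Vectors::subjectHits(ov2), sum)
  r2[as.integer(names(a2))] <- as.numeric(a2)
  ratio <- (r1 + pseudocount) / (r2 + pseudocount)
  call <- rep("shared", n)
  call[ratio >= ratio_threshold] <- paste0(species_names[1], "_specific")
  call[1 / ratio >= ratio_threshold] <- paste0(species_names[2], "_specific")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                    start = GenomicRanges::start(regions),
                    end = GenomicRanges::end(regions),
                    reads_sp1 = r1, reads_sp2 = r2, ratio = ratio,
                    call = call, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  list(regions = out, unmapped = unmapped)
}
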