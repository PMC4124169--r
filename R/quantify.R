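#' RPKM from a count table
#'
#' Reads per kilobase of exon model per million mapped reads. The exon model
#' length is the union of a gene's exons; the per-sample denominator defaults
#' to the column total of the count table (exon-assigned reads), overridable
#' when a library's full mapped-read total is known.
#'
#' @param counts matrix (genes x samples) with gene rownames, or a count TSV
#'   path.
#' @param ann a `genome_annotation` covering every gene in `counts`.
#' @param mapped_total optional named per-sample totals (> 0); default
#'   `colSums(counts)`.
#' @return long data.frame: gene_id, sample, count, rpkm.
#' @export
compute_rpkm <- function(counts, ann, mapped_total = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  unknown <- setdiff(rownames(counts), ann$genes$gene_id)
  if (length(unknown))
    stop("gene_id(s) absent from annotation: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) sprintf(" (+%d more)", length(unknown) - 10))
  if (is.null(mapped_total)) mapped_total <- colSums(counts)
  if (is.null(names(mapped_total)) && length(mapped_total) == ncol(counts))
    names(mapped_total) <- colnames(counts)
  mapped_total <- mapped_total[colnames(counts)]
  if (anyNA(mapped_total) || any(mapped_total <= 0))
    stop("mapped_total must be > 0 for every sample")
  len_kb <- merged_exon_length(ann, rownames(counts)) / 1000
  rpkm <- sweep(counts / len_kb, 2, mapped_total / 1e6, "/")
  data.frame(
    gene_id = rep(rownames(counts), times = ncol(counts)),
    sample = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts),
    rpkm = as.vector(rpkm),
    stringsAsFactors = FALSE)
}

#' Replicate-mean RPKM per gene
#'
#' @param rpkm_long output of [compute_rpkm()].
#' @param samples samples to average over (default all).
#' @return named numeric vector keyed by gene_id.
#' @export
mean_rpkm <- function(rpkm_long, samples = NULL) {
  if (!is.null(samples)) rpkm_long <- rpkm_long[rpkm_long$sample %in% samples, ]
  out <- tapply(rpkm_long$rpkm, rpkm_long$gene_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Per-gene fraction of mapped reads
#'
#' The share of each sample's reads attributed to each gene, e.g. insulin
#' transcripts holding 13% of all beta-cell reads.
#'
#' @param counts matrix (genes x samples).
#' @param average logical: also report the replicate-mean fraction per gene.
#' @return long data.frame gene_id, sample, count, fraction; with
#'   `average = TRUE` a data.frame gene_id, mean_fraction.
#' @export
read_fractions <- function(counts, average = FALSE) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("per-sample totals must be > 0")
  frac <- sweep(counts, 2, totals, "/")
  if (average) {
    return(data.frame(gene_id = rownames(counts),
                      mean_fraction = rowMeans(frac),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  data.frame(gene_id = rep(rownames(counts), times = ncol(counts)),
             sample = rep(colnames(counts), each = nrow(counts)),
             count = as.vector(counts),
             fraction = as.vector(frac),
             stringsAsFactors = FALSE)
}

#' RPKM of arbitrary intervals from a coverage track
#'
#' Estimates read counts over each interval as (sum of per-base coverage) /
#' read length, then applies the RPKM formula. Used to attach population
#' expression to segmented transcript candidates.
#'
#' @param intervals data.frame chrom, start, end (1-based closed).
#' @param cov coverage track (data.frame chrom, start, end, score, 1-based
#'   closed, as from [read_bedgraph()]).
#' @param mapped_total library size (mapped reads) for the track.
#' @param read_length read length in bp used to turn base-coverage into reads.
#' @return numeric vector of RPKM values, one per interval row.
#' @export
interval_rpkm <- function(intervals, cov, mapped_total, read_length = 100) {
  stopifnot(mapped_total > 0, read_length > 0)
  qi <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start, intervals$end))
  ci <- GenomicRanges::GRanges(cov$chrom, IRanges::IRanges(cov$start, cov$end))
  ov <- GenomicRanges::findOverlaps(qi, ci)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qi)[S4Vectors::queryHits(ov)],
    IRanges::ranges(ci)[S4Vectors::subjectHits(ov)]))
  base_cov <- w * cov$score[S4Vectors::subjectHits(ov)]
  tot <- rep(0, nrow(intervals))
  agg <- tapply(base_cov, S4Vectors::queryHits(ov), sum)
  tot[as.integer(names(agg))] <- as.numeric(agg)
  reads <- tot / read_length
  len_kb <- (intervals$end - intervals$start + 1) / 1000
  reads / (len_kb * mapped_total / 1e6)
}
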