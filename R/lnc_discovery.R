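#' lncRNA filter configuration
#'
#' The five rules a candidate must clear: no exon overlap, length strictly
#' over 3 kb, replicate-mean RPKM > 1 in alpha OR beta cells, no rRNA-locus
#' overlap, and mean conservation not above 0.4 (strictly greater fails).
#' `merge_dist` is the segmentation merge distance (runs separated by gaps
#' shorter than 1500 bp are joined); `min_coverage` the read-density floor
#' defining a run.
#'
#' @param min_length bp, strict > to pass.
#' @param min_rpkm RPKM gate, strict > in either population.
#' @param max_phastcon conservation gate; fail iff mean > this.
#' @param merge_dist bp; gaps < merge_dist are merged, >= split.
#' @param min_coverage combined per-base read density defining a run.
#' @export
lnc_filter_config <- function(min_length = 3000, min_rpkm = 1,
                              max_phastcon = 0.4, merge_dist = 1500,
                              min_coverage = 2) {
  stopifnot(min_length > 0, min_rpkm > 0, max_phastcon > 0, merge_dist > 0,
            min_coverage > 0)
  structure(list(min_length = min_length, min_rpkm = min_rpkm,
                 max_phastcon = max_phastcon, merge_dist = merge_dist,
                 min_coverage = min_coverage), class = "lnc_filter_config")
}

#' Segment a coverage track into candidate transcripts
#'
#' Maximal runs of per-base coverage at or above `min_coverage`; runs on the
#' same chromosome separated by gaps shorter than `merge_dist` are merged
#' (a 1499 bp gap joins, a 1500 bp gap splits).
#'
#' @param cov coverage track: data.frame chrom, start, end, score, 1-based
#'   closed (see [read_bedgraph()]); intervals need not be sorted.
#' @param cfg a [lnc_filter_config()].
#' @return data.frame chrom, start, end sorted by chrom then start.
#' @export
segment_coverage <- function(cov, cfg = lnc_filter_config()) {
  cov <- cov[cov$score >= cfg$min_coverage, , drop = FALSE]
  if (nrow(cov) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(cov$chrom,
                               IRanges::IRanges(cov$start, cov$end))
  # reduce with min.gapwidth merges gaps strictly smaller than merge_dist
  red <- GenomicRanges::reduce(gr, min.gapwidth = cfg$merge_dist)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
}

.overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start, query$end))
  s <- GenomicRanges::GRanges(subject$chrom,
                              IRanges::IRanges(subject$start, subject$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Mean conservation score over intervals
#'
#' Base-weighted mean of a PhastCons-like track over each interval; an
#' interval with no overlapping track data is an error.
#'
#' @param intervals data.frame chrom, start, end (1-based closed).
#' @param cons conservation track: data.frame chrom, start, end, score.
#' @return numeric vector of means in `[0, 1]`.
#' @export
conservation_mean <- function(intervals, cons) {
  qi <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  ci <- GenomicRanges::GRanges(cons$chrom,
                               IRanges::IRanges(cons$start, cons$end))
  ov <- GenomicRanges::findOverlaps(qi, ci)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qi)[S4Vectors::queryHits(ov)],
    IRanges::ranges(ci)[S4Vectors::subjectHits(ov)]))
  sc <- cons$score[S4Vectors::subjectHits(ov)]
  num <- den <- rep(0, nrow(intervals))
  an <- tapply(w * sc, S4Vectors::queryHits(ov), sum)
  ad <- tapply(w, S4Vectors::queryHits(ov), sum)
  num[as.integer(names(an))] <- as.numeric(an)
  den[as.integer(names(ad))] <- as.numeric(ad)
  if (any(den == 0))
    stop("no conservation data for ", sum(den == 0), " candidate(s), e.g. ",
         paste(utils::head(paste0(intervals$chrom, ":", intervals$start, "-",
                                  intervals$end)[den == 0], 3),
               collapse = ", "))
  num / den
}

#' Apply the five lncRNA filters to candidate intervals
#'
#' Every rule is evaluated for every candidate (no short-circuiting) so the
#' filter trace records exactly which rules a rejected candidate violates.
#' Rule order: exon overlap, length, RPKM, rRNA overlap, conservation.
#'
#' @param cands candidate intervals (data.frame chrom, start, end), e.g.
#'   from [segment_coverage()].
#' @param ann `genome_annotation`; any >= 1 bp overlap with any gene exon
#'   fails the exon rule (strand ignored).
#' @param rrna rRNA loci (data.frame chrom, start, end, e.g. [read_bed()]).
#' @param cons conservation track for [conservation_mean()].
#' @param alpha_rpkm,beta_rpkm replicate-mean RPKM per candidate (vectors
#'   matching `cands` rows; see [interval_rpkm()]).
#' @param cfg a [lnc_filter_config()].
#' @return data.frame: chrom, start, end, length, alpha_rpkm, beta_rpkm,
#'   conservation_mean, pass_exon, pass_length, pass_rpkm, pass_rrna,
#'   pass_conservation, filter_trace (ordered "rule:pass/fail" string),
#'   survives.
#' @export
apply_lnc_filters <- function(cands, ann, rrna, cons, alpha_rpkm, beta_rpkm,
                              cfg = lnc_filter_config()) {
  stopifnot(length(alpha_rpkm) == nrow(cands),
            length(beta_rpkm) == nrow(cands))
  len <- cands$end - cands$start + 1
  pass_exon <- !.overlaps_any(cands, ann$exons)
  pass_length <- len > cfg$min_length
  pass_rpkm <- alpha_rpkm > cfg$min_rpkm | beta_rpkm > cfg$min_rpkm
  pass_rrna <- !.overlaps_any(cands, rrna)
  cmean <- conservation_mean(cands, cons)
  pass_cons <- !(cmean > cfg$max_phastcon)
  pf <- function(x) ifelse(x, "pass", "fail")
  trace <- paste0("exon_overlap:", pf(pass_exon), ";length:", pf(pass_length),
                  ";rpkm:", pf(pass_rpkm), ";rrna:", pf(pass_rrna),
                  ";conservation:", pf(pass_cons))
  out <- data.frame(chrom = cands$chrom, start = cands$start,
                    end = cands$end, length = len,
                    alpha_rpkm = alpha_rpkm, beta_rpkm = beta_rpkm,
                    conservation_mean = cmean,
                    pass_exon = pass_exon, pass_length = pass_length,
                    pass_rpkm = pass_rpkm, pass_rrna = pass_rrna,
                    pass_conservation = pass_cons,
                    filter_trace = trace,
                    survives = pass_exon & pass_length & pass_rpkm &
                      pass_rrna & pass_cons,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
}

#' Classify surviving transcripts as intronic or intergenic
#'
#' Intronic when the interval lies fully within the gene-body span (first
#' exon start to last exon end) of at least one protein-coding gene;
#' intergenic otherwise. Survivors are non-exonic by construction, so
#' containment in a gene body means containment in introns.
#'
#' @param survivors data.frame chrom, start, end.
#' @param ann `genome_annotation`.
#' @return character vector `"intronic"`/`"intergenic"` per row.
#' @export
classify_position <- function(survivors, ann) {
  spans <- gene_spans(ann, biotype = "protein_coding")
  if (nrow(spans) == 0 || nrow(survivors) == 0)
    return(rep("intergenic", nrow(survivors)))
  q <- GenomicRanges::GRanges(survivors$chrom,
                              IRanges::IRanges(survivors$start,
                                               survivors$end))
  s <- GenomicRanges::GRanges(spans$chrom,
                              IRanges::IRanges(spans$start, spans$end))
  within <- GenomicRanges::countOverlaps(q, s, type = "within") > 0
  ifelse(within, "intronic", "intergenic")
}

#' Discover novel lncRNAs from coverage tracks
#'
#' End-to-end discovery: segments the combined alpha+beta coverage
#' meta-experiment, attaches per-population RPKM, applies the five filters,
#' and classifies survivors as intronic or intergenic.
#'
#' @param cov_alpha,cov_beta per-population coverage tracks (1-based closed).
#' @param ann `genome_annotation`.
#' @param rrna rRNA loci data.frame.
#' @param cons conservation track.
#' @param mapped_totals named list/vector with elements `alpha` and `beta`:
#'   mapped reads per population used for RPKM.
#' @param cfg a [lnc_filter_config()].
#' @param read_length read length for coverage-to-reads conversion.
#' @return list: `survivors` (with `class` and `lnc_id` columns),
#'   `rejected`, and `candidates` (all segmented intervals).
#' @export
discover_lncrnas <- function(cov_alpha, cov_beta, ann, rrna, cons,
                             mapped_totals, cfg = lnc_filter_config(),
                             read_length = 100) {
  combined <- combine_coverage(cov_alpha, cov_beta)
  cands <- segment_coverage(combined, cfg)
  if (nrow(cands) == 0)
    return(list(survivors = cands, rejected = cands, candidates = cands))
  a_rpkm <- interval_rpkm(cands, cov_alpha, mapped_totals[["alpha"]],
                          read_length)
  b_rpkm <- interval_rpkm(cands, cov_beta, mapped_totals[["beta"]],
                          read_length)
  filt <- apply_lnc_filters(cands, ann, rrna, cons, a_rpkm, b_rpkm, cfg)
  surv <- filt[filt$survives, , drop = FALSE]
  if (nrow(surv)) {
    surv$class <- classify_position(surv, ann)
    surv$lnc_id <- sprintf("novel_%04d", seq_len(nrow(surv)))
  } else {
    surv$class <- character(0)
    surv$lnc_id <- character(0)
  }
  list(survivors = surv, rejected = filt[!filt$survives, , drop = FALSE],
       candidates = cands)
}

#' Sum coverage tracks base-wise
#'
#' Flattens two (or more) interval coverage tracks into disjoint intervals
#' whose score is the sum of overlapping inputs.
#'
#' @param ... coverage data.frames (chrom, start, end, score, 1-based
#'   closed).
#' @return combined coverage data.frame with disjoint intervals.
#' @export
combine_coverage <- function(...) {
  cov <- do.call(rbind, lapply(list(...), function(x)
    x[c("chrom", "start", "end", "score")]))
  gr <- GenomicRanges::GRanges(cov$chrom,
                               IRanges::IRanges(cov$start, cov$end))
  dj <- GenomicRanges::disjoin(gr)
  ov <- GenomicRanges::findOverlaps(dj, gr)
  sc <- rep(0, length(dj))
  agg <- tapply(cov$score[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), sum)
  sc[as.integer(names(agg))] <- as.numeric(agg)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(dj)),
                    start = GenomicRanges::start(dj),
                    end = GenomicRanges::end(dj), score = sc,
                    stringsAsFactors = FALSE)
  out[out$score > 0, , drop = FALSE]
}
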