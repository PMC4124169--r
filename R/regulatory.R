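#' Position weight matrix
#'
#' Per-position nucleotide probabilities of a TF binding motif, scored as
#' log2 odds against a background composition.
#'
#' @param matrix 4 x L numeric matrix of probabilities, rows A/C/G/T,
#'   columns summing to 1; L >= 4.
#' @param name motif label.
#' @param background length-4 background probabilities (A, C, G, T).
#' @param score_threshold default log2-odds hit threshold; `NULL` means
#'   80% of the maximal achievable score, computed at scan time.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                score_threshold = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4, ncol(matrix) >= 4)
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  stopifnot(identical(rownames(matrix), c("A", "C", "G", "T")))
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  stopifnot(length(background) == 4, all(background > 0))
  structure(list(matrix = matrix, name = name,
                 background = background / sum(background),
                 score_threshold = score_threshold), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[apply(x$matrix, 2, which.max)],
                collapse = "")
  cat("pwm '", x$name, "', length ", ncol(x$matrix), ", consensus ", cons,
      "\n", sep = "")
  invisible(x)
}

#' Maximal log2-odds score of a PWM
#' @param x a [pwm()].
#' @export
pwm_max_score <- function(x) {
  s <- log2(x$matrix / x$background)
  sum(apply(s, 2, max))
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned with log2-odds scoring; a window is a hit when
#' its score reaches the threshold. Windows containing N are skipped.
#' Positions are 1-based starts on the forward strand.
#'
#' @param seq character sequence over A/C/G/T/N (single string).
#' @param x a [pwm()].
#' @param threshold log2-odds threshold; default `x$score_threshold`, or 80%
#'   of [pwm_max_score()] when that is NULL.
#' @return data.frame pos, strand, score, sorted by pos.
#' @export
scan_pwm <- function(seq, x, threshold = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside A/C/G/T/N")
  if (is.null(threshold)) threshold <- x$score_threshold
  if (is.null(threshold)) threshold <- 0.8 * pwm_max_score(x)
  L <- ncol(x$matrix)
  n <- nchar(seq)
  empty <- data.frame(pos = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  S <- log2(x$matrix / x$background)
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  nw <- n - L + 1
  score_with <- function(M) {
    sc <- numeric(nw)
    ok <- rep(TRUE, nw)
    for (j in seq_len(L)) {
      b <- idx[j:(j + nw - 1)]
      ok <- ok & !is.na(b)
      v <- M[cbind(ifelse(is.na(b), 1L, b), j)]
      sc <- sc + v
    }
    sc[!ok] <- -Inf
    sc
  }
  fwd <- score_with(S)
  # reverse strand: reverse-complemented matrix scanned on the forward index
  Src <- S[c(4, 3, 2, 1), rev(seq_len(L)), drop = FALSE]
  rownames(Src) <- c("A", "C", "G", "T")
  rev <- score_with(Src)
  hf <- which(fwd >= threshold)
  hr <- which(rev >= threshold)
  out <- data.frame(pos = c(hf, hr),
                    strand = rep(c("+", "-"), c(length(hf), length(hr))),
                    score = c(fwd[hf], rev[hr]),
                    stringsAsFactors = FALSE)
  out[order(out$pos, out$strand, method = "radix"), , drop = FALSE]
}

#' Motif clusters by count-in-window statistic
#'
#' Finds maximal windows of at most `window` bp containing at least
#' `min_sites` motif hits (MCAST-style evidence of a dense cis-regulatory
#' element), merges overlapping qualifying windows, and estimates an
#' empirical p-value for the maximal within-window count by uniformly
#' shuffling hit positions over the scanned region.
#'
#' @param positions motif hit positions (bp, sorted or not).
#' @param region_length length of the scanned region (bp) for the shuffles.
#' @param window window size in bp (default 300).
#' @param min_sites minimum hits per window to call a cluster.
#' @param n_shuffle number of position shuffles for the p-value.
#' @param seed optional RNG seed.
#' @return list: `clusters` (data.frame start, end, n_sites), `max_count`
#'   (maximal hits in any window), `p_value` (with +1 correction; never 0).
#' @export
motif_cluster <- function(positions, region_length, window = 300,
                          min_sites = 2, n_shuffle = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  positions <- sort(as.numeric(positions))
  count_stat <- function(pos) {
    if (length(pos) == 0) return(integer(0))
    # hits within [pos_i, pos_i + window - 1]
    ub <- findInterval(pos + window - 1, pos)
    as.integer(ub - seq_along(pos) + 1)
  }
  counts <- count_stat(positions)
  max_count <- if (length(counts)) max(counts) else 0L
  qual <- which(counts >= min_sites)
  clusters <- data.frame(start = numeric(0), end = numeric(0),
                         n_sites = integer(0))
  if (length(qual)) {
    ub <- findInterval(positions + window - 1, positions)
    ws <- positions[qual]
    we <- positions[ub[qual]]
    # merge overlapping/adjacent qualifying windows
    ir <- IRanges::reduce(IRanges::IRanges(as.integer(ws), as.integer(we)))
    cs <- IRanges::start(ir); ce <- IRanges::end(ir)
    ns <- vapply(seq_along(cs), function(i)
      sum(positions >= cs[i] & positions <= ce[i]), 1L)
    clusters <- data.frame(start = cs, end = ce, n_sites = ns)
  }
  p <- NA_real_
  if (length(positions) && n_shuffle > 0) {
    null_max <- vapply(seq_len(n_shuffle), function(r) {
      pos <- sort(sample.int(region_length, length(positions),
                             replace = TRUE))
      max(count_stat(pos))
    }, 1L)
    p <- (1 + sum(null_max >= max_count)) / (1 + n_shuffle)
  }
  list(clusters = clusters, max_count = max_count, p_value = p)
}

#' TF-peak enrichment at transcript ends
#'
#' Observed statistic: the fraction of transcript boundaries (both the 5'
#' and 3' ends of each interval) with at least one peak within +/- `window`
#' bp. The null re-draws the same number of positions uniformly over the
#' chromosomes `n_random` times; the enrichment ratio is observed rate over
#' mean null rate and the empirical p-value uses the +1 correction.
#'
#' @param transcripts data.frame chrom, start, end.
#' @param peaks data.frame chrom, start, end.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window bp around an end (default 1000).
#' @param n_random number of null replicates (>= 100).
#' @param seed optional RNG seed.
#' @return list: observed_rate, null_rate (mean), ratio, p_value, n_ends.
#'   With zero peaks the ratio and p are NA (with a message).
#' @export
end_enrichment <- function(transcripts, peaks, chrom_sizes, window = 1000,
                           n_random = 1000, seed = NULL) {
  if (n_random < 100)
    stop("n_random must be >= 100 for a stable empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  n_ends <- 2L * nrow(transcripts)
  if (nrow(peaks) == 0) {
    message("no peaks supplied; enrichment undefined")
    return(list(observed_rate = NA_real_, null_rate = NA_real_,
                ratio = NA_real_, p_value = NA_real_, n_ends = n_ends))
  }
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(pmax(1, peaks$start - window),
                                  peaks$end + window))
  hit_rate <- function(chrom, pos) {
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    mean(GenomicRanges::countOverlaps(g, pk) > 0)
  }
  obs <- hit_rate(rep(transcripts$chrom, 2),
                  c(transcripts$start, transcripts$end))
  chroms <- names(chrom_sizes)
  # one batch of n_random x n_ends uniform positions, rates per replicate
  tot <- n_random * n_ends
  ch <- sample(chroms, tot, replace = TRUE,
               prob = chrom_sizes / sum(chrom_sizes))
  pos <- floor(stats::runif(tot, 1, chrom_sizes[ch] + 1))
  g <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::countOverlaps(g, pk) > 0
  null_rates <- rowMeans(matrix(hit, nrow = n_random, byrow = TRUE))
  ratio <- obs / mean(null_rates)
  p <- (1 + sum(null_rates >= obs)) / (1 + n_random)
  list(observed_rate = obs, null_rate = mean(null_rates), ratio = ratio,
       p_value = p, n_ends = n_ends)
}
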