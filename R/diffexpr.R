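#' Differential-expression configuration
#'
#' Thresholds and numerical settings for [nb_test()]. The default calling
#' gate (p < 1e-7 together with Benjamini-Hochberg q < 0.1%) is the stringent
#' double criterion used for the alpha/beta and cross-species comparisons.
#'
#' @param p_threshold two-sided Wald p-value gate.
#' @param fdr_threshold Benjamini-Hochberg q-value gate.
#' @param dispersion_floor lower clamp for the NB dispersion.
#' @param pseudocount added to normalized group means before the log2 fold.
#' @param dispersion_method `"trend"` (default) evaluates a mean-dispersion
#'   trend fitted across genes; `"per-gene"` uses each gene's own
#'   method-of-moments estimate.
#' @return list of class `de_config`.
#' @export
de_config <- function(p_threshold = 1e-7, fdr_threshold = 1e-3,
                      dispersion_floor = 1e-3, pseudocount = 0.5,
                      dispersion_method = c("trend", "per-gene")) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1,
            dispersion_floor > 0, pseudocount > 0)
  structure(list(p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 dispersion_floor = dispersion_floor,
                 pseudocount = pseudocount,
                 dispersion_method = match.arg(dispersion_method)),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples, restricted to genes with positive
#' counts in every sample; factors are rescaled to geometric mean 1.
#'
#' @param counts matrix (genes x samples).
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no gene has positive counts in every sample; ",
         "filter the table or check the inputs")
  f <- apply(counts[ok, , drop = FALSE], 2, function(x)
    stats::median(exp(log(x) - loggeo[ok])))
  f / exp(mean(log(f)))
}

# gene-wise method-of-moments dispersion plus a fitted mean-dispersion trend
# alpha(m) = a0 + a1/m (least squares on all finite gene-wise values).
.estimate_dispersion <- function(k, groups, method, floor) {
  lev <- levels(groups)
  m_g <- lapply(lev, function(l) rowMeans(k[, groups == l, drop = FALSE]))
  v_g <- lapply(lev, function(l) {
    kk <- k[, groups == l, drop = FALSE]
    rowSums((kk - rowMeans(kk))^2) / (ncol(kk) - 1)
  })
  w <- vapply(lev, function(l) sum(groups == l) - 1, 1)
  vres <- Reduce(`+`, Map(`*`, v_g, w)) / sum(w)
  m <- rowMeans(k)
  mom <- (vres - m) / m^2
  if (method == "per-gene") {
    alpha <- pmax(mom, floor)
    alpha[!is.finite(alpha)] <- floor
    return(list(alpha = alpha, mom = mom))
  }
  sel <- is.finite(mom) & m >= 1
  if (sum(sel) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / m[sel]), mom[sel])
    a0 <- fit$coefficients[1]; a1 <- fit$coefficients[2]
    if (!all(is.finite(c(a0, a1)))) { a0 <- mean(mom[sel]); a1 <- 0 }
  } else {
    a0 <- if (any(sel)) mean(mom[sel]) else floor
    a1 <- 0
  }
  alpha <- pmin(pmax(a0 + a1 / pmax(m, 1), floor), 100)
  list(alpha = alpha, mom = mom, trend = c(a0 = unname(a0), a1 = unname(a1)))
}

#' Negative-binomial Wald test between two groups
#'
#' Counts are normalized by median-of-ratios size factors; the NB dispersion
#' (Var = mu + alpha mu^2) is estimated from within-group variability and,
#' by default, pooled across genes through a mean-dispersion trend. The test
#' statistic is the log2 ratio of normalized group means (pseudocount added)
#' divided by its delta-method standard error; p-values are two-sided normal,
#' q-values Benjamini-Hochberg over all tested genes. Genes with zero counts
#' in every sample are excluded from testing and reported as `ns` with NA
#' statistics.
#'
#' @param counts matrix (genes x samples) with gene rownames.
#' @param groups factor of length `ncol(counts)` with two levels; the first
#'   level is "A": positive log2 folds mean higher in A.
#' @param cfg a [de_config()].
#' @return data.frame of class `de_result`: gene_id, base_mean, log2_fold,
#'   p_value, q_value, call (`A_enriched`/`B_enriched`/`ns`, prefixed by the
#'   group level names).
#' @export
nb_test <- function(counts, groups, cfg = de_config()) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2))
    stop("each group needs >= 2 replicates (no dispersion estimate otherwise)")
  if (length(groups) != ncol(counts))
    stop("groups length must match the number of samples")
  lev <- levels(groups)
  f <- size_factors(counts)
  k <- sweep(counts, 2, f, "/")
  testable <- rowSums(counts) > 0
  out <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(k),
                    log2_fold = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, call = "ns",
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(testable)) {
    kt <- k[testable, , drop = FALSE]
    disp <- .estimate_dispersion(kt, groups, cfg$dispersion_method,
                                 cfg$dispersion_floor)
    a <- disp$alpha
    cA <- groups == lev[1]; cB <- groups == lev[2]
    nA <- sum(cA); nB <- sum(cB)
    mA <- rowMeans(kt[, cA, drop = FALSE]) + cfg$pseudocount
    mB <- rowMeans(kt[, cB, drop = FALSE]) + cfg$pseudocount
    # Var(k_s / f_s) = mu/f_s + alpha mu^2 for a sample with normalized mean mu
    vA <- (mA * sum(1 / f[cA]) / nA^2 + a * mA^2 / nA) / (mA^2 * log(2)^2)
    vB <- (mB * sum(1 / f[cB]) / nB^2 + a * mB^2 / nB) / (mB^2 * log(2)^2)
    lfc <- log2(mA) - log2(mB)
    z <- lfc / sqrt(vA + vB)
    p <- 2 * stats::pnorm(-abs(z))
    q <- stats::p.adjust(p, method = "BH")
    call <- rep("ns", length(p))
    sig <- p < cfg$p_threshold & q < cfg$fdr_threshold
    call[sig & lfc > 0] <- paste0(lev[1], "_enriched")
    call[sig & lfc < 0] <- paste0(lev[2], "_enriched")
    out$log2_fold[testable] <- lfc
    out$p_value[testable] <- p
    out$q_value[testable] <- q
    out$call[testable] <- call
    attr(out, "dispersion_trend") <- disp$trend
  }
  attr(out, "size_factors") <- f
  attr(out, "groups") <- lev
  attr(out, "config") <- cfg
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  lev <- attr(x, "groups")
  cat("Negative-binomial differential expression: ", lev[1], " vs ", lev[2],
      "\n  ", nrow(x), " genes (", sum(!is.na(x$p_value)), " tested)\n",
      sep = "")
  tab <- table(x$call)
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  cfg <- attr(object, "config")
  cat("Gate: p <", format(cfg$p_threshold), "and BH q <",
      format(cfg$fdr_threshold), "\n")
  print(object)
  top <- object[order(object$p_value), ]
  top <- utils::head(top[top$call != "ns", ], 5)
  if (nrow(top)) {
    cat("  top calls:\n")
    print(top[c("gene_id", "log2_fold", "p_value", "q_value", "call")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Glucose-response ranking
#'
#' Runs [nb_test()] of stimulated (high glucose) over control (low glucose)
#' libraries across the combined coding + lncRNA transcript universe and
#' returns the table ordered by signed significance (most up-regulated
#' first), with lncRNA rows flagged.
#'
#' @param counts_low,counts_high matrices over the same transcript universe
#'   (identical rownames), >= 2 replicates each.
#' @param cfg a [de_config()].
#' @param lnc_ids transcript ids to flag as lncRNA.
#' @return data.frame: de_result columns plus `is_lnc` and `signed_score`
#'   (sign(log2 fold) x -log10 p), sorted decreasing.
#' @export
glucose_response <- function(counts_low, counts_high, cfg = de_config(),
                             lnc_ids = character()) {
  if (!identical(rownames(counts_low), rownames(counts_high)))
    stop("low and high tables must share the same transcript universe")
  counts <- cbind(counts_high, counts_low)
  groups <- factor(rep(c("high", "low"),
                       c(ncol(counts_high), ncol(counts_low))),
                   levels = c("high", "low"))
  de <- nb_test(counts, groups, cfg)
  de$is_lnc <- de$gene_id %in% lnc_ids
  de$signed_score <- sign(de$log2_fold) * -log10(pmax(de$p_value, 1e-300))
  de$signed_score[is.na(de$p_value)] <- 0
  de[order(-de$signed_score, de$gene_id, method = "radix"), , drop = FALSE]
}
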