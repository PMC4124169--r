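cov_track <- function(starts, ends, score = 10, chrom = "chr2") {
  data.frame(chrom = chrom, start = starts, end = ends, score = score,
             stringsAsFactors = FALSE)
}

test_that("segmentation merges gaps below 1500 bp and splits at 1500", {
  cfg <- lnc_filter_config()
  merged <- segment_coverage(cov_track(c(1000, 3500), c(2000, 4000)), cfg)
  expect_equal(nrow(merged), 1)  # gap 1499
  expect_equal(c(merged$start, merged$end), c(1000, 4000))
  split <- segment_coverage(cov_track(c(1000, 3501), c(2000, 4000)), cfg)
  expect_equal(nrow(split), 2)   # gap 1500
})

test_that("segmentation drops runs below the coverage floor", {
  cov <- cov_track(c(100, 5000), c(400, 5400), score = c(1.9, 2))
  out <- segment_coverage(cov, lnc_filter_config(min_coverage = 2))
  expect_equal(out$start, 5000)
})

test_that("segmentation matches the per-base oracle on random tracks", {
  for (s in 1:500) {
    set.seed(s)
    n <- sample(1:12, 1)
    st <- sort(sample(1:20000, n))
    en <- st + sample(1:3000, n, replace = TRUE)
    md <- sample(c(1, 2, 100, 1500), 1)
    got <- segment_coverage(cov_track(st, en),
                            lnc_filter_config(merge_dist = md))
    want <- bf_segment(unlist(mapply(seq, st, en, SIMPLIFY = FALSE)), md)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

filter_fixture <- function() {
  ann <- tiny_ann(list(
    list(gene_id = "pc1", chrom = "chr2",
         exons = cbind(c(100001, 120001), c(100500, 120500))),
    list(gene_id = "rr", chrom = "chr2", biotype = "rRNA",
         exons = cbind(200001, 200600))))
  cons <- data.frame(chrom = "chr2", start = 1, end = 5e5, score = 0.1)
  rrna <- data.frame(chrom = "chr2", start = 300001, end = 300600)
  list(ann = ann, cons = cons, rrna = rrna)
}

test_that("filter boundaries follow the stated strict inequalities", {
  fx <- filter_fixture()
  cands <- data.frame(
    chrom = "chr2",
    start = c(10001, 20001, 30001, 40001),
    end = c(10001 + 2998, 20001 + 2999, 30001 + 4000, 40001 + 4000))
  # 2999 bp and exactly 3000 bp fail the strict > 3000 rule; 4001 passes
  cons <- fx$cons
  out <- apply_lnc_filters(cands, fx$ann, fx$rrna, cons,
                           alpha_rpkm = c(2, 2, 2, 0.5),
                           beta_rpkm = c(2, 2, 2, 1.0))
  expect_equal(out$pass_length, c(FALSE, FALSE, TRUE, TRUE))
  # RPKM rule is strict > 1 in either population (row 4: 0.5 / 1.0 fails)
  expect_equal(out$pass_rpkm, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$survives, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("one base of exon or rRNA overlap fails the overlap rules", {
  fx <- filter_fixture()
  cands <- data.frame(chrom = "chr2",
                      start = c(96500, 296500),
                      end = c(100001, 300001))  # 1 bp into exon / rRNA
  out <- apply_lnc_filters(cands, fx$ann, fx$rrna, fx$cons,
                           alpha_rpkm = c(2, 2), beta_rpkm = c(2, 2))
  expect_equal(out$pass_exon, c(FALSE, TRUE))
  expect_equal(out$pass_rrna, c(TRUE, FALSE))
  expect_match(out$filter_trace[1], "exon_overlap:fail")
  expect_match(out$filter_trace[2], "rrna:fail")
})

test_that("mean conservation exactly at 0.4 is kept (exclusion strict)", {
  fx <- filter_fixture()
  cands <- data.frame(chrom = "chr2", start = 10001, end = 14000)
  at_04 <- data.frame(chrom = "chr2", start = 1, end = 5e5, score = 0.4)
  out <- apply_lnc_filters(cands, fx$ann, fx$rrna, at_04,
                           alpha_rpkm = 2, beta_rpkm = 2)
  expect_true(out$pass_conservation)
  over <- data.frame(chrom = "chr2", start = 1, end = 5e5, score = 0.401)
  out2 <- apply_lnc_filters(cands, fx$ann, fx$rrna, over,
                            alpha_rpkm = 2, beta_rpkm = 2)
  expect_false(out2$pass_conservation)
})

test_that("candidates without conservation data are an error", {
  fx <- filter_fixture()
  cands <- data.frame(chrom = "chrX", start = 1, end = 4000)
  expect_error(apply_lnc_filters(cands, fx$ann, fx$rrna, fx$cons,
                                 alpha_rpkm = 2, beta_rpkm = 2),
               "conservation")
})

test_that("position class: inside an intron vs 30 kb upstream", {
  ann <- tiny_ann(list(
    list(gene_id = "host", chrom = "chr2",
         exons = cbind(c(100001, 140001), c(100500, 140500))),
    list(gene_id = "rr", chrom = "chr2", biotype = "rRNA",
         exons = cbind(500001, 500100))))
  iv <- data.frame(chrom = "chr2",
                   start = c(110001, 66001), end = c(114000, 70000))
  expect_equal(classify_position(iv, ann), c("intronic", "intergenic"))
  # containment in a non-coding gene body does not make it intronic
  iv2 <- data.frame(chrom = "chr2", start = 500001, end = 500050)
  expect_equal(classify_position(iv2, ann), "intergenic")
})

test_that("filter output is invariant to candidate input order", {
  fx <- filter_fixture()
  cands <- data.frame(chrom = "chr2",
                      start = c(40001, 10001, 96500),
                      end = c(44000, 14000, 100001))
  a <- apply_lnc_filters(cands, fx$ann, fx$rrna, fx$cons,
                         alpha_rpkm = c(2, 2, 2), beta_rpkm = c(2, 2, 2))
  perm <- c(3, 1, 2)
  b <- apply_lnc_filters(cands[perm, ], fx$ann, fx$rrna, fx$cons,
                         alpha_rpkm = c(2, 2, 2)[perm],
                         beta_rpkm = c(2, 2, 2)[perm])
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("planted lncRNAs are recovered exactly on the small fixture", {
  cfg <- sim_config_small(seed = 5)
  mouse <- simulate_annotation(cfg, "mouse")
  human <- simulate_annotation(cfg, "human")
  counts <- simulate_counts(cfg, mouse, human)
  lnc <- simulate_lnc_loci(cfg, mouse, counts)
  disc <- discover_lncrnas(lnc$cov_alpha, lnc$cov_beta, mouse$ann,
                           lnc$rrna, lnc$conservation, lnc$mapped_totals)
  truth <- lnc$lnc_truth[lnc$lnc_truth$label == "true_lnc", ]
  got <- disc$survivors[order(disc$survivors$start), ]
  want <- truth[order(truth$start), ]
  expect_equal(nrow(got), cfg$n_lnc)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$class,
               ifelse(is.na(want$host), "intergenic", "intronic"))
})
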