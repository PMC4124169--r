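fake_de <- function(ids, lfc, p) {
  structure(data.frame(gene_id = ids, base_mean = 100, log2_fold = lfc,
                       p_value = p, q_value = p * 2, call = "ns",
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}
pair_tab <- function(ids) data.frame(src_gene_id = ids,
                                     dst_gene_id = toupper(ids),
                                     stringsAsFactors = FALSE)

test_that("one-to-one filtering drops one-to-many and many-to-many pairs", {
  pairs <- data.frame(src_gene_id = c("a", "a", "b", "c", "d"),
                      dst_gene_id = c("A", "B", "B", "C", "D"))
  out <- suppressMessages(one_to_one_orthologs(pairs))
  expect_equal(out$src_gene_id, c("c", "d"))
  expect_equal(attr(out, "n_dropped"), 3)
})

test_that("common core requires RPKM strictly above 1 in both species", {
  pairs <- pair_tab(c("a", "b", "c"))
  r1 <- c(a = 5, b = 5, c = 0.5)
  r2 <- c(A = 2, B = 1, C = 9)
  core <- common_core(r1, r2, pairs)
  expect_equal(core$src_gene_id, "a")       # (5, 2) in; (5, 1) boundary out
})

test_that("specificity rules: unique vs enriched vs ns", {
  pairs <- pair_tab(c("a", "b", "c", "d"))
  r1 <- c(a = 50, b = 50, c = 40, d = 30)
  r2 <- c(A = 0.9, B = 2.0, C = 35, D = 28)
  de <- fake_de(pairs$src_gene_id,
                lfc = c(log2(55), log2(25), log2(8), 0.1),
                p = c(1e-9, 1e-9, 1e-12, 0.5))
  calls <- classify_specificity(r1, r2, de, pairs,
                                species_names = c("mouse", "human"))
  got <- setNames(calls$call, calls$src_gene_id)
  expect_equal(got[["a"]], "mouse_unique")    # other species RPKM < 1
  expect_equal(got[["b"]], "mouse_enriched")  # detectable in both
  expect_equal(got[["c"]], "ns")              # fold gate fails despite p
  expect_equal(got[["d"]], "shared")          # expressed in both, no side
})

test_that("classification partitions each side into unique + enriched", {
  sim <- local({
    cfg <- sim_config(seed = 11)
    mouse <- simulate_annotation(cfg, "mouse")
    human <- simulate_annotation(cfg, "human")
    list(cfg = cfg, mouse = mouse, human = human,
         counts = simulate_counts(cfg, mouse, human))
  })
  cm <- sim$counts$counts_mouse; ch <- sim$counts$counts_human
  pairs <- suppressMessages(one_to_one_orthologs(sim$counts$orthologs))
  mr <- mean_rpkm(compute_rpkm(cm, sim$mouse$ann), c("beta_1", "beta_2"))
  hr <- mean_rpkm(compute_rpkm(ch, sim$human$ann), c("beta_1", "beta_2"))
  de <- xspecies_de(cm[, 1:2], ch[, 1:2], pairs)
  calls <- classify_specificity(mr, hr, de, pairs,
                                species_names = c("mouse", "human"))
  tab <- table(calls$call)
  # the side totals decompose exactly into unique + enriched
  n_mouse_side <- sum(calls$call %in% c("mouse_unique", "mouse_enriched"))
  expect_equal(n_mouse_side,
               sum(tab["mouse_unique"], tab["mouse_enriched"]))
  expect_setequal(unique(calls$call),
                  intersect(c("mouse_unique", "mouse_enriched",
                              "human_unique", "human_enriched", "shared",
                              "ns"), unique(calls$call)))

  # planted recovery >= 95% for unique genes
  tr <- sim$counts$truth
  cc <- setNames(calls$call, calls$src_gene_id)
  for (lab in c("mouse_unique", "human_unique")) {
    planted <- tr$mouse_gene[tr$species_label == lab & tr$one_to_one]
    expect_gte(mean(cc[planted] == lab), 0.95)
  }

  # species-swap mirror: recompute with species roles exchanged
  pairs_sw <- data.frame(src_gene_id = pairs$dst_gene_id,
                         dst_gene_id = pairs$src_gene_id)
  de_sw <- xspecies_de(ch[, 1:2], cm[, 1:2], pairs_sw)
  calls_sw <- classify_specificity(hr, mr, de_sw, pairs_sw,
                                   species_names = c("human", "mouse"))
  cc_sw <- setNames(calls_sw$call, calls_sw$dst_gene_id)
  expect_equal(cc_sw[names(cc)], cc, ignore_attr = TRUE)
})

test_that("species-specific peaks use the inclusive 4-fold rule", {
  map <- block_map(data.frame(
    src_chrom = "h1", src_start = 1, src_end = 100000,
    dst_chrom = "m1", dst_start = 1, dst_end = 100000,
    dst_strand = "+", stringsAsFactors = FALSE))
  pk1 <- data.frame(chrom = "m1", start = c(1000, 5000), end = c(1200, 5200),
                    reads = c(40, 30))
  pk2 <- data.frame(chrom = "h1", start = c(1000, 5000), end = c(1200, 5200),
                    reads = c(10, 60))
  # equal totals (70 vs 70) => per-million normalization cancels
  res <- suppressMessages(species_specific_peaks(
    pk1, pk2, map, pseudocount = 0, species_names = c("m", "h")))
  expect_equal(res$regions$call, c("m_specific", "shared"))  # 4.0 and 2.0
  expect_equal(nrow(res$unmapped), 0)
})

test_that("unconvertible peaks are reported separately", {
  map <- block_map(data.frame(
    src_chrom = "h1", src_start = 5000, src_end = 6000,
    dst_chrom = "m1", dst_start = 5000, dst_end = 6000,
    dst_strand = "+", stringsAsFactors = FALSE))
  pk1 <- data.frame(chrom = "m1", start = 5100, end = 5200, reads = 10)
  pk2 <- data.frame(chrom = "h1", start = c(5100, 100), end = c(5200, 300),
                    reads = c(10, 99))
  res <- suppressMessages(species_specific_peaks(pk1, pk2, map))
  expect_equal(nrow(res$unmapped), 1)
  expect_equal(res$unmapped$reads, 99)
})

test_that("planted read-ratio-5 peaks are all called species-specific", {
  cfg <- sim_config_small(seed = 6)
  mouse <- simulate_annotation(cfg, "mouse")
  counts <- simulate_counts(cfg, mouse, simulate_annotation(cfg, "human"))
  lnc <- simulate_lnc_loci(cfg, mouse, counts)
  bm <- simulate_block_map(cfg, mouse$ann$chrom_sizes)
  reg <- simulate_regulatory(cfg, mouse, lnc$lnc_truth, bm)
  pk <- suppressMessages(species_specific_peaks(
    reg$peaks_mouse, reg$peaks_human, bm$map,
    species_names = c("mouse", "human")))
  ptr <- reg$peak_truth
  idx <- which(ptr$species_label != "shared" & ptr$mapped_to_human)
  expect_equal(length(idx), 2 * cfg$n_peak_specific)
  calls <- vapply(idx, function(i) {
    rg <- pk$regions[pk$regions$chrom == ptr$chrom[i] &
                       pk$regions$start <= ptr$end[i] &
                       pk$regions$end >= ptr$start[i], ]
    any(rg$call == paste0(sub("_specific", "", ptr$species_label[i]),
                          "_specific"))
  }, TRUE)
  expect_true(all(calls))
})
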