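test_that("regenerating with the same seed is byte-identical", {
  cfg <- sim_config_small(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  expect_identical(h(d1, f1), h(d2, f2))
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(sim_config_small(seed = 8), d3)
  expect_false(identical(h(d1, f1), h(d3, f1)))
})

test_that("planted decoys violate exactly their designed rule on disk", {
  cfg <- sim_config_small(seed = 3)
  mouse <- simulate_annotation(cfg, "mouse")
  human <- simulate_annotation(cfg, "human")
  counts <- simulate_counts(cfg, mouse, human)
  lnc <- simulate_lnc_loci(cfg, mouse, counts)
  tr <- lnc$lnc_truth
  dec <- tr[startsWith(tr$label, "decoy"), ]
  # recompute each rule from the emitted tracks/annotation
  for (i in seq_len(nrow(dec))) {
    iv <- dec[i, ]
    len_ok <- (iv$end - iv$start + 1) > 3000
    exon_ok <- !any(mouse$ann$exons$chrom == iv$chrom &
                      mouse$ann$exons$start <= iv$end &
                      mouse$ann$exons$end >= iv$start)
    rrna_ok <- !any(lnc$rrna$chrom == iv$chrom &
                      lnc$rrna$start <= iv$end & lnc$rrna$end >= iv$start)
    cons_ok <- conservation_mean(iv, lnc$conservation) <= 0.4
    rpkm_ok <- iv$alpha_rpkm > 1 || iv$beta_rpkm > 1
    fails <- c(exon_overlap = !exon_ok, length = !len_ok,
               rpkm = !rpkm_ok, rrna = !rrna_ok, conservation = !cons_ok)
    expect_equal(names(which(fails)), sub("decoy:", "", iv$label),
                 label = iv$id)
  }
})

test_that("true lncRNAs respect every discovery rule by construction", {
  cfg <- sim_config_small(seed = 4)
  mouse <- simulate_annotation(cfg, "mouse")
  counts <- simulate_counts(cfg, mouse, simulate_annotation(cfg, "human"))
  lnc <- simulate_lnc_loci(cfg, mouse, counts)
  tr <- lnc$lnc_truth[lnc$lnc_truth$label == "true_lnc", ]
  expect_true(all(tr$end - tr$start + 1 > 3000))
  expect_true(all(tr$alpha_rpkm > 1 | tr$beta_rpkm > 1))
  expect_true(all(conservation_mean(tr, lnc$conservation) <= 0.4))
  expect_false(any(bf_overlaps_any(
    tr$start, tr$end,
    mouse$ann$exons$start[mouse$ann$exons$chrom == tr$chrom[1]],
    mouse$ann$exons$end[mouse$ann$exons$chrom == tr$chrom[1]])))
  # intronic labels match containment in their host gene span
  hosts <- tr[!is.na(tr$host), ]
  spans <- gene_spans(mouse$ann)
  for (i in seq_len(nrow(hosts))) {
    sp <- spans[spans$gene_id == hosts$host[i], ]
    expect_true(sp$start < hosts$start[i] && hosts$end[i] < sp$end)
  }
})

test_that("category overflow in the config is rejected", {
  expect_error(sim_config(n_genes = 200, n_beta_enriched = 100,
                          n_alpha_enriched = 100),
               "config error")
})

test_that("planted species-unique genes are near-silent across species", {
  cfg <- sim_config_small(seed = 9)
  mouse <- simulate_annotation(cfg, "mouse")
  human <- simulate_annotation(cfg, "human")
  counts <- simulate_counts(cfg, mouse, human)
  tr <- counts$truth
  mu_genes <- tr[tr$species_label == "mouse_unique", ]
  hr <- mean_rpkm(compute_rpkm(counts$counts_human, human$ann),
                  c("beta_1", "beta_2"))
  expect_true(all(hr[mu_genes$human_gene] < 0.5))
})

test_that("the simulated motif cluster holds the planted site count", {
  cfg <- sim_config_small(seed = 2)
  mouse <- simulate_annotation(cfg, "mouse")
  counts <- simulate_counts(cfg, mouse, simulate_annotation(cfg, "human"))
  lnc <- simulate_lnc_loci(cfg, mouse, counts)
  bm <- simulate_block_map(cfg, mouse$ann$chrom_sizes)
  reg <- simulate_regulatory(cfg, mouse, lnc$lnc_truth, bm)
  hits <- scan_pwm(reg$sequences[["cluster_region"]], reg$pwm)
  expect_equal(nrow(hits), cfg$cluster_sites)
  expect_equal(sort(hits$pos), reg$site_positions)
  bg <- scan_pwm(reg$sequences[["background_region"]], reg$pwm)
  expect_equal(nrow(bg), 0)
})
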