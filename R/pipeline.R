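#' Run the full analysis pipeline on a simulated dataset
#'
#' Generates the fixture set for `cfg`, then runs every stage in order:
#' RPKM quantification, beta-vs-alpha differential expression, cross-species
#' core/specificity classification, species-specific peak calling, lncRNA
#' discovery with positional classification, transcript-end peak enrichment,
#' PWM scanning with motif-cluster detection, lncRNA/neighbor co-regulation
#' and the glucose-response ranking. All outputs are deterministic TSV/JSON;
#' re-running with the same config gives byte-identical files.
#'
#' @param out_dir output directory; fixtures under `sim/`, results under
#'   `results/`.
#' @param cfg a [sim_config()]; use [sim_config_small()] for quick runs.
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config_small()) {
  sim <- simulate_dataset(cfg, file.path(out_dir, "sim"))
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(res_dir, ...)
  json <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                 digits = 10, pretty = TRUE)

  # quantify
  rpkm_m <- compute_rpkm(sim$counts$counts_mouse, sim$mouse$ann)
  rpkm_h <- compute_rpkm(sim$counts$counts_human, sim$human$ann)
  write_tsv(rpkm_m[order(rpkm_m$gene_id, rpkm_m$sample, method = "radix"), ],
            p("rpkm_mouse.tsv"))
  frac <- read_fractions(sim$counts$counts_mouse, average = TRUE)
  write_tsv(frac[order(frac$gene_id, method = "radix"), ],
            p("read_fractions_mouse.tsv"))

  # beta vs alpha differential expression (mouse)
  cm <- sim$counts$counts_mouse
  groups <- factor(sub("_[0-9]+$", "", colnames(cm)),
                   levels = c("beta", "alpha"))
  de <- nb_test(cm, groups)
  write_tsv(de[order(de$gene_id, method = "radix"), ], p("de_beta_alpha.tsv"))

  # cross-species classification
  pairs <- one_to_one_orthologs(sim$counts$orthologs)
  beta_m <- grep("^beta_", colnames(cm), value = TRUE)
  ch <- sim$counts$counts_human
  beta_h <- grep("^beta_", colnames(ch), value = TRUE)
  mr <- mean_rpkm(rpkm_m, beta_m)
  hr <- mean_rpkm(rpkm_h, beta_h)
  core <- common_core(mr, hr, pairs)
  write_tsv(core, p("common_core.tsv"))
  xde <- xspecies_de(cm[, beta_m, drop = FALSE], ch[, beta_h, drop = FALSE],
                     pairs)
  calls <- classify_specificity(mr, hr, xde, pairs,
                                species_names = c("mouse", "human"))
  write_tsv(calls, p("xspecies_calls.tsv"))

  # species-specific peaks
  pm <- sim$reg$peaks_mouse
  ph <- sim$reg$peaks_human
  pk <- suppressMessages(species_specific_peaks(
    pm, ph, sim$bm$map, species_names = c("mouse", "human")))
  write_tsv(pk$regions, p("peak_regions.tsv"))

  # lncRNA discovery
  disc <- discover_lncrnas(sim$lnc$cov_alpha, sim$lnc$cov_beta,
                           sim$mouse$ann, sim$lnc$rrna,
                           sim$lnc$conservation, sim$lnc$mapped_totals,
                           read_length = sim$lnc$read_length)
  write_tsv(disc$survivors, p("lnc_survivors.tsv"))
  write_bed(data.frame(chrom = disc$survivors$chrom,
                       start = disc$survivors$start,
                       end = disc$survivors$end,
                       name = disc$survivors$lnc_id),
            p("lnc_survivors.bed"))
  write_tsv(disc$rejected, p("lnc_rejected.tsv"))

  # regulatory overlay
  surv <- disc$survivors
  enr <- end_enrichment(surv, pm, sim$mouse$ann$chrom_sizes,
                        n_random = 500, seed = cfg$seed + 71L)
  json(enr, p("end_enrichment.json"))
  hits <- scan_pwm(sim$reg$sequences[["cluster_region"]], sim$reg$pwm)
  cl <- motif_cluster(hits$pos,
                      region_length = nchar(sim$reg$sequences[[1]]),
                      window = cfg$cluster_window, min_sites = 3,
                      n_shuffle = 500, seed = cfg$seed + 72L)
  write_tsv(hits, p("motif_hits.tsv"))
  json(list(clusters = cl$clusters, max_count = cl$max_count,
            p_value = cl$p_value), p("motif_clusters.json"))

  # co-regulation
  np <- nearest_gene(data.frame(chrom = surv$chrom, start = surv$start,
                                end = surv$end, lnc_id = surv$lnc_id),
                     sim$mouse$ann)
  lnc_a <- stats::setNames(surv$alpha_rpkm, surv$lnc_id)
  lnc_b <- stats::setNames(surv$beta_rpkm, surv$lnc_id)
  alpha_m <- grep("^alpha_", colnames(cm), value = TRUE)
  gene_a <- mean_rpkm(rpkm_m, alpha_m)
  gene_b <- mr
  np <- neighbor_log_ratios(np, lnc_a, lnc_b, gene_a, gene_b)
  write_tsv(np, p("neighbor_pairs.tsv"))
  coreg <- coreg_correlation(np)
  json(coreg, p("coregulation.json"))

  # glucose response
  gr <- glucose_response(sim$glucose$counts_low, sim$glucose$counts_high,
                         lnc_ids = sim$glucose$truth$transcript[
                           sim$glucose$truth$is_lnc])
  write_tsv(gr, p("glucose_ranking.tsv"))

  invisible(list(sim = sim, rpkm_mouse = rpkm_m, de = de, core = core,
                 calls = calls, peaks = pk, discovery = disc,
                 end_enrichment = enr, clusters = cl, coreg = coreg,
                 glucose = gr))
}
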