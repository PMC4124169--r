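#' Simulation configuration
#'
#' Parameters of the paired-species synthetic dataset with planted ground
#' truth. Defaults emulate the study design: two replicate groups of beta
#' and alpha cells per species, negative-binomial counts (Var = mu +
#' alpha mu^2, alpha = 0.05), population-enriched genes at a 20-fold mean
#' ratio, species-unique genes below 0.5 RPKM in the other species, 145
#' novel lncRNAs (18 intronic, 127 intergenic) plus five decoy classes that
#' each violate exactly one discovery rule, TF peaks planted at transcript
#' ends, and a 13-site motif cluster inside a 300 bp window.
#'
#' @param n_genes total genes per species.
#' @param n_lnc planted true lncRNAs; `n_lnc_intronic` of them intronic.
#' @param n_lnc_intronic intronic subset of `n_lnc`.
#' @param n_decoys_per_rule decoys per filter rule (5 rules).
#' @param replicates replicates per population (>= 2).
#' @param nb_dispersion NB dispersion alpha.
#' @param n_beta_enriched,n_alpha_enriched planted population-enriched genes.
#' @param enrichment_fold mean ratio between populations for planted genes.
#' @param n_species_unique,n_species_enriched planted species-specific genes
#'   (per species).
#' @param species_fold mean ratio for species-enriched genes.
#' @param coreg_rho latent correlation between lncRNA and nearest-gene
#'   beta/alpha log-ratios.
#' @param n_peaks TF peaks per species; `end_peak_fraction` of them placed
#'   within 1 kb of lncRNA transcript ends.
#' @param end_peak_fraction fraction of peaks at transcript ends.
#' @param n_peak_specific species-specific peaks per species (read ratio
#'   `peak_ratio`).
#' @param peak_ratio read ratio for species-specific peaks.
#' @param cluster_sites motif sites planted within `cluster_window` bp.
#' @param cluster_window cluster window in bp.
#' @param n_glucose_up,n_glucose_down glucose-regulated transcripts planted
#'   at `glucose_fold`; a subset are lncRNAs.
#' @param glucose_fold glucose response fold.
#' @param n_chr2_genes ordinary genes on the sparse chromosome.
#' @param neighbor_ratio_sd sd of the latent beta/alpha log2-ratio given to
#'   genes neighbouring planted lncRNAs (the gene side of the co-regulation
#'   signal); 0 removes it.
#' @param depth library-depth scale: baseline gene means are multiplied by
#'   this factor so per-sample totals match deep bulk RNA-seq libraries
#'   (tens of millions of reads), keeping sub-RPKM expression measurable.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_lnc = 145, n_lnc_intronic = 18,
                       n_decoys_per_rule = 20, replicates = 2,
                       nb_dispersion = 0.05,
                       n_beta_enriched = 50, n_alpha_enriched = 50,
                       enrichment_fold = 20,
                       n_species_unique = 40, n_species_enriched = 30,
                       species_fold = 20,
                       coreg_rho = 0.6,
                       n_peaks = 400, end_peak_fraction = 0.6,
                       n_peak_specific = 30, peak_ratio = 5,
                       cluster_sites = 13, cluster_window = 300,
                       n_glucose_up = 30, n_glucose_down = 30,
                       glucose_fold = 10,
                       n_chr2_genes = 40, neighbor_ratio_sd = 1.5,
                       depth = 400, seed = 1) {
  stopifnot(replicates >= 2, nb_dispersion > 0, depth > 0,
            n_lnc_intronic <= n_lnc,
            coreg_rho >= -1, coreg_rho <= 1, enrichment_fold >= 1)
  cfg <- structure(as.list(environment()), class = "sim_config")
  n_chr2 <- n_lnc_intronic + n_chr2_genes + n_decoys_per_rule
  planted <- n_beta_enriched + n_alpha_enriched +
    2 * (n_species_unique + n_species_enriched)
  if (n_chr2 + planted > floor(0.9 * n_genes) - 10)
    stop("config error: planted category counts exceed the available genes")
  cfg
}

#' Small preset of [sim_config()]
#'
#' Reduced sizes for fast end-to-end runs (pipeline smoke tests and the CLI
#' `--preset small`).
#' @param seed RNG seed.
#' @export
sim_config_small <- function(seed = 1) {
  sim_config(n_genes = 400, n_lnc = 25, n_lnc_intronic = 5,
             n_decoys_per_rule = 3, n_beta_enriched = 10,
             n_alpha_enriched = 10, n_species_unique = 10,
             n_species_enriched = 8, n_peaks = 120, n_peak_specific = 10,
             n_glucose_up = 8, n_glucose_down = 8, n_chr2_genes = 15,
             seed = seed)
}

# ---- genome layout ---------------------------------------------------------

.place_dense_genes <- function(ids, chrom, offset = 1000) {
  n <- length(ids)
  e1 <- sample(250:400, n, TRUE)
  e2 <- sample(250:400, n, TRUE)
  intron <- sample(80:200, n, TRUE)
  gap <- sample(120:280, n, TRUE)
  span <- e1 + intron + e2
  start <- offset + cumsum(gap + span) - span
  data.frame(gene_id = ids, chrom = chrom, start = start,
             e1 = e1, intron = intron, e2 = e2,
             end = start + span - 1, stringsAsFactors = FALSE)
}

.dense_exons <- function(placed) {
  data.frame(
    gene_id = rep(placed$gene_id, each = 2),
    chrom = rep(placed$chrom, each = 2),
    start = as.vector(rbind(placed$start,
                            placed$start + placed$e1 + placed$intron)),
    end = as.vector(rbind(placed$start + placed$e1 - 1, placed$end)),
    stringsAsFactors = FALSE)
}

# Lay out the sparse chromosome: lncRNA hosts, intergenic lncRNAs, decoys
# (one per rule) and ordinary genes, with inter-element margins wide enough
# that segmentation never merges neighbouring elements.
.layout_chr2 <- function(cfg, chrom, id_prefix) {
  k <- cfg$n_decoys_per_rule
  items <- c(rep("host", cfg$n_lnc_intronic),
             rep("lnc", cfg$n_lnc - cfg$n_lnc_intronic),
             rep("decoy_short", k), rep("decoy_low_rpkm", k),
             rep("decoy_conserved", k), rep("decoy_rrna", k),
             rep("decoy_exonic", k),
             rep("gene", cfg$n_chr2_genes))
  items <- sample(items)
  genes <- list(); exons <- list(); lnc <- list(); rrna <- list()
  cursor <- 1000
  gi <- 0; li <- 0; di <- 0
  for (it in items) {
    cursor <- cursor + sample(1700:2600, 1)
    if (it == "gene" || it == "decoy_exonic") {
      gi <- gi + 1
      e1 <- sample(400:700, 1); e2 <- sample(400:700, 1)
      intron <- sample(150:400, 1)
      id <- sprintf("%s_c2g%04d", id_prefix, gi)
      gstart <- cursor; gend <- gstart + e1 + intron + e2 - 1
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, chrom = chrom, start = gstart, end = gend,
        role = if (it == "gene") "chr2_gene" else "exonic_decoy_gene",
        stringsAsFactors = FALSE)
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = id, chrom = chrom,
        start = c(gstart, gstart + e1 + intron),
        end = c(gstart + e1 - 1, gend), stringsAsFactors = FALSE)
      cursor <- gend
      if (it == "decoy_exonic") {
        # expressed interval running off the last exon into open space:
        # overlaps an exon by 200 bp, clears every other rule
        di <- di + 1
        dlen <- sample(3200:4500, 1)
        dstart <- gend - 199; dend <- dstart + dlen - 1
        lnc[[length(lnc) + 1]] <- data.frame(
          id = sprintf("decoy_exonic_%03d", di), chrom = chrom,
          start = dstart, end = dend, label = "decoy:exon_overlap",
          host = NA_character_, stringsAsFactors = FALSE)
        cursor <- dend
      }
    } else if (it == "host") {
      gi <- gi + 1; li <- li + 1
      margin <- sample(1600:1800, 2, TRUE)
      llen <- sample(3200:4500, 1)
      id <- sprintf("%s_c2g%04d", id_prefix, gi)
      e <- sample(450:550, 2, TRUE)
      gstart <- cursor
      intron <- margin[1] + llen + margin[2]
      gend <- gstart + e[1] + intron + e[2] - 1
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, chrom = chrom, start = gstart, end = gend,
        role = "host", stringsAsFactors = FALSE)
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = id, chrom = chrom,
        start = c(gstart, gstart + e[1] + intron),
        end = c(gstart + e[1] - 1, gend), stringsAsFactors = FALSE)
      lstart <- gstart + e[1] + margin[1]
      lnc[[length(lnc) + 1]] <- data.frame(
        id = sprintf("lnc_intronic_%03d", li), chrom = chrom,
        start = lstart, end = lstart + llen - 1, label = "true_lnc",
        host = id, stringsAsFactors = FALSE)
      cursor <- gend
    } else if (it == "lnc") {
      li <- li + 1
      llen <- sample(3200:5000, 1)
      lnc[[length(lnc) + 1]] <- data.frame(
        id = sprintf("lnc_intergenic_%03d", li), chrom = chrom,
        start = cursor, end = cursor + llen - 1, label = "true_lnc",
        host = NA_character_, stringsAsFactors = FALSE)
      cursor <- cursor + llen - 1
    } else {
      di <- di + 1
      rule <- sub("decoy_", "", it)
      llen <- switch(rule, short = sample(2200:2900, 1),
                     sample(3200:4500, 1))
      dstart <- cursor; dend <- dstart + llen - 1
      lab <- switch(rule, short = "decoy:length",
                    low_rpkm = "decoy:rpkm", conserved = "decoy:conservation",
                    rrna = "decoy:rrna")
      lnc[[length(lnc) + 1]] <- data.frame(
        id = sprintf("%s_%03d", it, di), chrom = chrom,
        start = dstart, end = dend, label = lab, host = NA_character_,
        stringsAsFactors = FALSE)
      if (rule == "rrna")
        rrna[[length(rrna) + 1]] <- data.frame(
          chrom = chrom, start = dstart + 800, end = dstart + 1399,
          name = sprintf("rRNA_%03d", di), stringsAsFactors = FALSE)
      cursor <- dend
    }
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons),
       lnc = do.call(rbind, lnc),
       rrna = if (length(rrna)) do.call(rbind, rrna) else
         data.frame(chrom = character(), start = integer(),
                    end = integer(), name = character()),
       extent = cursor)
}

#' Simulate the annotation of one species
#'
#' Two mini-chromosomes: a dense one carrying most genes and a sparse one
#' hosting the planted lncRNA loci, decoys and rRNA loci (mouse only).
#'
#' @param cfg a [sim_config()].
#' @param species `"mouse"` or `"human"`; lncRNA loci are planted on the
#'   mouse genome only.
#' @return list: `ann` (a `genome_annotation`), `lnc` (planted intervals
#'   with labels), `rrna` loci, `gene_roles`.
#' @export
simulate_annotation <- function(cfg, species = c("mouse", "human")) {
  species <- match.arg(species)
  set.seed(cfg$seed + if (species == "mouse") 11L else 12L)
  pre <- if (species == "mouse") "m" else "h"
  chr <- paste0(if (species == "mouse") "chr" else "hchr", 1:2)
  sizes <- stats::setNames(c(2e6, 2e6), chr)
  if (species == "mouse") {
    c2 <- .layout_chr2(cfg, chr[2], pre)
    if (c2$extent > sizes[2] - 1000)
      stop("generation error: insufficient intergenic space on ", chr[2])
    n1 <- cfg$n_genes - nrow(c2$genes)
    ids1 <- sprintf("%sgene%05d", pre, seq_len(n1))
    p1 <- .place_dense_genes(ids1, chr[1])
    if (max(p1$end) > sizes[1] - 1000)
      stop("generation error: insufficient space on ", chr[1])
    genes <- data.frame(
      gene_id = c(p1$gene_id, c2$genes$gene_id),
      chrom = c(p1$chrom, c2$genes$chrom),
      strand = sample(c("+", "-"), cfg$n_genes, TRUE),
      biotype = "protein_coding", stringsAsFactors = FALSE)
    exons <- rbind(.dense_exons(p1), c2$exons)
    ann <- genome_annotation(genes, exons, genome_id = "mouse_sim",
                             chrom_sizes = sizes)
    roles <- stats::setNames(rep("dense", cfg$n_genes), genes$gene_id)
    roles[c2$genes$gene_id] <- c2$genes$role
    list(ann = ann, lnc = c2$lnc, rrna = c2$rrna, gene_roles = roles)
  } else {
    n_half <- ceiling(cfg$n_genes / 2)
    ids <- sprintf("%sgene%05d", pre, seq_len(cfg$n_genes))
    p1 <- .place_dense_genes(ids[1:n_half], chr[1])
    p2 <- .place_dense_genes(ids[(n_half + 1):cfg$n_genes], chr[2])
    if (max(p1$end, p2$end) > 2e6 - 1000)
      stop("generation error: insufficient space for human genes")
    placed <- rbind(p1, p2)
    genes <- data.frame(gene_id = placed$gene_id, chrom = placed$chrom,
                        strand = sample(c("+", "-"), cfg$n_genes, TRUE),
                        biotype = "protein_coding", stringsAsFactors = FALSE)
    ann <- genome_annotation(genes, .dense_exons(placed),
                             genome_id = "human_sim", chrom_sizes = sizes)
    list(ann = ann, lnc = NULL, rrna = NULL,
         gene_roles = stats::setNames(rep("dense", cfg$n_genes),
                                      genes$gene_id))
  }
}

# ---- counts ----------------------------------------------------------------

#' Simulate paired-species count tables with planted ground truth
#'
#' Negative-binomial counts for beta and alpha (mouse) / beta and non-beta
#' (human) populations, `replicates` each, with library-size factors drawn
#' log-uniform in `[0.5, 2]`. Planted categories: population-enriched genes
#' at `enrichment_fold`, species-unique genes (near-zero expression in the
#' other species) and species-enriched genes at `species_fold`. Genes on
#' the sparse chromosome that neighbour a planted lncRNA receive a latent
#' beta/alpha log2-ratio (sd 1.5) that the lncRNA ratios are later
#' correlated with.
#'
#' @param cfg a [sim_config()].
#' @param mouse,human outputs of [simulate_annotation()].
#' @return list: `counts_mouse`, `counts_human` (matrices), `orthologs`
#'   (TSV-ready pair table including non-1:1 fodder rows), `truth`
#'   (per-gene labels and latent ratios), `mu_mouse`, `mu_human`.
#' @export
simulate_counts <- function(cfg, mouse, human) {
  set.seed(cfg$seed + 21L)
  m_ids <- mouse$ann$genes$gene_id
  h_ids <- human$ann$genes$gene_id
  n <- cfg$n_genes
  n_orth <- floor(0.9 * n)
  # orthologs pair the i-th mouse gene with the i-th human gene
  orth_m <- m_ids[seq_len(n_orth)]
  orth_h <- h_ids[seq_len(n_orth)]
  is_orth <- stats::setNames(rep(FALSE, n), m_ids)
  is_orth[orth_m] <- TRUE
  # a few many-to-many rows exercise the one-to-one filter; the genes
  # involved are excluded from planted categories
  n_fodder <- min(5, n_orth %/% 50)
  fodder_idx <- seq(n_orth - n_fodder + 1, length.out = n_fodder)
  extra <- data.frame(src_gene_id = orth_m[fodder_idx],
                      dst_gene_id = orth_h[rev(fodder_idx)],
                      stringsAsFactors = FALSE)
  orthologs <- rbind(data.frame(src_gene_id = orth_m, dst_gene_id = orth_h,
                                stringsAsFactors = FALSE), extra)

  roles <- mouse$gene_roles[m_ids]
  # planted categories live on the dense chromosome among clean 1:1 pairs
  pool <- which(roles == "dense" & seq_len(n) <= n_orth &
                  !seq_len(n) %in% fodder_idx)
  need <- cfg$n_beta_enriched + cfg$n_alpha_enriched +
    2 * (cfg$n_species_unique + cfg$n_species_enriched)
  if (need > length(pool))
    stop("config error: planted category counts exceed the available genes")
  picks <- sample(pool, need)
  take <- function(k) {
    out <- picks[seq_len(k)]
    picks <<- picks[-seq_len(k)]
    out
  }
  idx_beta <- take(cfg$n_beta_enriched)
  idx_alpha <- take(cfg$n_alpha_enriched)
  idx_mu <- take(cfg$n_species_unique)   # mouse-unique
  idx_hu <- take(cfg$n_species_unique)   # human-unique
  idx_me <- take(cfg$n_species_enriched) # mouse-enriched
  idx_he <- take(cfg$n_species_enriched) # human-enriched

  pop_label <- rep("neutral", n)
  pop_label[idx_beta] <- "beta_enriched"
  pop_label[idx_alpha] <- "alpha_enriched"
  sp_label <- ifelse(is_orth[m_ids], "common", "absent")
  sp_label[idx_mu] <- "mouse_unique"
  sp_label[idx_hu] <- "human_unique"
  sp_label[idx_me] <- "mouse_enriched"
  sp_label[idx_he] <- "human_enriched"

  # latent beta/alpha log2 ratio
  t_g <- rep(0, n)
  lfold <- log2(cfg$enrichment_fold)
  t_g[idx_beta] <- lfold
  t_g[idx_alpha] <- -lfold
  host_or_neighbor <- roles %in% c("host", "chr2_gene", "exonic_decoy_gene")
  coreg_idx <- which(host_or_neighbor)
  t_g[coreg_idx] <- stats::rnorm(length(coreg_idx), 0, cfg$neighbor_ratio_sd)
  pop_label[coreg_idx] <- "coreg"

  d <- cfg$depth
  base <- 2^stats::rnorm(n, 5, 2) * d
  base[c(idx_beta, idx_alpha)] <- 2^stats::rnorm(
    cfg$n_beta_enriched + cfg$n_alpha_enriched, 6, 1) * d
  # species-specific genes emulate abundantly expressed markers
  strong <- c(idx_mu, idx_me)
  base[strong] <- 2^stats::rnorm(length(strong), 8, 0.5) * d
  base_h <- base[seq_len(n)]               # shared biology for orthologs
  base_h[idx_hu] <- 2^stats::rnorm(cfg$n_species_unique, 8, 0.5) * d
  base_h[idx_he] <- base[idx_he] * cfg$species_fold
  # "unique in the other species" means ~0.15 RPKM there: scale the mean
  # with the expected table total so the RPKM target holds at any size
  weak <- 8.2e-6 * n * d
  base_h[idx_mu] <- weak
  base_h[idx_me] <- base[idx_me] / cfg$species_fold
  base[idx_hu] <- weak
  # human-only genes get their own baselines
  h_only <- seq_len(n) > n_orth
  base_h[h_only] <- 2^stats::rnorm(sum(h_only), 5, 2) * d

  r <- cfg$replicates
  sim_species <- function(base_mu, ratio, pops) {
    nsamp <- 2 * r
    lib <- exp(stats::runif(nsamp, log(0.5), log(2)))
    mu <- outer(base_mu * 2^(ratio / 2), rep(1, r))      # first population
    mu2 <- outer(base_mu * 2^(-ratio / 2), rep(1, r))    # second population
    mus <- cbind(mu, mu2)
    mus <- sweep(mus, 2, lib, "*")
    cnt <- matrix(stats::rnbinom(length(mus), mu = mus,
                                 size = 1 / cfg$nb_dispersion),
                  nrow = length(base_mu))
    colnames(cnt) <- paste0(rep(pops, each = r), "_", seq_len(r))
    list(counts = cnt, mu = mus, lib = lib)
  }
  ms <- sim_species(base, t_g, c("beta", "alpha"))
  hs <- sim_species(base_h, t_g, c("beta", "nonbeta"))
  rownames(ms$counts) <- m_ids
  rownames(hs$counts) <- h_ids

  truth <- data.frame(
    mouse_gene = m_ids,
    human_gene = c(orth_h, rep(NA_character_, n - n_orth)),
    pop_label = pop_label, species_label = sp_label,
    log2_beta_alpha = t_g, base_mu_mouse = base, base_mu_human = base_h,
    one_to_one = !(seq_len(n) %in% fodder_idx) & is_orth[m_ids],
    stringsAsFactors = FALSE)
  list(counts_mouse = ms$counts, counts_human = hs$counts,
       orthologs = orthologs, truth = truth,
       mu_mouse = ms$mu, mu_human = hs$mu)
}

# ---- lncRNA loci -----------------------------------------------------------

# nearest protein-coding gene by brute force over gene-body spans
.nearest_span <- function(chrom, start, end, spans) {
  g <- spans[spans$chrom == chrom, , drop = FALSE]
  d <- pmax(0, pmax(g$start - end - 1, start - g$end - 1))
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[order(g$start[best], g$gene_id[best])][1]
  c(gene = g$gene_id[best], distance = d[best])
}

#' Simulate lncRNA coverage and conservation tracks
#'
#' Emits per-population coverage (alpha, beta) over gene exons and planted
#' loci, a binned conservation track, and the rRNA locus list. True lncRNAs
#' get a beta/alpha log-ratio correlated (latent rho = `coreg_rho`) with
#' their nearest protein-coding gene's planted ratio; decoys violate exactly
#' their designed rule. Coverage depth encodes RPKM through
#' cov = RPKM x read_length x mapped_total / 1e9, so [interval_rpkm()]
#' recovers the planted expression exactly.
#'
#' @param cfg a [sim_config()].
#' @param mouse output of [simulate_annotation()] for the mouse.
#' @param counts output of [simulate_counts()].
#' @param mapped_total assumed mapped reads per population track.
#' @param read_length read length in bp.
#' @return list: `cov_alpha`, `cov_beta` (1-based closed tracks),
#'   `conservation`, `rrna`, `lnc_truth` (planted intervals with labels,
#'   class, neighbor gene, planted RPKM), `mapped_totals`.
#' @export
simulate_lnc_loci <- function(cfg, mouse, counts, mapped_total = 6e7,
                              read_length = 100) {
  set.seed(cfg$seed + 31L)
  ann <- mouse$ann
  lnc <- mouse$lnc
  spans <- gene_spans(ann, biotype = "protein_coding")
  cov_scale <- read_length * mapped_total / 1e9  # cov per unit RPKM

  # neighbor and correlated ratio for true lncRNAs
  t_gene <- stats::setNames(counts$truth$log2_beta_alpha,
                            counts$truth$mouse_gene)
  is_true <- lnc$label == "true_lnc"
  nb <- t(vapply(which(is_true), function(i) {
    if (!is.na(lnc$host[i])) c(gene = lnc$host[i], distance = "0")
    else .nearest_span(lnc$chrom[i], lnc$start[i], lnc$end[i], spans)
  }, c(gene = "", distance = "")))
  lnc$neighbor_gene <- NA_character_
  lnc$neighbor_gene[is_true] <- nb[, "gene"]
  sd_t <- max(cfg$neighbor_ratio_sd, 1e-8)
  z_gene <- t_gene[lnc$neighbor_gene[is_true]] / sd_t
  z_lnc <- cfg$coreg_rho * z_gene +
    sqrt(1 - cfg$coreg_rho^2) * stats::rnorm(sum(is_true))
  t_lnc <- rep(0, nrow(lnc))
  t_lnc[is_true] <- cfg$neighbor_ratio_sd * z_lnc

  # planted RPKM per population: the stronger population draws U(2.5, 8)
  top <- stats::runif(nrow(lnc), 2.5, 8)
  low <- stats::runif(nrow(lnc), 0.35, 0.7)
  beta_rpkm <- ifelse(t_lnc >= 0, top, top * 2^t_lnc)
  alpha_rpkm <- ifelse(t_lnc >= 0, top * 2^-t_lnc, top)
  lowr <- lnc$label == "decoy:rpkm"
  beta_rpkm[lowr] <- low[lowr]
  alpha_rpkm[lowr] <- low[lowr] * stats::runif(sum(lowr), 0.8, 1)
  lnc$beta_rpkm <- beta_rpkm
  lnc$alpha_rpkm <- alpha_rpkm
  lnc$log2_beta_alpha <- t_lnc

  # gene-exon coverage from the count model (expected RPKM of each exon)
  ex <- ann$exons
  glen <- merged_exon_length(ann)
  tot_m <- sum(counts$truth$base_mu_mouse)
  g_rpkm <- function(mu) mu / (glen[ann$genes$gene_id] / 1000 * tot_m / 1e6)
  base_mu <- counts$truth$base_mu_mouse
  t_g <- counts$truth$log2_beta_alpha
  rpkm_b <- stats::setNames(g_rpkm(base_mu * 2^(t_g / 2)),
                            ann$genes$gene_id)
  rpkm_a <- stats::setNames(g_rpkm(base_mu * 2^(-t_g / 2)),
                            ann$genes$gene_id)
  gene_cov <- function(rpkm_by_gene) {
    sc <- rpkm_by_gene[ex$gene_id] * cov_scale
    keep <- sc >= 0.2
    data.frame(chrom = ex$chrom[keep], start = ex$start[keep],
               end = ex$end[keep], score = round(unname(sc[keep]), 3),
               stringsAsFactors = FALSE)
  }
  lnc_cov <- function(rpkm) data.frame(
    chrom = lnc$chrom, start = lnc$start, end = lnc$end,
    score = round(rpkm * cov_scale, 3), stringsAsFactors = FALSE)
  tidy <- function(df) df[order(df$chrom, df$start, method = "radix"), ,
                          drop = FALSE]
  cov_alpha <- tidy(rbind(gene_cov(rpkm_a), lnc_cov(alpha_rpkm)))
  cov_beta <- tidy(rbind(gene_cov(rpkm_b), lnc_cov(beta_rpkm)))

  # conservation: 1 kb bins, low background, planted-high over conserved
  # decoys
  sizes <- ann$chrom_sizes
  bins <- do.call(rbind, lapply(names(sizes), function(ch) {
    s <- seq(1, sizes[ch], by = 1000)
    data.frame(chrom = ch, start = s, end = pmin(s + 999, sizes[ch]),
               stringsAsFactors = FALSE)
  }))
  bins$score <- round(stats::runif(nrow(bins), 0.02, 0.35), 3)
  consv <- lnc[lnc$label == "decoy:conservation", , drop = FALSE]
  if (nrow(consv)) {
    hit <- .overlaps_any(bins, consv)
    bins$score[hit] <- 0.8
  }
  # expected class of each true lncRNA (host => intronic)
  lnc$class <- ifelse(lnc$label != "true_lnc", NA_character_,
                      ifelse(is.na(lnc$host), "intergenic", "intronic"))
  list(cov_alpha = cov_alpha, cov_beta = cov_beta, conservation = bins,
       rrna = mouse$rrna, lnc_truth = lnc,
       mapped_totals = c(alpha = mapped_total, beta = mapped_total),
       read_length = read_length)
}

# ---- block map and regulatory landscape ------------------------------------

#' Simulate a human-to-mouse block map
#'
#' Colinear equal-length blocks tiling the mouse chromosomes, with small
#' unmapped gaps on both sides, one large human gap per chromosome (for
#' deliberately unconvertible intervals) and occasional strand flips.
#'
#' @param cfg a [sim_config()].
#' @param mouse_sizes named mouse chromosome lengths.
#' @return list: `map` (a `block_map`, src = human), `human_gap` (one large
#'   unmapped human interval per chromosome).
#' @export
simulate_block_map <- function(cfg, mouse_sizes) {
  set.seed(cfg$seed + 41L)
  rows <- list(); gaps <- list()
  for (ci in seq_along(mouse_sizes)) {
    mch <- names(mouse_sizes)[ci]
    hch <- paste0("hchr", ci)
    mpos <- 1; hpos <- 1
    first <- TRUE
    bi <- 0
    while (mpos < mouse_sizes[ci] - 5e4) {
      hgap <- if (first) 5000 else sample(200:800, 1)
      if (first) gaps[[length(gaps) + 1]] <- data.frame(
        chrom = hch, start = hpos, end = hpos + hgap - 1,
        stringsAsFactors = FALSE)
      first <- FALSE
      hpos <- hpos + hgap
      mpos <- mpos + sample(200:800, 1)
      w <- min(sample(40000:80000, 1), mouse_sizes[ci] - mpos)
      bi <- bi + 1
      rows[[length(rows) + 1]] <- data.frame(
        src_chrom = hch, src_start = hpos, src_end = hpos + w - 1,
        dst_chrom = mch, dst_start = mpos, dst_end = mpos + w - 1,
        dst_strand = if (bi %% 15 == 7) "-" else "+",
        stringsAsFactors = FALSE)
      hpos <- hpos + w
      mpos <- mpos + w
    }
  }
  list(map = block_map(do.call(rbind, rows), src_genome = "human_sim",
                       dst_genome = "mouse_sim"),
       human_gap = do.call(rbind, gaps))
}

#' Simulate TF peaks and motif-cluster sequence
#'
#' Mouse peaks: a fraction placed within 1 kb of planted lncRNA transcript
#' ends, the rest uniform. Each mouse peak has a human counterpart obtained
#' by mapping through the inverse block map; planted species-specific peaks
#' carry a `peak_ratio` read imbalance, a few human-only peaks sit in
#' unmapped gaps. One FASTA sequence carries `cluster_sites` motif
#' consensus copies inside a `cluster_window` bp stretch; accidental motif
#' hits in background sequence are scrubbed.
#'
#' @param cfg a [sim_config()].
#' @param mouse annotation output; `lnc_truth` supplies transcript ends.
#' @param lnc_truth planted lncRNA table ([simulate_lnc_loci()]`$lnc_truth`).
#' @param bm output of [simulate_block_map()].
#' @return list: `peaks_mouse`, `peaks_human` (chrom, start, end, name,
#'   reads), `peak_truth`, `sequences` (named character), `pwm`,
#'   `cluster_truth` (sequence name, window, positions).
#' @export
simulate_regulatory <- function(cfg, mouse, lnc_truth, bm) {
  set.seed(cfg$seed + 51L)
  sizes <- mouse$ann$chrom_sizes
  truelnc <- lnc_truth[lnc_truth$label == "true_lnc", , drop = FALSE]
  n_end <- round(cfg$end_peak_fraction * cfg$n_peaks)
  n_unif <- cfg$n_peaks - n_end
  # end-proximal peaks: distinct transcript boundaries, small jitter
  ends <- data.frame(chrom = rep(truelnc$chrom, 2),
                     pos = c(truelnc$start, truelnc$end))
  pick <- sample(nrow(ends), min(n_end, nrow(ends)))
  n_end <- length(pick)
  centers <- ends$pos[pick] + sample(-300:300, n_end, TRUE)
  # uniform peaks: a 3 kb grid away from transcript ends, sampled without
  # replacement so peak regions never collide (differentially bound loci
  # are distinct regions)
  grid <- do.call(rbind, lapply(names(sizes), function(ch) data.frame(
    chrom = ch, pos = seq(3000, sizes[[ch]] - 3000, by = 3000),
    stringsAsFactors = FALSE)))
  near_end <- vapply(seq_len(nrow(grid)), function(i)
    any(ends$chrom == grid$chrom[i] & abs(ends$pos - grid$pos[i]) < 2000),
    TRUE)
  grid <- grid[!near_end, , drop = FALSE]
  upick <- grid[sample(nrow(grid), n_unif), ]
  w <- sample(200:300, n_end + n_unif, TRUE)
  pk <- data.frame(
    chrom = c(ends$chrom[pick], upick$chrom),
    start = pmax(1, c(centers, upick$pos) - w %/% 2),
    stringsAsFactors = FALSE)
  pk$end <- pk$start + w - 1
  pk$name <- sprintf("peak_%04d", seq_len(nrow(pk)))
  pk$at_end <- rep(c(TRUE, FALSE), c(n_end, n_unif))
  # human coordinates through the inverse map; species-specific peaks are
  # planted only among peaks with a convertible human counterpart
  inv <- invert_block_map(bm$map)
  conv <- suppressMessages(convert_intervals(
    pk[c("chrom", "start", "end")], inv))
  ok <- conv$mapped
  n_pk <- nrow(pk)
  spec <- rep("shared", n_pk)
  eligible <- which(ok & !pk$at_end)
  spec[sample(eligible, 2 * cfg$n_peak_specific)] <-
    rep(c("mouse_specific", "human_specific"), each = cfg$n_peak_specific)
  base_reads <- sample(40:200, n_pk, TRUE)
  base_reads[spec != "shared"] <- sample(80:240, sum(spec != "shared"), TRUE)
  reads_m <- round(base_reads *
                     ifelse(spec == "human_specific", 1 / cfg$peak_ratio, 1))
  reads_h <- round(base_reads *
                     ifelse(spec == "mouse_specific", 1 / cfg$peak_ratio,
                            ifelse(spec == "shared",
                                   stats::runif(n_pk, 0.9, 1.1), 1)))
  pk$reads <- reads_m
  peaks_human <- data.frame(chrom = conv$chrom[ok], start = conv$start[ok],
                            end = conv$end[ok],
                            name = paste0("h", pk$name[ok]),
                            reads = reads_h[ok], stringsAsFactors = FALSE)
  # a few human-only peaks inside the large unmapped gaps
  gap <- bm$human_gap
  extra <- data.frame(chrom = gap$chrom, start = gap$start + 1000,
                      end = gap$start + 1299,
                      name = sprintf("honly_%02d", seq_len(nrow(gap))),
                      reads = sample(40:120, nrow(gap), TRUE),
                      stringsAsFactors = FALSE)
  peaks_human <- rbind(peaks_human, extra)
  pk$species_label <- spec
  pk$mapped_to_human <- ok

  # motif + planted cluster sequence
  consensus <- "ACAGGAAGTG"
  L <- nchar(consensus)
  mat <- matrix(0.02, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  cidx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  mat[cbind(cidx, seq_len(L))] <- 0.94
  motif <- pwm(mat, name = "ETS1_like",
               score_threshold = 0.8 * pwm_max_score(
                 pwm(mat, name = "ETS1_like")))
  randseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
  scrub <- function(s) {
    repeat {
      hits <- scan_pwm(s, motif)
      if (nrow(hits) == 0) return(s)
      i <- hits$pos[1] + sample.int(L, 1) - 1
      b <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))
      substr(s, i, i) <- sample(b, 1)
    }
  }
  bg <- scrub(randseq(5000))
  win_start <- 2001
  step <- (cfg$cluster_window - L) %/% max(1, cfg$cluster_sites - 1)
  pos <- win_start + step * (seq_len(cfg$cluster_sites) - 1)
  rc <- .revcomp(consensus)
  site_seq <- ifelse(seq_len(cfg$cluster_sites) %% 2 == 0, rc, consensus)
  cl <- bg
  for (i in seq_len(cfg$cluster_sites))
    substr(cl, pos[i], pos[i] + L - 1) <- site_seq[i]
  seqs <- c(cluster_region = cl, background_region = scrub(randseq(5000)))
  list(peaks_mouse = pk[c("chrom", "start", "end", "name", "reads")],
       peaks_human = peaks_human,
       peak_truth = pk,
       sequences = seqs, pwm = motif,
       cluster_truth = data.frame(seq = "cluster_region",
                                  window_start = min(pos),
                                  window_end = max(pos) + L - 1,
                                  n_sites = cfg$cluster_sites,
                                  stringsAsFactors = FALSE),
       site_positions = pos)
}

# ---- glucose ---------------------------------------------------------------

#' Simulate a glucose stimulation experiment
#'
#' Counts for the combined coding + lncRNA transcript universe in control
#' (low glucose) and stimulated (high glucose) islets, with planted up- and
#' down-regulated transcripts at `glucose_fold`, lncRNAs among them.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids coding transcript ids.
#' @param lnc_ids lncRNA transcript ids.
#' @return list: `counts_low`, `counts_high`, `truth` (transcript, label).
#' @export
simulate_glucose <- function(cfg, gene_ids, lnc_ids) {
  set.seed(cfg$seed + 61L)
  ids <- c(gene_ids, lnc_ids)
  n <- length(ids)
  base <- 2^stats::rnorm(n, 5, 2) * cfg$depth
  lab <- rep("neutral", n)
  n_lnc_up <- min(8, cfg$n_glucose_up, length(lnc_ids))
  n_lnc_dn <- min(5, cfg$n_glucose_down, length(lnc_ids))
  lnc_pick <- sample(length(lnc_ids), n_lnc_up + n_lnc_dn)
  gene_pick <- sample(length(gene_ids),
                      cfg$n_glucose_up + cfg$n_glucose_down -
                        n_lnc_up - n_lnc_dn)
  up <- c(length(gene_ids) + lnc_pick[seq_len(n_lnc_up)],
          gene_pick[seq_len(cfg$n_glucose_up - n_lnc_up)])
  dn <- setdiff(c(length(gene_ids) + lnc_pick, gene_pick), up)
  lab[up] <- "up"; lab[dn] <- "down"
  base[c(up, dn)] <- 2^stats::rnorm(length(c(up, dn)), 6, 1) * cfg$depth
  t <- rep(0, n)
  t[up] <- log2(cfg$glucose_fold)
  t[dn] <- -log2(cfg$glucose_fold)
  r <- cfg$replicates
  lib <- exp(stats::runif(2 * r, log(0.5), log(2)))
  mu_high <- outer(base * 2^(t / 2), lib[seq_len(r)])
  mu_low <- outer(base * 2^(-t / 2), lib[r + seq_len(r)])
  draw <- function(mu, pop) {
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / cfg$nb_dispersion), nrow = n)
    rownames(cnt) <- ids
    colnames(cnt) <- paste0(pop, "_", seq_len(ncol(mu)))
    cnt
  }
  list(counts_low = draw(mu_low, "low"), counts_high = draw(mu_high, "high"),
       truth = data.frame(transcript = ids, label = lab, is_lnc = ids %in%
                            lnc_ids, stringsAsFactors = FALSE))
}

# ---- full dataset ----------------------------------------------------------

#' Simulate the full paired-species dataset
#'
#' Runs every generator stage in a fixed order under `cfg$seed` and,
#' optionally, writes the complete fixture set (GTF, chrom sizes, count
#' TSVs, ortholog and block-map tables, coverage and conservation tracks,
#' rRNA BED, peak BEDs, FASTA, JASPAR PWM, glucose counts, and ground-truth
#' tables) into `out_dir`. Re-running with the same config is byte-identical.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory; created if missing.
#' @return list with all in-memory pieces: `mouse`, `human` (annotation),
#'   `counts`, `lnc`, `bm`, `reg`, `glucose`, and `files` (named paths,
#'   when written).
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  mouse <- simulate_annotation(cfg, "mouse")
  human <- simulate_annotation(cfg, "human")
  counts <- simulate_counts(cfg, mouse, human)
  lnc <- simulate_lnc_loci(cfg, mouse, counts)
  bm <- simulate_block_map(cfg, mouse$ann$chrom_sizes)
  reg <- simulate_regulatory(cfg, mouse, lnc$lnc_truth, bm)
  truelnc <- lnc$lnc_truth[lnc$lnc_truth$label == "true_lnc", ]
  glucose <- simulate_glucose(cfg, mouse$ann$genes$gene_id, truelnc$id)
  out <- list(cfg = cfg, mouse = mouse, human = human, counts = counts,
              lnc = lnc, bm = bm, reg = reg, glucose = glucose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_annotation_gtf(mouse$ann, p("mouse.gtf"))
    write_annotation_gtf(human$ann, p("human.gtf"))
    for (sp in c("mouse", "human")) {
      sz <- out[[sp]]$ann$chrom_sizes
      writeLines(paste(names(sz), format(sz, scientific = FALSE,
                                         trim = TRUE), sep = "\t"),
                 p(paste0(sp, ".chrom.sizes")))
    }
    write_counts(counts$counts_mouse, p("counts_mouse.tsv"))
    write_counts(counts$counts_human, p("counts_human.tsv"))
    write_tsv(counts$orthologs, p("orthologs.tsv"))
    write_block_map(bm$map, p("blockmap.tsv"))
    write_bedgraph(lnc$cov_alpha, p("coverage_alpha.tsv"))
    write_bedgraph(lnc$cov_beta, p("coverage_beta.tsv"))
    write_bedgraph(lnc$conservation, p("conservation.tsv"))
    write_bed(lnc$rrna, p("rrna.bed"))
    pm <- reg$peaks_mouse; ph <- reg$peaks_human
    write_bed(data.frame(chrom = pm$chrom, start = pm$start, end = pm$end,
                         name = pm$name, score = pm$reads),
              p("peaks_mouse.bed"))
    write_bed(data.frame(chrom = ph$chrom, start = ph$start, end = ph$end,
                         name = ph$name, score = ph$reads),
              p("peaks_human.bed"))
    write_fasta(reg$sequences, p("sequences.fasta"))
    write_jaspar_pwm(reg$pwm, p("motif.jaspar"))
    write_counts(glucose$counts_low, p("glucose_low.tsv"))
    write_counts(glucose$counts_high, p("glucose_high.tsv"))
    dir.create(p("truth"), showWarnings = FALSE)
    write_tsv(counts$truth, p("truth", "gene_labels.tsv"))
    write_tsv(lnc$lnc_truth, p("truth", "lnc_labels.tsv"))
    write_tsv(reg$peak_truth, p("truth", "peak_labels.tsv"))
    write_tsv(reg$cluster_truth, p("truth", "cluster.tsv"))
    write_tsv(glucose$truth, p("truth", "glucose_labels.tsv"))
    out$files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  }
  out
}

#' Simulate a pure-null count table
#'
#' Convenience for calibration studies: [simulate_counts()] with every
#' planted effect removed (no population or species enrichment, no
#' lncRNA-neighbor ratios), so the two populations share every gene mean.
#'
#' @param n_genes genes to simulate.
#' @param replicates replicates per population.
#' @param nb_dispersion NB dispersion.
#' @param seed RNG seed.
#' @param depth library-depth scale (see [sim_config()]).
#' @return matrix of counts (beta then alpha columns).
#' @export
simulate_null_counts <- function(n_genes = 2000, replicates = 2,
                                 nb_dispersion = 0.05, seed = 1,
                                 depth = 400) {
  cfg <- sim_config(n_genes = n_genes, replicates = replicates,
                    nb_dispersion = nb_dispersion,
                    n_beta_enriched = 0, n_alpha_enriched = 0,
                    n_species_unique = 0, n_species_enriched = 0,
                    neighbor_ratio_sd = 0, depth = depth, seed = seed)
  mouse <- simulate_annotation(cfg, "mouse")
  human <- simulate_annotation(cfg, "human")
  simulate_counts(cfg, mouse, human)$counts_mouse
}
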