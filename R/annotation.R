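#' Genome annotation container
#'
#' Bundles gene models (one row per gene), their exons, a genome identifier
#' and chromosome sizes. Coordinates are 1-based closed throughout the
#' package; BED-style inputs are converted at the boundary.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `biotype` (one of `"protein_coding"`, `"rRNA"`, `"other"`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @param genome_id single string naming the assembly.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, genome_id = "genome",
                              chrom_sizes = NULL) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  need_g <- c("gene_id", "chrom", "strand", "biotype")
  need_e <- c("gene_id", "chrom", "start", "end")
  if (!all(need_g %in% names(genes)))
    stop("genes must have columns: ", paste(need_g, collapse = ", "))
  if (!all(need_e %in% names(exons)))
    stop("exons must have columns: ", paste(need_e, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("validation error: duplicated gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (nrow(exons)) {
    bad <- exons$end < exons$start
    if (any(bad))
      stop("validation error: exon end < start for gene(s): ",
           paste(unique(exons$gene_id[bad]), collapse = ", "))
    if (any(exons$start < 1))
      stop("validation error: exon start < 1 for gene(s): ",
           paste(unique(exons$gene_id[exons$start < 1]), collapse = ", "))
    # exons of a gene must share the gene's chromosome
    gchrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
    if (anyNA(gchrom))
      stop("validation error: exon with unknown gene_id: ",
           paste(unique(exons$gene_id[is.na(gchrom)]), collapse = ", "))
    if (any(exons$chrom != gchrom))
      stop("validation error: exons on a different chromosome than their gene")
    miss <- setdiff(genes$gene_id, exons$gene_id)
    if (length(miss))
      stop("validation error: gene(s) without exons: ",
           paste(miss, collapse = ", "))
    if (!is.null(chrom_sizes)) {
      len <- chrom_sizes[exons$chrom]
      out <- !is.na(len) & exons$end > len
      if (any(out))
        stop("validation error: exon beyond chromosome end for gene(s): ",
             paste(unique(exons$gene_id[out]), collapse = ", "))
    }
  }
  structure(list(genes = genes, exons = exons, genome_id = genome_id,
                 chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation '", x$genome_id, "': ", nrow(x$genes), " genes, ",
      nrow(x$exons), " exons", sep = "")
  if (!is.null(x$chrom_sizes))
    cat(" on ", length(x$chrom_sizes), " chromosome(s)", sep = "")
  cat("\n")
  tab <- table(x$genes$biotype)
  cat("  biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.normalize_biotype <- function(x) {
  x <- ifelse(is.na(x), "other", x)
  ifelse(x %in% c("protein_coding", "rRNA"), x, "other")
}

#' Read chromosome sizes
#'
#' @param path two-column TSV (chromosome, length in bp), no header.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a GTF annotation
#'
#' Parses exon features of an Ensembl-dialect GTF into a
#' [genome_annotation()]. A pre-scan reports malformed lines by line number;
#' exon coordinates are preserved 1-based closed.
#'
#' @param path GTF file; exon features with `gene_id` attributes required.
#' @param chrom_sizes optional named vector (see [read_chrom_sizes()]); when
#'   given, exons outside `[1, chrom length]` are a validation error.
#' @param genome_id assembly label stored on the result.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, chrom_sizes = NULL, genome_id = "genome") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (any(body)) {
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9))
      stop("parse error: GTF line ", which(body)[which(nf < 9)[1]],
           " has ", nf[which(nf < 9)[1]], " fields (9 required)")
    starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- is.na(starts) | is.na(ends)
    if (any(bad))
      stop("parse error: GTF line ", which(body)[which(bad)[1]],
           ": non-numeric coordinates")
    rev <- ends < starts
    if (any(rev))
      stop("validation error: GTF line ", which(body)[which(rev)[1]],
           ": end < start")
  }
  if (!any(body)) {
    return(genome_annotation(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), biotype = character(),
                         stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE),
      genome_id = genome_id, chrom_sizes = chrom_sizes))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0) {
    return(genome_annotation(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), biotype = character(),
                         stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE),
      genome_id = genome_id, chrom_sizes = chrom_sizes))
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("parse error: exon feature without gene_id attribute")
  bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else NA_character_
  exons <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = .normalize_biotype(bt),
    stringsAsFactors = FALSE)
  first <- !duplicated(exons$gene_id)
  str_by_gene <- tapply(exons$strand, exons$gene_id, function(s) length(unique(s)))
  if (any(str_by_gene > 1))
    stop("validation error: gene(s) with exons on both strands: ",
         paste(names(str_by_gene)[str_by_gene > 1], collapse = ", "))
  genes <- data.frame(
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    biotype = exons$biotype[first],
    stringsAsFactors = FALSE)
  genome_annotation(genes,
                    exons[c("gene_id", "chrom", "start", "end")],
                    genome_id = genome_id, chrom_sizes = chrom_sizes)
}

#' Write a genome_annotation as GTF
#'
#' Emits one `exon` feature per exon, 1-based closed, with
#' `gene_id`/`transcript_id`/`gene_biotype` attributes. Rows are sorted by
#' chromosome, start, then gene_id so output is deterministic.
#'
#' @param ann a `genome_annotation`.
#' @param path output file.
#' @export
write_annotation_gtf <- function(ann, path) {
  ex <- ann$exons
  g <- ann$genes
  if (nrow(ex) == 0) { writeLines(character(0), path); return(invisible(path)) }
  i <- match(ex$gene_id, g$gene_id)
  ord <- order(ex$chrom, ex$start, ex$gene_id, method = "radix")
  ex <- ex[ord, ]; i <- i[ord]
  lines <- paste0(ex$chrom, "\tlncislet\texon\t", ex$start, "\t", ex$end,
                  "\t.\t", g$strand[i], "\t.\t",
                  'gene_id "', ex$gene_id, '"; transcript_id "', ex$gene_id,
                  '.t1"; gene_biotype "', g$biotype[i], '";')
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into 1-based closed intervals
#'
#' @param path BED3/BED6 file (0-based half-open on disk).
#' @return data.frame chrom, start, end (1-based closed), and name, score,
#'   strand when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- ifelse(s == "*", ".", s)
  df
}

#' Write 1-based closed intervals as BED6
#'
#' @param df data.frame with chrom, start, end (1-based closed); optional
#'   name, score, strand columns get BED defaults when absent.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  n <- nrow(df)
  name <- if (!is.null(df$name)) df$name else rep(".", n)
  score <- if (!is.null(df$score)) df$score else rep(0, n)
  strand <- if (!is.null(df$strand)) df$strand else rep(".", n)
  ord <- order(df$chrom, df$start, method = "radix")
  lines <- paste(df$chrom, format(df$start - 1L, scientific = FALSE, trim = TRUE),
                 format(df$end, scientific = FALSE, trim = TRUE),
                 name, score, strand, sep = "\t")[ord]
  writeLines(lines, path)
  invisible(path)
}

#' Merged exon length per gene
#'
#' Length of the union of a gene's exons ("exon model") in bp. Overlapping
#' exons are collapsed before summing.
#'
#' @param ann a `genome_annotation`.
#' @param gene_ids genes to report; default all.
#' @return named numeric vector of lengths in bp.
#' @export
merged_exon_length <- function(ann, gene_ids = NULL) {
  ex <- ann$exons
  if (is.null(gene_ids)) gene_ids <- ann$genes$gene_id
  ex <- ex[ex$gene_id %in% gene_ids, ]
  if (nrow(ex) == 0) return(stats::setNames(numeric(0), character(0)))
  # reduce per gene by keying ranges on gene_id
  ir <- IRanges::IRanges(ex$start, ex$end)
  red <- IRanges::reduce(S4Vectors::split(ir, ex$gene_id))
  len <- sum(IRanges::width(red))
  out <- stats::setNames(rep(NA_real_, length(gene_ids)), gene_ids)
  out[names(len)] <- as.numeric(len)
  out
}

#' Gene-body spans
#'
#' First exon start to last exon end per gene.
#'
#' @param ann a `genome_annotation`.
#' @param biotype optional filter, e.g. `"protein_coding"`.
#' @return data.frame gene_id, chrom, start, end, strand, biotype.
#' @export
gene_spans <- function(ann, biotype = NULL) {
  g <- ann$genes
  if (!is.null(biotype)) g <- g[g$biotype %in% biotype, , drop = FALSE]
  ex <- ann$exons[ann$exons$gene_id %in% g$gene_id, ]
  if (nrow(ex) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), biotype = character()))
  st <- tapply(ex$start, ex$gene_id, min)
  en <- tapply(ex$end, ex$gene_id, max)
  ids <- names(st)
  i <- match(ids, g$gene_id)
  out <- data.frame(gene_id = ids, chrom = g$chrom[i],
                    start = as.integer(st), end = as.integer(en),
                    strand = g$strand[i], biotype = g$biotype[i],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$chrom, out$start, out$gene_id, method = "radix"), , drop = FALSE]
}
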