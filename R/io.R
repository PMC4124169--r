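#' Read a count table
#'
#' @param path TSV with a `gene_id` column followed by one integer column per
#'   sample.
#' @return numeric matrix, genes in rows (rownames = gene_id), samples in
#'   columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("count table must have a gene_id column")
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative counts in ", path)
  m
}

#' Write a count table
#'
#' @param counts matrix with gene rownames.
#' @param path output TSV.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a data.frame as deterministic TSV
#'
#' Tab-separated, header row, no quoting, no row names; numbers formatted by
#' `format()` with 15 significant digits so identical inputs give identical
#' bytes.
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 15, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a bedGraph-like track
#'
#' Four columns (chrom, start, end, score), 0-based half-open on disk,
#' converted to 1-based closed.
#'
#' @param path TSV, no header.
#' @return data.frame chrom, start, end, score (1-based closed).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  df$start <- df$start + 1L
  df
}

#' Write a bedGraph-like track
#'
#' @param df data.frame chrom, start, end, score with 1-based closed
#'   coordinates; written 0-based half-open.
#' @param path output file.
#' @export
write_bedgraph <- function(df, path) {
  ord <- order(df$chrom, df$start, method = "radix")
  lines <- paste(df$chrom[ord],
                 format(df$start[ord] - 1L, scientific = FALSE, trim = TRUE),
                 format(df$end[ord], scientific = FALSE, trim = TRUE),
                 format(df$score[ord], digits = 15, scientific = FALSE,
                        trim = TRUE),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog identifier table
#'
#' @param path two-column TSV (species1 gene id, species2 gene id) with
#'   header.
#' @return data.frame with columns `src_gene_id`, `dst_gene_id`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog table needs two columns")
  names(df)[1:2] <- c("src_gene_id", "dst_gene_id")
  df[1:2]
}

#' Restrict an ortholog table to one-to-one pairs
#'
#' Drops every pair involving an identifier that occurs more than once on
#' either side (one-to-many and many-to-many orthology), with a message
#' reporting how many pairs were removed.
#'
#' @param pairs data.frame from [read_ortholog_map()].
#' @return filtered data.frame; attribute `n_dropped` records the removals.
#' @export
one_to_one_orthologs <- function(pairs) {
  dup <- pairs$src_gene_id %in% pairs$src_gene_id[duplicated(pairs$src_gene_id)] |
    pairs$dst_gene_id %in% pairs$dst_gene_id[duplicated(pairs$dst_gene_id)]
  out <- pairs[!dup, , drop = FALSE]
  if (any(dup))
    message(sum(dup), " ortholog pair(s) dropped (not one-to-one)")
  attr(out, "n_dropped") <- sum(dup)
  out
}

#' Read a JASPAR-format position weight matrix
#'
#' Expects a `>name` header followed by four rows `A [ ... ]`, `C [ ... ]`,
#' `G [ ... ]`, `T [ ... ]` of counts or frequencies.
#'
#' @param path PWM text file.
#' @param pseudocount added to each count before normalization.
#' @param background per-base background probabilities (A, C, G, T).
#' @return a `pwm` object (see [pwm()]).
#' @export
read_jaspar_pwm <- function(path, pseudocount = 0.5,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- sub("^>\\s*", "", lines[startsWith(lines, ">")][1])
  if (is.na(name)) name <- "motif"
  rows <- lines[grepl("^[ACGT]\\b", lines)]
  if (length(rows) != 4) stop("JASPAR file must have A/C/G/T rows")
  base <- substr(rows, 1, 1)
  nums <- lapply(rows, function(l) {
    x <- gsub("[][]", " ", substring(l, 2))
    as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  })
  mat <- do.call(rbind, nums)[match(c("A", "C", "G", "T"), base), , drop = FALSE]
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  pwm(mat, name = name, background = background)
}

#' Write a PWM in JASPAR text format
#'
#' @param x a `pwm` object; probabilities are written as-is.
#' @param path output file.
#' @export
write_jaspar_pwm <- function(x, path) {
  m <- x$matrix
  lines <- c(paste0(">", x$name),
             vapply(c("A", "C", "G", "T"), function(b)
               paste0(b, " [ ", paste(format(m[b, ], digits = 6), collapse = " "),
                      " ]"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  stats::setNames(seqs, id)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
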