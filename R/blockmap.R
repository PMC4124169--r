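#' Cross-genome block map
#'
#' A liftOver-style set of colinear, equal-length blocks between two
#' assemblies. Within a block, position `src_start + k` maps to
#' `dst_start + k` on `+` blocks and to `dst_end - k` on `-` blocks.
#'
#' @param blocks data.frame with columns src_chrom, src_start, src_end,
#'   dst_chrom, dst_start, dst_end, dst_strand (`"+"`/`"-"`); coordinates
#'   1-based closed.
#' @param src_genome,dst_genome assembly labels.
#' @return object of class `block_map`.
#' @export
block_map <- function(blocks, src_genome = "src", dst_genome = "dst") {
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start",
            "dst_end", "dst_strand")
  if (!all(need %in% names(blocks)))
    stop("block map needs columns: ", paste(need, collapse = ", "))
  w_src <- blocks$src_end - blocks$src_start + 1
  w_dst <- blocks$dst_end - blocks$dst_start + 1
  if (any(w_src != w_dst))
    stop("validation error: block src and dst spans differ in length")
  if (any(w_src < 1)) stop("validation error: empty block")
  # src blocks must not overlap within a chromosome
  sp <- split(blocks, blocks$src_chrom)
  for (b in sp) {
    b <- b[order(b$src_start), ]
    if (nrow(b) > 1 && any(b$src_start[-1] <= b$src_end[-nrow(b)]))
      stop("validation error: overlapping src blocks on ", b$src_chrom[1])
  }
  structure(list(blocks = blocks[need], src_genome = src_genome,
                 dst_genome = dst_genome), class = "block_map")
}

#' @export
print.block_map <- function(x, ...) {
  cat("block_map ", x$src_genome, " -> ", x$dst_genome, ": ",
      nrow(x$blocks), " blocks, ",
      format(sum(x$blocks$src_end - x$blocks$src_start + 1), big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Read a block map from TSV
#'
#' @param path seven-column TSV with header (src_chrom, src_start, src_end,
#'   dst_chrom, dst_start, dst_end, dst_strand), 1-based closed.
#' @param src_genome,dst_genome assembly labels.
#' @export
read_block_map <- function(path, src_genome = "src", dst_genome = "dst") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  block_map(df, src_genome, dst_genome)
}

#' Write a block map
#'
#' @param map a `block_map`.
#' @param path output TSV.
#' @export
write_block_map <- function(map, path) {
  b <- map$blocks
  write_tsv(b[order(b$src_chrom, b$src_start, method = "radix"), ], path)
}

#' Invert a block map
#'
#' Swaps source and destination so converted intervals can be mapped back.
#'
#' @param map a `block_map`.
#' @export
invert_block_map <- function(map) {
  b <- map$blocks
  block_map(data.frame(src_chrom = b$dst_chrom, src_start = b$dst_start,
                       src_end = b$dst_end, dst_chrom = b$src_chrom,
                       dst_start = b$src_start, dst_end = b$src_end,
                       dst_strand = b$dst_strand, stringsAsFactors = FALSE),
            src_genome = map$dst_genome, dst_genome = map$src_genome)
}

#' Convert one interval across genomes
#'
#' The interval maps when at least `min_mapped` of its bases fall inside
#' blocks; the result is the destination span covering all mapped bases
#' (strand-aware). Unmapped is a value, not an error.
#'
#' @param chrom,start,end source interval, 1-based closed.
#' @param map a `block_map`.
#' @param min_mapped minimum fraction of bases inside blocks (default 0.5).
#' @return list with `mapped` (logical), and when mapped: `chrom`, `start`,
#'   `end`, `strand` in the destination genome.
#' @export
convert_interval <- function(chrom, start, end, map, min_mapped = 0.5) {
  b <- map$blocks
  b <- b[b$src_chrom == chrom & b$src_end >= start & b$src_start <= end, ,
         drop = FALSE]
  unmapped <- list(mapped = FALSE, chrom = NA_character_,
                   start = NA_integer_, end = NA_integer_,
                   strand = NA_character_)
  if (nrow(b) == 0) return(unmapped)
  s <- pmax(start, b$src_start)
  e <- pmin(end, b$src_end)
  covered <- sum(e - s + 1)
  if (covered / (end - start + 1) < min_mapped) return(unmapped)
  plus <- b$dst_strand == "+"
  ds <- ifelse(plus, b$dst_start + (s - b$src_start),
               b$dst_end - (e - b$src_start))
  de <- ifelse(plus, b$dst_start + (e - b$src_start),
               b$dst_end - (s - b$src_start))
  # majority destination chromosome / strand by mapped bases
  bases_by_chrom <- tapply(e - s + 1, b$dst_chrom, sum)
  dchrom <- names(bases_by_chrom)[which.max(bases_by_chrom)]
  keep <- b$dst_chrom == dchrom
  strand <- if (sum((e - s + 1)[keep & plus]) >= covered / 2) "+" else "-"
  list(mapped = TRUE, chrom = dchrom,
       start = as.integer(min(ds[keep])), end = as.integer(max(de[keep])),
       strand = strand)
}

#' Convert a table of intervals across genomes
#'
#' @param df data.frame with chrom, start, end (1-based closed); other
#'   columns are carried through.
#' @param map a `block_map`.
#' @param min_mapped minimum mapped-base fraction (default 0.5).
#' @return `df` with columns `chrom`, `start`, `end`, `strand` replaced by
#'   destination coordinates and a logical `mapped` column; unmapped rows
#'   keep NA coordinates. The number of unmapped intervals is reported with
#'   a message.
#' @export
convert_intervals <- function(df, map, min_mapped = 0.5) {
  res <- lapply(seq_len(nrow(df)), function(i)
    convert_interval(df$chrom[i], df$start[i], df$end[i], map, min_mapped))
  out <- df
  out$chrom <- vapply(res, `[[`, "", "chrom")
  out$start <- vapply(res, `[[`, 1L, "start")
  out$end <- vapply(res, `[[`, 1L, "end")
  out$strand <- vapply(res, `[[`, "", "strand")
  out$mapped <- vapply(res, `[[`, TRUE, "mapped")
  if (any(!out$mapped))
    message(sum(!out$mapped), " interval(s) unmapped across genomes")
  out
}
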