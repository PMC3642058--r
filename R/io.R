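#' Read / write probe-level intensity tables
#'
#' Plain TSV with columns `chrom`, `pos`, `strand` and one column per
#' sample.  Positions are 1-based.
#'
#' @param probes a `probe_matrix`.
#' @param path file path.
#' @param sample_cols,control_cols optional column-group names recorded as
#'   attributes on read.
#' @return `read_probe_tsv` returns a `probe_matrix`.
#' @export
write_probe_tsv <- function(probes, path) {
  data.table::fwrite(as.data.frame(probes), path, sep = "\t")
  invisible(path)
}

#' @rdname write_probe_tsv
#' @export
read_probe_tsv <- function(path, sample_cols = NULL, control_cols = NULL) {
  x <- as.data.frame(data.table::fread(path, sep = "\t"))
  attr(x, "sample_cols") <- sample_cols
  attr(x, "control_cols") <- control_cols
  class(x) <- c("probe_matrix", "data.frame")
  x
}

#' Write a track as bedGraph
#'
#' Converts the internal 1-based closed positions to the format's 0-based
#' half-open intervals (one grid step wide) at the I/O boundary.
#'
#' @param track track data.frame (`chrom`, `pos`, `value`).
#' @param path output file.
#' @param step grid step (bp); default inferred per chromosome.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path, step = NULL) {
  out <- lapply(unique(track$chrom), function(ch) {
    sel <- track$chrom == ch
    s <- step %||% grid_step(track$pos[sel])
    data.frame(chrom = ch, start = track$pos[sel] - 1L,
               end = track$pos[sel] - 1L + s,
               value = track$value[sel])
  })
  data.table::fwrite(do.call(rbind, out), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t",
                                       col.names = c("chrom", "start",
                                                     "end", "value")))
  data.frame(chrom = x$chrom, pos = x$start + 1L, value = x$value,
             stringsAsFactors = FALSE)
}

#' Write nucleosome calls as BED6
#'
#' Scores are min-max scaled to 0-1000 as BED requires; genic calls are
#' named `gene:index`, others `nuc<i>`.  Full-precision scores belong in
#' the TSV written alongside ([write_calls_tsv()]).
#'
#' @param calls call data.frame; may carry `gene_id`/`index` columns.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  nm <- if (all(c("gene_id", "index") %in% names(calls)))
    paste0(calls$gene_id, ":+", calls$index)
  else paste0("nuc", seq_len(nrow(calls)))
  rng <- range(calls$score)
  sc <- if (diff(rng) > 0)
    as.integer(round(1000 * (calls$score - rng[1]) / diff(rng)))
  else rep(0L, nrow(calls))
  bed <- data.frame(chrom = calls$chrom, start = calls$center - 1L,
                    end = calls$center, name = nm, score = sc,
                    strand = if ("strand" %in% names(calls))
                      calls$strand else ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
write_calls_tsv <- function(calls, path) {
  data.table::fwrite(as.data.frame(calls), path, sep = "\t")
  invisible(path)
}

#' Write / read gene models as GFF3
#'
#' Uses `rtracklayer` when available for standards-compliant GFF3;
#' coordinates stay 1-based closed as the format requires.
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param path file path.
#' @return `read_genes_gff3` returns a gene table with `tss`/`tes`.
#' @export
write_genes_gff3 <- function(genes, path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      strand = genes$strand)
    S4Vectors::mcols(gr)$ID <- genes$gene_id
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$source <- "nucshift"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    lines <- sprintf("%s\tnucshift\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id)
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    g <- data.frame(gene_id = as.character(S4Vectors::mcols(gr)$ID),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  } else {
    x <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
    g <- data.frame(gene_id = sub(".*ID=([^;]+).*", "\\1", x$V9),
                    chrom = x$V1, start = x$V4, end = x$V5,
                    strand = x$V7, stringsAsFactors = FALSE)
  }
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g
}

#' Write fragment records as BEDPE
#'
#' Each ~147-bp fragment is emitted as its two 36-nt read anchors (the
#' paired-end representation); coordinates convert to 0-based half-open.
#'
#' @param pairs data.frame `chrom`, `start`, `end` (1-based closed
#'   fragments).
#' @param path output file.
#' @param read_len anchor read length in nt.
#' @return the path, invisibly.
#' @export
write_bedpe <- function(pairs, path, read_len = 36) {
  bedpe <- data.frame(
    chrom1 = pairs$chrom, start1 = pairs$start - 1L,
    end1 = pmin(pairs$start - 1L + read_len, pairs$end),
    chrom2 = pairs$chrom,
    start2 = pmax(pairs$end - read_len, pairs$start - 1L),
    end2 = pairs$end)
  data.table::fwrite(bedpe, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t"))[, 1:6]
  names(x) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  data.frame(chrom = x$chrom1, start = x$start1 + 1L, end = x$end2,
             stringsAsFactors = FALSE)
}
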