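#' Promoter NDR window of a gene
#'
#' The nucleosome-depleted region is operationalized as the 200-bp window
#' directly upstream of the curated TSS, strand-aware: it abuts but does
#' not include the TSS.
#'
#' @param tss TSS coordinate(s).
#' @param strand gene strand(s).
#' @param width window width in bp.
#' @return data.frame `start`, `end` (1-based closed).
#' @export
ndr_window <- function(tss, strand, width = 200) {
  start <- ifelse(strand == "+", tss - width, tss + 1)
  end <- ifelse(strand == "+", tss - 1, tss + width)
  data.frame(start = as.integer(start), end = as.integer(end))
}

# Mean of a track's value over [start, end] on one chromosome; truncates
# at track limits and flags the truncation.
window_mean <- function(track, chrom, start, end) {
  sel <- track$chrom == chrom & track$pos >= max(1L, start) &
    track$pos <= end
  v <- track$value[sel]
  if (!length(v)) return(list(mean = NA_real_, truncated = TRUE))
  covered <- track$pos[sel]
  list(mean = mean(v),
       truncated = start < min(track$pos[track$chrom == chrom]) ||
         end > max(track$pos[track$chrom == chrom]))
}

#' Mean NDR occupancy change per gene
#'
#' Averages a per-position occupancy-change track (condition minus wild
#' type, log2) over each gene's promoter NDR window.
#'
#' @param genes gene table.
#' @param docc occupancy-change track (`chrom`, `pos`, `value`).
#' @param width NDR width in bp.
#' @return genes with added `ndr_start`, `ndr_end`, `mean_docc`,
#'   `truncated`.
#' @export
ndr_occupancy_change <- function(genes, docc, width = 200) {
  w <- ndr_window(genes$tss, genes$strand, width)
  genes$ndr_start <- w$start
  genes$ndr_end <- w$end
  res <- lapply(seq_len(nrow(genes)), function(i)
    window_mean(docc, genes$chrom[i], w$start[i], w$end[i]))
  genes$mean_docc <- vapply(res, `[[`, numeric(1), "mean")
  genes$truncated <- vapply(res, `[[`, logical(1), "truncated")
  genes
}

#' Scan for transcripts de-repressed together with upstream nucleosome loss
#'
#' The co-repressor signature (TCR scan): an up-regulated transfrag whose
#' 200-bp upstream window (anchored at the transfrag's own 5' end,
#' strand-aware) shows a mean log2 occupancy decrease of at least
#' `log2(occ_fold)`.  Hits are categorized as `subtelomeric` when the 5'
#' end lies within `subtel_dist` of a chromosome end, else `antisense`
#' when the transfrag is intragenic-antisense, else `intergenic`.
#'
#' @param tf classified transfrag data.frame (needs `direction` and
#'   `orientation_class`).
#' @param docc occupancy-change track (condition minus wild type, log2).
#' @param chrom_lengths named chromosome lengths.
#' @param occ_fold required linear fold decrease in upstream occupancy.
#' @param upstream_width upstream window width in bp.
#' @param subtel_dist distance from a chromosome end defining
#'   "subtelomeric" (bp).
#' @return the hit transfrags with added `upstream_docc` and `category`.
#' @export
detect_tcr <- function(tf, docc, chrom_lengths, occ_fold = 1.5,
                       upstream_width = 200, subtel_dist = 25000) {
  if (!nrow(tf)) {
    tf$upstream_docc <- numeric(0)
    tf$category <- character(0)
    return(tf)
  }
  p5 <- five_prime(tf$start, tf$end, tf$strand)
  win <- ndr_window(p5, tf$strand, upstream_width)
  tf$upstream_docc <- vapply(seq_len(nrow(tf)), function(i)
    window_mean(docc, tf$chrom[i], win$start[i], win$end[i])$mean,
    numeric(1))
  hit <- tf$direction == "up" & !is.na(tf$upstream_docc) &
    tf$upstream_docc <= -log2(occ_fold)
  out <- tf[hit, , drop = FALSE]
  if (nrow(out)) {
    p5h <- five_prime(out$start, out$end, out$strand)
    dist_end <- pmin(p5h, chrom_lengths[out$chrom] - p5h)
    out$category <- ifelse(dist_end <= subtel_dist, "subtelomeric",
                           ifelse(out$orientation_class ==
                                    "intragenic-antisense",
                                  "antisense", "intergenic"))
  } else out$category <- character(0)
  rownames(out) <- NULL
  out
}

#' Detect promoter-associated transcripts
#'
#' A transfrag is a promoter-associated transcript (PAT) when its 5' end
#' lies inside the promoter NDR window of some gene; ties between two
#' genes' windows resolve to the gene with the nearer TSS.  The promoter
#' configuration of each anchor gene is `diverging` when its nearest
#' upstream neighbor gene is on the opposite strand (a shared divergent
#' promoter) and `tandem` when it is on the same strand.
#'
#' @param tf transfrag data.frame.
#' @param genes gene table.
#' @param ndr_width NDR width in bp.
#' @return list: `hits` (PAT transfrags with `anchor_gene` and
#'   `promoter_config`), `n_diverging`, `n_tandem`, `frac_diverging`,
#'   `frac_tandem`.
#' @export
detect_pat <- function(tf, genes, ndr_width = 200) {
  w <- ndr_window(genes$tss, genes$strand, ndr_width)
  anchor <- rep(NA_character_, nrow(tf))
  if (nrow(tf)) {
    p5 <- five_prime(tf$start, tf$end, tf$strand)
    for (i in seq_len(nrow(tf))) {
      inw <- which(genes$chrom == tf$chrom[i] & p5[i] >= w$start &
                     p5[i] <= w$end)
      if (!length(inw)) next
      if (length(inw) > 1L)
        inw <- inw[which.min(abs(genes$tss[inw] - p5[i]))]
      anchor[i] <- genes$gene_id[inw]
    }
  }
  hits <- tf[!is.na(anchor), , drop = FALSE]
  hits$anchor_gene <- anchor[!is.na(anchor)]
  hits$promoter_config <- vapply(hits$anchor_gene, function(gid) {
    promoter_configuration(genes, gid)
  }, character(1))
  n_div <- sum(hits$promoter_config == "diverging")
  n_tan <- sum(hits$promoter_config == "tandem")
  ntot <- n_div + n_tan
  list(hits = hits, n_diverging = n_div, n_tandem = n_tan,
       frac_diverging = if (ntot) n_div / ntot else NA_real_,
       frac_tandem = if (ntot) n_tan / ntot else NA_real_)
}

# Orientation of the gene pair flanking a gene's promoter NDR: the nearest
# gene on the upstream (promoter) side determines the configuration.
promoter_configuration <- function(genes, gene_id) {
  g <- genes[genes$gene_id == gene_id, ]
  gg <- genes[genes$chrom == g$chrom & genes$gene_id != gene_id, ,
              drop = FALSE]
  if (!nrow(gg)) return("isolated")
  if (g$strand == "+") {
    up <- gg[gg$end < g$start, , drop = FALSE]
    if (!nrow(up)) return("isolated")
    nb <- up[which.max(up$end), ]
  } else {
    up <- gg[gg$start > g$end, , drop = FALSE]
    if (!nrow(up)) return("isolated")
    nb <- up[which.min(up$start), ]
  }
  if (nb$strand == g$strand) "tandem" else "diverging"
}

#' TSS-anchored average occupancy profile
#'
#' Aligns per-gene occupancy to the TSS (offset 0), reflecting
#' minus-strand genes so that positive offsets always run into the gene
#' body, and averages across genes at each offset.
#'
#' @param track occupancy track (`chrom`, `pos`, `value`).
#' @param genes gene table.
#' @param from,to offset range in bp relative to the TSS.
#' @return data.frame `offset`, `n`, `mean`.
#' @export
tss_profile <- function(track, genes, from = -500, to = 2000) {
  offs <- seq.int(from, to)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  for (ch in unique(genes$chrom)) {
    sel <- track$chrom == ch
    pos <- track$pos[sel]
    val <- track$value[sel]
    if (!length(pos)) next
    step <- grid_step(pos)
    p0 <- pos[1]
    gg <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(gg))) {
      dir <- strand_dir(gg$strand[i])
      gpos <- gg$tss[i] + dir * offs
      idx <- round((gpos - p0) / step) + 1L
      ok <- idx >= 1L & idx <= length(pos) &
        abs(pos[pmin(pmax(idx, 1L), length(pos))] - gpos) < step
      acc[ok] <- acc[ok] + val[idx[ok]]
      cnt[ok] <- cnt[ok] + 1L
    }
  }
  data.frame(offset = offs, n = cnt,
             mean = ifelse(cnt > 0, acc / cnt, NA_real_))
}

#' Rank genes by NDR occupancy change against expression change
#'
#' Sorts genes by mean NDR occupancy change (ascending: strongest loss
#' first), pairs each with its expression change, and reports the
#' Spearman rank correlation between the two.  Genes without an
#' expression value are excluded and counted.
#'
#' @param gene_docc an [ndr_occupancy_change()] result.
#' @param expr_change named vector of per-gene expression changes (log2).
#' @return list: `table` (ranked data.frame with `rank`), `rho` (Spearman
#'   correlation, `NA` when undefined), `n_missing`.
#' @export
rank_by_ndr <- function(gene_docc, expr_change) {
  g <- gene_docc
  g$expr_change <- expr_change[g$gene_id]
  miss <- is.na(g$expr_change) | is.na(g$mean_docc)
  n_missing <- sum(miss)
  g <- g[!miss, , drop = FALSE]
  g <- g[order(g$mean_docc, g$gene_id), , drop = FALSE]
  g$rank <- seq_len(nrow(g))
  rho <- if (nrow(g) >= 3 && sd(g$mean_docc) > 0 && sd(g$expr_change) > 0)
    stats::cor(g$mean_docc, g$expr_change, method = "spearman")
  else NA_real_
  rownames(g) <- NULL
  list(table = g, rho = rho, n_missing = n_missing)
}
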