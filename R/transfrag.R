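#' Two-sided rank-sum p-value for a probe window
#'
#' Wilcoxon rank-sum comparing two pooled value sets.  Complete separation
#' (all of one group beyond all of the other) gets the exact permutation
#' tail `2 / choose(n + m, n)` — identical to the exact Wilcoxon value and
#' valid under arbitrary within-group ties.  Otherwise a normal
#' approximation with tie correction and continuity correction is used
#' (the same approximation [stats::wilcox.test()] applies in the presence
#' of ties).  Windows with fewer than 3 values in either group are
#' untestable and return p = 1.
#'
#' @param x,y numeric value vectors (treatment, control).
#' @return two-sided p-value.
#' @export
ranksum_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 3L || ny < 3L) return(1)
  if (min(x) > max(y) || max(x) < min(y))
    return(min(1, 2 / choose(nx + ny, nx)))
  all_v <- c(x, y)
  r <- rank(all_v)
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  cnt <- rle(sort(all_v))$lengths
  ntot <- nx + ny
  sigma2 <- (nx * ny / 12) *
    ((ntot + 1) - sum(cnt^3 - cnt) / (ntot * (ntot - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  corr <- sign(z) * 0.5
  min(1, 2 * pnorm(-abs((z - corr) / sqrt(sigma2))))
}

#' Per-probe differential-expression statistics
#'
#' For every probe, pools treatment and control intensities from all
#' replicates over all probes within `bandwidth` bp on the same strand,
#' then reports the log2 fold change of the window means and a two-sided
#' rank-sum p-value ([ranksum_p()]).
#'
#' @param probes expression `probe_matrix` ([simulate_expression()] or
#'   imported), with `sample_cols`/`control_cols` attributes or explicit
#'   column names.
#' @param bandwidth pooling half-window in bp.
#' @param treat_cols,control_cols intensity column names.
#' @return data.frame `chrom`, `pos`, `strand`, `log2_fc`, `p`.
#' @export
probe_stats <- function(probes, bandwidth = 30, treat_cols = NULL,
                        control_cols = NULL) {
  treat_cols <- treat_cols %||% attr(probes, "sample_cols")
  control_cols <- control_cols %||% attr(probes, "control_cols")
  stopifnot(!is.null(treat_cols), !is.null(control_cols))
  key <- paste(probes$chrom, probes$strand)
  out <- probes[, c("chrom", "pos", "strand")]
  out$log2_fc <- NA_real_
  out$p <- NA_real_
  for (grp in unique(key)) {
    idx <- which(key == grp)
    step <- grid_step(probes$pos[idx])
    h <- floor(bandwidth / step)
    tm <- as.matrix(probes[idx, treat_cols, drop = FALSE])
    cm <- as.matrix(probes[idx, control_cols, drop = FALSE])
    n <- length(idx)
    fc <- numeric(n)
    p <- numeric(n)
    for (i in seq_len(n)) {
      w <- max(1L, i - h):min(n, i + h)
      tv <- tm[w, ]
      cv <- cm[w, ]
      fc[i] <- log2(mean(tv) / mean(cv))
      p[i] <- ranksum_p(tv, cv)
    }
    out$log2_fc[idx] <- fc
    out$p[idx] <- p
  }
  out
}

#' Detect raw differentially transcribed regions
#'
#' Scans each strand for maximal runs of probes passing both thresholds
#' (|fold change| >= `fc_thresh`, p <= `p_thresh`) with a consistent sign
#' of change, where consecutive passing probes are at most `max_gap` bp
#' apart.  A run is emitted as a transfrag only if it spans at least
#' `min_len` bp and contains at least `min_probes` passing probes; bounds
#' are the first and last passing probe.
#'
#' @param stats a [probe_stats()] result, position-sorted within strand.
#' @param fc_thresh linear fold-change threshold.
#' @param p_thresh p-value threshold.
#' @param min_len minimum span in bp.
#' @param min_probes minimum number of passing probes.
#' @param max_gap maximum gap between consecutive passing probes in bp.
#' @return data.frame `chrom`, `strand`, `start`, `end`, `direction`
#'   (`"up"`/`"down"`), `n_probes`, `mean_log2_fc`.
#' @export
detect_transfrags <- function(stats, fc_thresh = 2, p_thresh = 0.05,
                              min_len = 80, min_probes = 10,
                              max_gap = 48) {
  lfc <- log2(fc_thresh)
  pass <- abs(stats$log2_fc) >= lfc & stats$p <= p_thresh
  key <- paste(stats$chrom, stats$strand)
  out <- list()
  for (grp in unique(key)) {
    idx <- which(key == grp & pass)
    if (!length(idx)) next
    pos <- stats$pos[idx]
    sgn <- sign(stats$log2_fc[idx])
    brk <- c(TRUE, diff(pos) > max_gap | sgn[-1] != sgn[-length(sgn)])
    run <- cumsum(brk)
    for (r in unique(run)) {
      ii <- idx[run == r]
      span <- stats$pos[ii[length(ii)]] - stats$pos[ii[1]] + 1L
      if (span < min_len || length(ii) < min_probes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = stats$chrom[ii[1]], strand = stats$strand[ii[1]],
        start = stats$pos[ii[1]], end = stats$pos[ii[length(ii)]],
        direction = if (sgn[run == r][1] > 0) "up" else "down",
        n_probes = length(ii),
        mean_log2_fc = mean(stats$log2_fc[ii]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_transfrags()
  rownames(res) <- NULL
  res[order(res$chrom, res$strand, res$start), ]
}

empty_transfrags <- function() {
  data.frame(chrom = character(), strand = character(), start = integer(),
             end = integer(), direction = character(),
             n_probes = integer(), mean_log2_fc = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge neighboring transfrags
#'
#' Two adjacent transfrags merge when all four criteria hold: (i) gap at
#' most `max_gap` bp; (ii) same strand; (iii) same direction of change;
#' (iv) every intervening probe shows an expression change of the same
#' sign.  Merging iterates to a fixed point; merged bounds are the
#' enclosing interval, and probe counts / mean fold changes are
#' recomputed over the merged span.
#'
#' @param tf a [detect_transfrags()] result.
#' @param stats the [probe_stats()] the transfrags came from.
#' @param max_gap maximum merge gap in bp.
#' @return merged transfrag data.frame.
#' @export
merge_transfrags <- function(tf, stats, max_gap = 250) {
  if (nrow(tf) < 2L) return(tf)
  repeat {
    tf <- tf[order(tf$chrom, tf$strand, tf$start), , drop = FALSE]
    merged_any <- FALSE
    keep <- rep(TRUE, nrow(tf))
    i <- 1L
    while (i < nrow(tf)) {
      a <- tf[i, ]
      b <- tf[i + 1L, ]
      ok <- a$chrom == b$chrom && a$strand == b$strand &&
        a$direction == b$direction &&
        (b$start - a$end - 1L) <= max_gap && b$start > a$end
      if (ok) {
        between <- stats$chrom == a$chrom & stats$strand == a$strand &
          stats$pos > a$end & stats$pos < b$start
        dsgn <- if (a$direction == "up") 1 else -1
        ok <- all(sign(stats$log2_fc[between]) == dsgn)
      }
      if (ok) {
        tf$end[i] <- b$end
        tf$n_probes[i] <- a$n_probes + b$n_probes
        tf$mean_log2_fc[i] <-
          (a$mean_log2_fc * a$n_probes + b$mean_log2_fc * b$n_probes) /
          (a$n_probes + b$n_probes)
        keep[i + 1L] <- FALSE
        tf <- tf[keep | seq_len(nrow(tf)) != i + 1L, , drop = FALSE]
        keep <- rep(TRUE, nrow(tf))
        merged_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  rownames(tf) <- NULL
  tf
}

#' Remove transfrags overlapping annotation on the same strand
#'
#' A transfrag is dropped when the union of its same-strand overlaps with
#' annotated features exceeds `max_overlap_frac` of its own length
#' (strictly more than).
#'
#' @param tf transfrag data.frame.
#' @param annotation feature table with `chrom`, `start`, `end`, `strand`.
#' @param max_overlap_frac maximum tolerated overlap fraction.
#' @return the retained transfrags.
#' @export
filter_annotated <- function(tf, annotation, max_overlap_frac = 0.20) {
  if (!nrow(tf)) return(tf)
  keep <- vapply(seq_len(nrow(tf)), function(i) {
    len <- tf$end[i] - tf$start[i] + 1L
    ann <- annotation[annotation$chrom == tf$chrom[i] &
                        annotation$strand == tf$strand[i], , drop = FALSE]
    if (!nrow(ann)) return(TRUE)
    ir <- IRanges::IRanges(start = ann$start, end = ann$end)
    hit <- IRanges::restrict(IRanges::reduce(ir), start = tf$start[i],
                             end = tf$end[i])
    ov <- sum(IRanges::width(hit))
    ov <= max_overlap_frac * len
  }, logical(1))
  tf[keep, , drop = FALSE]
}

# 5' end of a stranded interval.
five_prime <- function(start, end, strand) {
  ifelse(strand == "+", start, end)
}

#' Classify transfrags by orientation relative to genes
#'
#' Priority order: a transfrag overlapping a gene on the opposite strand
#' is `intragenic-antisense`.  Otherwise genes within `flank` bp of the
#' transfrag's 5' end are examined nearest-first: for an opposite-strand
#' gene whose TSS-proximal end faces the transfrag the class is
#' `diverging` (shared upstream region); for an opposite-strand gene whose
#' TES-proximal end faces it, `converging` when the transfrag is
#' transcribed toward the gene and `tandem-antisense` otherwise; a
#' same-strand gene whose TES lies upstream of the transfrag's 5' end
#' gives `tandem-sense`.  Transfrags matching no rule are `unclassified`.
#'
#' @param tf transfrag data.frame.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`).
#' @param flank search radius around the transfrag 5' end in bp.
#' @return transfrags with an added `orientation_class` column.
#' @export
classify_transfrags <- function(tf, genes, flank = 3000) {
  tf$orientation_class <- "unclassified"
  if (!nrow(tf)) return(tf)
  for (i in seq_len(nrow(tf))) {
    gg <- genes[genes$chrom == tf$chrom[i], , drop = FALSE]
    if (!nrow(gg)) next
    anti <- gg$strand != tf$strand[i] & gg$start <= tf$end[i] &
      gg$end >= tf$start[i]
    if (any(anti)) {
      tf$orientation_class[i] <- "intragenic-antisense"
      next
    }
    p5 <- five_prime(tf$start[i], tf$end[i], tf$strand[i])
    d <- ifelse(p5 < gg$start, gg$start - p5,
                ifelse(p5 > gg$end, p5 - gg$end, 0L))
    cand <- order(d)[d[order(d)] <= flank]
    tdir <- strand_dir(tf$strand[i])
    for (j in cand) {
      g <- gg[j, ]
      if (g$strand != tf$strand[i]) {
        d_tss <- abs(p5 - g$tss)
        d_tes <- abs(p5 - g$tes)
        if (d_tss <= d_tes) {
          tf$orientation_class[i] <- "diverging"
        } else {
          toward <- sign(g$tes - p5) == tdir
          tf$orientation_class[i] <-
            if (toward) "converging" else "tandem-antisense"
        }
        break
      } else {
        downstream_of_tes <- (p5 - g$tes) * strand_dir(g$strand) > 0
        if (downstream_of_tes) {
          tf$orientation_class[i] <- "tandem-sense"
          break
        }
        # same-strand gene not upstream: uninformative, try next gene
      }
    }
  }
  tf
}

#' Non-redundant union of transfrag sets across conditions
#'
#' Collapses same-strand overlapping transfrags from multiple conditions
#' into their interval union and reports each condition's mean log2 fold
#' change over every union region (`NA` where a condition contributed no
#' transfrag).
#'
#' @param tf_list named list of transfrag data.frames, one per condition.
#' @return data.frame `chrom`, `strand`, `start`, `end`, `n_conditions`,
#'   plus one `fc_<condition>` column per input set.
#' @export
union_regions <- function(tf_list) {
  stopifnot(length(tf_list) >= 1)
  if (is.null(names(tf_list)))
    names(tf_list) <- paste0("cond", seq_along(tf_list))
  all_tf <- do.call(rbind, lapply(names(tf_list), function(nm) {
    x <- tf_list[[nm]]
    if (!nrow(x)) return(NULL)
    x$condition <- nm
    x
  }))
  if (is.null(all_tf))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_conditions = integer()))
  out <- list()
  for (grp in unique(paste(all_tf$chrom, all_tf$strand))) {
    sel <- paste(all_tf$chrom, all_tf$strand) == grp
    x <- all_tf[sel, , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(start = x$start, end = x$end))
    for (k in seq_along(red)) {
      s <- IRanges::start(red)[k]
      e <- IRanges::end(red)[k]
      inreg <- x$start <= e & x$end >= s
      row <- data.frame(chrom = x$chrom[1], strand = x$strand[1],
                        start = s, end = e,
                        n_conditions = length(unique(x$condition[inreg])),
                        stringsAsFactors = FALSE)
      for (nm in names(tf_list)) {
        v <- x$mean_log2_fc[inreg & x$condition == nm]
        row[[paste0("fc_", nm)]] <- if (length(v)) mean(v) else NA_real_
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$strand, res$start), ]
}
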