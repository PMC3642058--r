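#' Match reference calls to condition calls and compute displacements
#'
#' Each reference (wild-type) center is matched to the nearest condition
#' center within `window` bp; equidistant ties resolve to the preferred
#' side.  Reference centers with no condition call in the window are
#' returned with `NA` (missing).
#'
#' @param ref_centers,cond_centers numeric center positions on one
#'   chromosome.
#' @param window matching half-window in bp.
#' @param prefer `"left"` or `"right"`: which side wins an equidistant tie.
#' @return data.frame `ref`, `cond` (matched position or `NA`), `delta`
#'   (`cond - ref`, chromosome orientation).
#' @export
match_shift <- function(ref_centers, cond_centers, window = 100,
                        prefer = c("left", "right")) {
  prefer <- match.arg(prefer)
  cond <- sort(cond_centers)
  n <- length(cond)
  matched <- rep(NA_real_, length(ref_centers))
  if (n > 0L) {
    j <- findInterval(ref_centers, cond)
    for (i in seq_along(ref_centers)) {
      lo <- j[i]
      hi <- lo + 1L
      dl <- if (lo >= 1L) ref_centers[i] - cond[lo] else Inf
      dr <- if (hi <= n) cond[hi] - ref_centers[i] else Inf
      pick <- if (dl < dr) lo
      else if (dr < dl) hi
      else if (prefer == "left") lo else hi
      d <- min(dl, dr)
      if (is.finite(d) && d <= window) matched[i] <- cond[pick]
    }
  }
  data.frame(ref = ref_centers, cond = matched,
             delta = matched - ref_centers)
}

#' Build per-nucleosome shift records against a wild-type panel
#'
#' For every genic wild-type call, matches the nearest condition call in
#' each replicate (within `window` bp, ties toward the TSS) and the nearest
#' call in each wild-type panel condition.  Deltas are strand-aware: a
#' positive shift moves the nucleosome away from the TSS.
#'
#' @param wt_genic genic calls of the wild-type reference
#'   ([assign_genic()] output).
#' @param cond_call_list list of call data.frames, one per condition
#'   replicate.
#' @param panel_call_list list of call data.frames, one per wild-type
#'   panel condition.
#' @param window matching half-window in bp.
#' @return data.frame with one row per genic wild-type nucleosome:
#'   `gene_id`, `index`, `chrom`, `strand`, `wt_center`, per-replicate
#'   matched centers (`cond_center_r*`) and signed deltas (`delta_r*`),
#'   `delta` (replicate mean), `n_panel`, and list-column
#'   `panel_positions`.
#' @export
shift_records <- function(wt_genic, cond_call_list, panel_call_list,
                          window = 100) {
  stopifnot(nrow(wt_genic) > 0, length(cond_call_list) >= 1)
  nrep <- length(cond_call_list)
  recs <- wt_genic[, c("gene_id", "index", "chrom", "strand")]
  recs$wt_center <- wt_genic$center
  dir <- strand_dir(wt_genic$strand)
  # equidistant ties resolve toward the TSS: leftward for "+" genes
  prefer <- ifelse(wt_genic$strand == "+", "left", "right")

  match_one <- function(calls) {
    kept <- calls[calls$retained, , drop = FALSE]
    res <- rep(NA_real_, nrow(wt_genic))
    for (ch in unique(wt_genic$chrom)) {
      wi <- which(wt_genic$chrom == ch)
      cc <- kept$center[kept$chrom == ch]
      for (pref in c("left", "right")) {
        sel <- wi[prefer[wi] == pref]
        if (!length(sel)) next
        m <- match_shift(wt_genic$center[sel], cc, window = window,
                         prefer = pref)
        res[sel] <- m$cond
      }
    }
    res
  }

  for (r in seq_len(nrep)) {
    cc <- match_one(cond_call_list[[r]])
    recs[[paste0("cond_center_r", r)]] <- cc
    recs[[paste0("delta_r", r)]] <- (cc - wt_genic$center) * dir
  }
  dmat <- as.matrix(recs[, paste0("delta_r", seq_len(nrep)), drop = FALSE])
  recs$delta <- rowMeans(dmat)

  panel <- lapply(panel_call_list, match_one)
  pmat <- do.call(cbind, panel)
  recs$n_panel <- rowSums(!is.na(pmat))
  recs$panel_positions <- lapply(seq_len(nrow(pmat)), function(i) {
    v <- pmat[i, ]
    v[!is.na(v)]
  })
  recs
}

# Pooled-variance two-sample t-test p-value with the panel sd floored at
# `floor_y` bp.  The replicate group has only 2 observations, so pooling
# borrows the panel's degrees of freedom (a Welch test would be left with
# ~1 df and no power); degenerate zero-variance panels are caught by the
# sd floor.
pooled_t_p <- function(x, y, floor_y = 1) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) return(NA_real_)
  vy <- max(stats::var(y), floor_y^2)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * vy) / (nx + ny - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tval), nx + ny - 2)
}

#' Flag significantly shifted nucleosomes
#'
#' A nucleosome is significant when every replicate moved by at least
#' `min_shift` bp in the same direction, and a two-sample t-test (pooled
#' variance, with the panel sd floored at 1 bp) of the replicate center
#' positions against the wild-type panel positions gives p < `alpha`.
#' Records with fewer than `min_panel` panel positions are flagged
#' untestable (never significant).
#'
#' @param records a [shift_records()] result.
#' @param min_shift minimum per-replicate |delta| in bp.
#' @param alpha significance level.
#' @param min_panel minimum panel size for the test.
#' @return records with added `p_value`, `significant`, `untestable`.
#' @export
shift_significance <- function(records, min_shift = 10, alpha = 0.05,
                               min_panel = 3L) {
  nrep <- sum(grepl("^delta_r", names(records)))
  dmat <- as.matrix(records[, paste0("delta_r", seq_len(nrep)),
                            drop = FALSE])
  cmat <- as.matrix(records[, paste0("cond_center_r", seq_len(nrep)),
                            drop = FALSE])
  complete <- rowSums(is.na(dmat)) == 0L
  big <- complete & rowSums(abs(dmat) >= min_shift) == nrep
  same_sign <- complete &
    (rowSums(dmat > 0) == nrep | rowSums(dmat < 0) == nrep)
  records$untestable <- records$n_panel < min_panel | !complete
  records$p_value <- NA_real_
  test_idx <- which(!records$untestable & big & same_sign)
  for (i in test_idx) {
    records$p_value[i] <- pooled_t_p(cmat[i, ],
                                     records$panel_positions[[i]])
  }
  records$significant <- !records$untestable & big & same_sign &
    !is.na(records$p_value) & records$p_value < alpha
  records
}

#' Per-genic-position shift summaries
#'
#' Median and quartiles of the (replicate-mean) shift at each genic
#' nucleosome index, over all genes with a matched nucleosome there.
#'
#' @param records a [shift_records()] result.
#' @param max_index largest genic index summarized (more distal positions
#'   are sparse).
#' @return data.frame `index`, `n`, `q1`, `median`, `q3`.
#' @export
position_summary <- function(records, max_index = 8L) {
  keep <- !is.na(records$delta) & records$index <= max_index
  r <- records[keep, , drop = FALSE]
  idx <- sort(unique(r$index))
  out <- lapply(idx, function(i) {
    d <- r$delta[r$index == i]
    q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(index = i, n = length(d), q1 = q[1], median = q[2],
               q3 = q[3])
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(index = integer(), n = integer(), q1 = numeric(),
                      median = numeric(), q3 = numeric())
  res
}

#' Flag a condition with a nucleosome-shift phenotype
#'
#' A condition is flagged when any genic position has an absolute median
#' shift of at least `threshold` bp.
#'
#' @param summaries a [position_summary()] result.
#' @param threshold median shift threshold in bp.
#' @return logical flag.
#' @export
flag_condition <- function(summaries, threshold = 4) {
  nrow(summaries) > 0 && any(abs(summaries$median) >= threshold)
}

#' Shift propagation profiles around a focal genic position
#'
#' Genes are grouped by the status of their nucleosome at the focal index
#' (significant positive shift, significant negative shift, or no
#' significant shift), and the mean shift with a normal-approximation 95%
#' confidence interval is reported at every genic index within each group
#' — revealing whether a local shift propagates along the array.
#'
#' @param records a [shift_significance()] result.
#' @param focal_index the genic index defining the grouping.
#' @param max_index largest index profiled.
#' @return data.frame `group`, `index`, `n`, `mean`, `lo`, `hi` (CI bounds
#'   `NA` when n < 2).
#' @export
neighbor_profiles <- function(records, focal_index, max_index = 8L) {
  foc <- records[records$index == focal_index, , drop = FALSE]
  status <- ifelse(!foc$significant, "none",
                   ifelse(foc$delta > 0, "positive", "negative"))
  grp <- stats::setNames(status, foc$gene_id)
  r <- records[records$gene_id %in% names(grp) &
                 records$index <= max_index & !is.na(records$delta), ,
               drop = FALSE]
  r$group <- grp[r$gene_id]
  out <- list()
  for (g in c("positive", "negative", "none")) {
    for (i in sort(unique(r$index))) {
      d <- r$delta[r$group == g & r$index == i]
      if (!length(d)) next
      m <- mean(d)
      if (length(d) >= 2L) {
        se <- sd(d) / sqrt(length(d))
        lo <- m - 1.96 * se
        hi <- m + 1.96 * se
      } else lo <- hi <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        group = g, index = i, n = length(d), mean = m, lo = lo, hi = hi)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group = character(), index = integer(),
                      n = integer(), mean = numeric(), lo = numeric(),
                      hi = numeric())
  res
}

#' Sliding-window mean curve with 95% confidence band
#'
#' At each offset, the mean and normal-approximation 95% CI of all values
#' whose offsets fall within `bandwidth` bp.  Offsets whose window is
#' empty produce a gap (no row).
#'
#' @param offsets bp offsets of the observations.
#' @param values observed values.
#' @param bandwidth window half-width in bp.
#' @param at offsets at which to evaluate (default: every integer offset
#'   spanned by the data).
#' @return data.frame `offset`, `n`, `mean`, `lo`, `hi`.
#' @export
smoothed_profile <- function(offsets, values, bandwidth = 25, at = NULL) {
  stopifnot(length(offsets) == length(values))
  if (diff(range(offsets)) < bandwidth)
    stop("offsets must span at least the bandwidth", call. = FALSE)
  at <- at %||% seq(min(offsets), max(offsets))
  o <- order(offsets)
  offsets <- offsets[o]
  values <- values[o]
  lo_i <- findInterval(at - bandwidth, offsets, left.open = TRUE) + 1L
  hi_i <- findInterval(at + bandwidth, offsets)
  keep <- hi_i >= lo_i
  out <- lapply(which(keep), function(k) {
    v <- values[lo_i[k]:hi_i[k]]
    m <- mean(v)
    se <- if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_
    data.frame(offset = at[k], n = length(v), mean = m,
               lo = m - 1.96 * se, hi = m + 1.96 * se)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(offset = numeric(), n = integer(), mean = numeric(),
                      lo = numeric(), hi = numeric())
  res
}
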