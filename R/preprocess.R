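#' Quantile-normalize probe intensities across samples
#'
#' Forces every sample column onto the identical value distribution (the
#' per-rank mean across samples), preserving within-sample ranks; ties are
#' averaged.  This is the standard first step for tiling arrays hybridized
#' in a common batch.
#'
#' @param probes a `probe_matrix` (data.frame with `chrom`, `pos`, `strand`
#'   and one or more intensity columns).
#' @param cols which columns to normalize; defaults to every column that is
#'   not a coordinate column.
#' @return the probe matrix with normalized intensity columns.
#' @export
quantile_normalize <- function(probes, cols = NULL) {
  cols <- cols %||% setdiff(names(probes), c("chrom", "pos", "strand"))
  if (length(cols) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(probes)
  }
  m <- as.matrix(probes[, cols])
  if (!all(is.finite(m))) stop("non-finite intensities", call. = FALSE)
  probes[, cols] <- limma::normalizeQuantiles(m, ties = TRUE)
  probes
}

#' Median-smooth a track over a genomic bandwidth
#'
#' Replaces the value at each probe by the median of all probe values within
#' `bandwidth` bp on either side (truncated at track edges).  Smoothing is
#' applied independently per chromosome (and per strand, if present).
#'
#' @param probes a `probe_matrix` or track data.frame on a uniform grid.
#' @param bandwidth half-window in bp; must be at least the grid step.
#' @param cols value columns to smooth (default: all non-coordinate).
#' @return smoothed data of the same shape.
#' @export
median_smooth <- function(probes, bandwidth = 30, cols = NULL) {
  if (nrow(probes) == 0L) return(probes)
  cols <- cols %||% setdiff(names(probes), c("chrom", "pos", "strand"))
  key <- if ("strand" %in% names(probes))
    paste(probes$chrom, probes$strand) else probes$chrom
  for (grp in unique(key)) {
    idx <- which(key == grp)
    step <- grid_step(probes$pos[idx])
    if (bandwidth < step)
      stop("bandwidth must be >= the grid step (", step, " bp)",
           call. = FALSE)
    half <- floor(bandwidth / step)
    for (cl in cols)
      probes[[cl]][idx] <- running_median(probes[[cl]][idx], half)
  }
  probes
}

grid_step <- function(pos) {
  if (length(pos) < 2L) return(1L)
  s <- diff(pos[1:2])
  s
}

#' Rescale samples to a common data range
#'
#' Affinely maps each sample so its 1st and 99th percentiles coincide with
#' the cross-sample mean of those percentiles.  Order within each sample is
#' preserved; a degenerate sample (no spread between the anchor
#' percentiles) is left untouched with a warning.
#'
#' @param probes a `probe_matrix`.
#' @param cols value columns (default: all non-coordinate).
#' @param probs the two anchor quantiles.
#' @return the rescaled probe matrix.
#' @export
rescale_common_range <- function(probes, cols = NULL,
                                 probs = c(0.01, 0.99)) {
  cols <- cols %||% setdiff(names(probes), c("chrom", "pos", "strand"))
  if (length(cols) < 2L) {
    warning("rescaling needs >= 2 samples; returning input")
    return(probes)
  }
  q <- vapply(cols, function(cl) quantile(probes[[cl]], probs, names = FALSE),
              numeric(2))
  target <- rowMeans(q)
  for (i in seq_along(cols)) {
    span <- q[2, i] - q[1, i]
    if (span <= 0) {
      warning("sample '", cols[i], "' has zero spread; left unscaled")
      next
    }
    probes[[cols[i]]] <- (probes[[cols[i]]] - q[1, i]) *
      (target[2] - target[1]) / span + target[1]
  }
  probes
}

#' Remove slow baseline variation with a running median
#'
#' Subtracts a running median taken over a wide genomic window (default
#' 5 kb) so that only features narrower than the window — nucleosome-scale
#' structure — survive, while chromosome-scale drifts in the baseline are
#' removed.
#'
#' @param track a track data.frame (`chrom`, `pos`, value columns).
#' @param window full window width in bp; must be >= 10 x the grid step.
#' @param cols value columns (default: all non-coordinate).
#' @return the detrended track.
#' @export
detrend_baseline <- function(track, window = 5000, cols = NULL) {
  if (nrow(track) == 0L) return(track)
  cols <- cols %||% setdiff(names(track), c("chrom", "pos", "strand"))
  key <- if ("strand" %in% names(track))
    paste(track$chrom, track$strand) else track$chrom
  for (grp in unique(key)) {
    idx <- which(key == grp)
    step <- grid_step(track$pos[idx])
    if (window < 10 * step)
      stop("window must be >= 10 x the grid step", call. = FALSE)
    half <- floor(window / 2 / step)
    for (cl in cols)
      track[[cl]][idx] <- track[[cl]][idx] -
        running_median(track[[cl]][idx], half)
  }
  track
}

#' Per-position log2 sample/control ratio
#'
#' @param probes a `probe_matrix` holding both columns.
#' @param sample_col,control_col column names.
#' @param value_col name of the output column.
#' @return a track data.frame (`chrom`, `pos`, `strand` if present,
#'   `value`) with `value = log2(sample/control)`.
#' @export
log_ratio <- function(probes, sample_col, control_col,
                      value_col = "value") {
  s <- probes[[sample_col]]
  ctl <- probes[[control_col]]
  bad <- which(ctl <= 0)
  if (length(bad))
    stop("nonpositive control intensity at ", probes$chrom[bad[1]], ":",
         probes$pos[bad[1]], call. = FALSE)
  out <- probes[, intersect(c("chrom", "pos", "strand"), names(probes)),
                drop = FALSE]
  out[[value_col]] <- log2(s / ctl)
  out
}

#' Bin fragment midpoints onto a uniform grid
#'
#' The midpoint of each paired-end mononucleosome fragment estimates a
#' nucleosome center; this counts rounded midpoints at the nearest grid
#' position.  Total fragment count is preserved (midpoints beyond the ends
#' are clamped to the terminal grid positions).  Malformed pairs
#' (`end < start`) are skipped and reported via the `n_skipped` attribute.
#'
#' @param pairs data.frame `chrom`, `start`, `end` (1-based closed).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param step grid step in bp.
#' @return a track data.frame `chrom`, `pos`, `value` (counts), with
#'   attribute `n_skipped`.
#' @export
midpoint_track <- function(pairs, chrom_lengths, step = 1) {
  bad <- pairs$end < pairs$start
  n_skipped <- sum(bad)
  if (n_skipped) pairs <- pairs[!bad, , drop = FALSE]
  out <- lapply(names(chrom_lengths), function(ch) {
    grid <- seq.int(step, chrom_lengths[[ch]], by = step)
    pp <- pairs[pairs$chrom == ch, , drop = FALSE]
    counts <- integer(length(grid))
    if (nrow(pp)) {
      mid <- round((pp$start + pp$end) / 2)
      idx <- pmin(length(grid), pmax(1L, as.integer(round(mid / step))))
      tab <- tabulate(idx, nbins = length(grid))
      counts <- tab
    }
    data.frame(chrom = ch, pos = grid, value = counts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Array-mode preprocessing chain
#'
#' Runs the full tiling-array normalization on a simulated or imported
#' probe matrix: quantile normalization across all sample and control
#' columns, 30-bp median smoothing, rescaling to a common data range,
#' per-replicate log2 sample/control ratio, and 5-kb running-median
#' baseline removal of the ratio track.
#'
#' @param probes a `probe_matrix` with `sample_cols`/`control_cols`
#'   attributes (as produced by [simulate_occupancy()]), or pass the column
#'   names explicitly.
#' @param sample_cols,control_cols intensity column names.  Every sample
#'   replicate is ratioed against the mean of the control columns.
#' @param bandwidth median-smoothing half-window (bp).
#' @param baseline_window baseline-removal window (bp).
#' @param average if `TRUE` also return the replicate-averaged track in
#'   column `value`.
#' @return a track data.frame with one occupancy column per replicate
#'   (`occ_rep1..n`) and, if `average`, their mean in `value`.
#' @export
preprocess_array <- function(probes, sample_cols = NULL, control_cols = NULL,
                             bandwidth = 30, baseline_window = 5000,
                             average = TRUE) {
  sample_cols <- sample_cols %||% attr(probes, "sample_cols")
  control_cols <- control_cols %||% attr(probes, "control_cols")
  stopifnot(!is.null(sample_cols), !is.null(control_cols))
  allcols <- c(sample_cols, control_cols)
  probes <- quantile_normalize(probes, cols = allcols)
  probes <- median_smooth(probes, bandwidth = bandwidth, cols = allcols)
  # rescale within array groups: sample and control hybridizations have
  # genuinely different value distributions, so each group is brought to
  # its own common range
  if (length(sample_cols) >= 2L)
    probes <- rescale_common_range(probes, cols = sample_cols)
  if (length(control_cols) >= 2L)
    probes <- rescale_common_range(probes, cols = control_cols)
  out <- probes[, intersect(c("chrom", "pos", "strand"), names(probes)),
                drop = FALSE]
  probes$.ctrl_mean <-
    rowMeans(as.matrix(probes[, control_cols, drop = FALSE]))
  for (i in seq_along(sample_cols)) {
    rc <- log_ratio(probes, sample_cols[i], ".ctrl_mean")
    out[[paste0("occ_rep", i)]] <- rc$value
  }
  occ_cols <- paste0("occ_rep", seq_along(sample_cols))
  out <- detrend_baseline(out, window = baseline_window, cols = occ_cols)
  if (average)
    out$value <- rowMeans(as.matrix(out[, occ_cols, drop = FALSE]))
  out
}

#' Sequencing-mode occupancy track from fragment midpoints
#'
#' Converts binned midpoint counts into a log2 occupancy track comparable
#' to the array mode: `log2((count + pseudocount) / (control +
#' pseudocount))`, where the control defaults to the genome-wide mean
#' count (flat coverage expectation).
#'
#' @param counts a [midpoint_track()] result.
#' @param control optional matching track of control counts.
#' @param pseudocount added to both numerator and denominator.
#' @return a track data.frame with a log2 `value` column.
#' @export
seq_occupancy <- function(counts, control = NULL, pseudocount = 1) {
  ctl <- if (is.null(control)) rep(mean(counts$value), nrow(counts))
  else control$value
  out <- counts
  out$value <- log2((counts$value + pseudocount) / (ctl + pseudocount))
  out
}

#' Occupancy change track (condition minus wild type)
#'
#' @param cond,wt tracks on the identical grid with a `value` column.
#' @return a track whose `value` is the per-position difference of log2
#'   occupancies.
#' @export
occupancy_change <- function(cond, wt) {
  stopifnot(nrow(cond) == nrow(wt), all(cond$pos == wt$pos),
            all(cond$chrom == wt$chrom))
  out <- cond[, intersect(c("chrom", "pos", "strand"), names(cond)),
              drop = FALSE]
  out$value <- cond$value - wt$value
  out
}
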