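#' Discretized Gaussian smoothing kernel
#'
#' The peak-calling filter: a normal density with mean zero discretized on
#' the track's grid, truncated at `half_support` bp and renormalized to
#' unit sum.
#'
#' @param sd kernel standard deviation in bp.
#' @param half_support truncation half-width in bp (must be >= `sd`).
#' @param step grid step in bp.
#' @return list with `offsets` (bp) and `weights` (sum to 1).
#' @export
gaussian_kernel <- function(sd = 25, half_support = 50, step = 1) {
  stopifnot(sd > 0, half_support >= sd, step >= 1, step <= half_support)
  h <- floor(half_support / step)
  offsets <- seq.int(-h, h) * step
  w <- dnorm(offsets, 0, sd)
  list(offsets = offsets, weights = w / sum(w))
}

# Truncated, edge-renormalized convolution of x with symmetric weights w.
conv_truncated <- function(x, w) {
  h <- (length(w) - 1L) %/% 2L
  n <- length(x)
  if (h == 0L || n == 0L) return(x)
  xp <- c(rep(0, h), x, rep(0, h))
  mp <- c(rep(0, h), rep(1, n), rep(0, h))
  num <- stats::filter(xp, w, sides = 2)[(h + 1L):(h + n)]
  den <- stats::filter(mp, w, sides = 2)[(h + 1L):(h + n)]
  as.numeric(num / den)
}

#' Gaussian-filter score of an occupancy track
#'
#' Convolves the occupancy values with a discretized Gaussian (default sd
#' 25 bp, support +/-50 bp); at track edges the kernel is truncated and
#' renormalized.  Local maxima of this score are candidate nucleosome
#' centers.
#'
#' @param track track data.frame (`chrom`, `pos`, value column).
#' @param sd,half_support kernel parameters in bp.
#' @param value_col input column name.
#' @return the track with an added `score` column.
#' @export
gaussian_score <- function(track, sd = 25, half_support = 50,
                           value_col = "value") {
  track$score <- NA_real_
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    step <- grid_step(track$pos[idx])
    k <- gaussian_kernel(sd, half_support, step)
    track$score[idx] <- conv_truncated(track[[value_col]][idx], k$weights)
  }
  track
}

# Interior local maxima of v: strictly greater than both flanking values,
# with plateaus represented by their leftmost point.  Returns indices.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 3L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(nr - 1L)
  cand <- j[r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]]
  starts[cand]
}

#' Call nucleosome centers by sequential maxima of the Gaussian score
#'
#' Greedy peak assignment: repeatedly take the highest remaining local
#' maximum of the score whose position is more than `min_separation` bp
#' from every already-called center, until no candidate remains.  Ties in
#' score break to the leftmost coordinate.
#'
#' @param scored a [gaussian_score()] result (needs a `score` column).
#' @param min_separation exclusion radius in bp.
#' @return data.frame of calls: `chrom`, `center`, `score`,
#'   `retained` (all `TRUE`; see [filter_low_scores()]).
#' @export
call_positions <- function(scored, min_separation = 100) {
  out <- lapply(unique(scored$chrom), function(ch) {
    idx <- which(scored$chrom == ch)
    v <- scored$score[idx]
    pos <- scored$pos[idx]
    cand <- local_maxima(v)
    if (!length(cand)) return(NULL)
    ord <- cand[order(-v[cand], pos[cand])]
    # one accepted center can occupy a cell of width min_separation, so
    # only adjacent cells need checking
    m <- as.integer(min_separation)
    ncell <- max(pos) %/% m + 2L
    cellpos <- rep(NA_integer_, ncell)
    acc <- integer(0)
    for (i in ord) {
      p <- pos[i]
      cell <- p %/% m + 1L
      near <- cellpos[max(1L, cell - 1L):min(ncell, cell + 1L)]
      near <- near[!is.na(near)]
      if (length(near) && any(abs(near - p) <= m)) next
      cellpos[cell] <- p
      acc <- c(acc, i)
    }
    acc <- acc[order(pos[acc])]
    data.frame(chrom = ch, center = pos[acc], score = v[acc],
               retained = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), center = integer(),
                      score = numeric(), retained = logical())
  rownames(res) <- NULL
  res
}

#' Exclude the lowest-scoring fraction of calls
#'
#' Marks the `floor(fraction * N)` calls with the lowest Gaussian score as
#' not retained, pooled globally over the whole call set.  Ties at the
#' cutoff are resolved by excluding the leftmost call first.
#'
#' @param calls a [call_positions()] result.
#' @param fraction fraction to exclude, in \[0, 1).
#' @return calls with updated `retained` flags.
#' @export
filter_low_scores <- function(calls, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 1)
  n_excl <- floor(fraction * nrow(calls))
  calls$retained <- TRUE
  if (n_excl > 0) {
    ord <- order(calls$score, calls$chrom, calls$center)
    calls$retained[ord[seq_len(n_excl)]] <- FALSE
  }
  calls
}

#' Number retained calls relative to gene TSSs
#'
#' For each gene, retained calls whose center lies strictly downstream of
#' the TSS (strand-aware) and no further than 100 bp past the TES are
#' numbered +1, +2, ... by increasing distance from the TSS.  A call may
#' serve two genes that overlap on opposite strands.  Genes without any
#' qualifying call simply contribute no rows.
#'
#' @param calls a call data.frame with `retained` flags.
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @param past_tes how far beyond the TES a call may lie (bp).
#' @return data.frame: `gene_id`, `index`, `chrom`, `center`, `score`,
#'   `strand`, `dist` (strand-aware bp from the TSS).
#' @export
assign_genic <- function(calls, genes, past_tes = 100) {
  kept <- calls[calls$retained, , drop = FALSE]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cc <- kept[kept$chrom == g$chrom, , drop = FALSE]
    if (!nrow(cc)) next
    d <- (cc$center - g$tss) * strand_dir(g$strand)
    lim <- abs(g$tes - g$tss) + past_tes
    sel <- d > 0 & d <= lim
    if (!any(sel)) next
    cc <- cc[sel, , drop = FALSE]
    d <- d[sel]
    o <- order(d)
    out[[i]] <- data.frame(
      gene_id = g$gene_id, index = seq_along(o), chrom = g$chrom,
      center = cc$center[o], score = cc$score[o], strand = g$strand,
      dist = d[o], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), index = integer(),
                      chrom = character(), center = integer(),
                      score = numeric(), strand = character(),
                      dist = integer())
  rownames(res) <- NULL
  res
}

#' Full occupancy-to-calls chain
#'
#' Gaussian scoring, sequential peak calling and low-score exclusion in
#' one step.
#'
#' @param track occupancy track (`chrom`, `pos`, value column).
#' @param sd,half_support kernel parameters (bp).
#' @param min_separation exclusion radius (bp).
#' @param score_fraction fraction of lowest-score calls to drop.
#' @param value_col value column name.
#' @return call data.frame as from [filter_low_scores()].
#' @export
call_nucleosomes <- function(track, sd = 25, half_support = 50,
                             min_separation = 100, score_fraction = 0.10,
                             value_col = "value") {
  scored <- gaussian_score(track, sd = sd, half_support = half_support,
                           value_col = value_col)
  calls <- call_positions(scored, min_separation = min_separation)
  filter_low_scores(calls, fraction = score_fraction)
}
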