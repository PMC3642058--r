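# Independent reference implementations used as oracles.  These are kept
# deliberately naive (direct loops, exhaustive enumeration) and must stay
# independent of the package code paths they check.

# O(n*k) direct convolution with edge truncation + renormalization.
brute_force_conv <- function(x, offsets_idx, weights) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- i + offsets_idx
    ok <- j >= 1 & j <= n
    sum(weights[ok] * x[j[ok]]) / sum(weights[ok])
  }, numeric(1))
}

# Exhaustive greedy peak assignment: recompute the full candidate list at
# every step and take the globally best remaining local maximum that is
# > min_sep from every accepted center (ties to the leftmost position).
reference_call_positions <- function(pos, score, min_sep = 100) {
  is_max <- logical(length(score))
  for (i in seq_along(score)) {
    if (i == 1L || i == length(score)) next
    # plateau-aware: strictly greater than nearest differing neighbors
    l <- i - 1L
    while (l >= 1L && score[l] == score[i]) l <- l - 1L
    r <- i + 1L
    while (r <= length(score) && score[r] == score[i]) r <- r + 1L
    if (l >= 1L && r <= length(score) &&
        score[i] > score[l] && score[i] > score[r] &&
        (i == 1L || score[i - 1L] != score[i]))  # leftmost of plateau
      is_max[i] <- TRUE
  }
  cand <- which(is_max)
  acc <- integer(0)
  repeat {
    ok <- cand[vapply(cand, function(i)
      !length(acc) || all(abs(pos[acc] - pos[i]) > min_sep), logical(1))]
    if (!length(ok)) break
    best <- ok[order(-score[ok], pos[ok])][1]
    acc <- c(acc, best)
    cand <- setdiff(cand, best)
  }
  sort(pos[acc])
}

# Exact two-sided rank-sum p-value by enumeration of all group
# assignments (valid under ties).  Only for small n + m.
exact_ranksum_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  n <- length(all_v)
  combs <- utils::combn(n, nx)
  W <- colSums(matrix(r[combs], nrow = nx))
  mu <- mean(W)
  obs <- sum(r[seq_len(nx)])
  mean(abs(W - mu) >= abs(obs - mu) - 1e-9)
}

# Small standard genome reused by several test files.
tiny_genome <- function(n_genes = 20, seed = 1, ...) {
  build_genome(genome_spec(n_chromosomes = 1, n_genes = n_genes,
                           seed = seed, ...))
}

# log2 occupancy of a single simulated replicate, with the probe affinity
# cancelled through the matched gDNA column (bypasses preprocessing).
raw_log2_occ <- function(probes, rep = 1) {
  data.frame(chrom = probes$chrom, pos = probes$pos,
             value = log2(probes[[paste0("nuc_rep", rep)]] /
                            probes[[paste0("gdna_rep", rep)]]))
}
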