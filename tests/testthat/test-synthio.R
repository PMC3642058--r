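test_that("genome geometry follows the yeast nucleosome repeat", {
  g <- tiny_genome(n_genes = 10, seed = 7)
  # consecutive genic centers are core + linker = 165 bp apart
  for (gid in unique(na.omit(g$centers$gene_id))) {
    p <- g$centers$pos[!is.na(g$centers$gene_id) & g$centers$gene_id == gid]
    if (length(p) > 1) expect_true(all(abs(diff(p)) == 165))
  }
  # +1 center sits ceiling(147/2) = 74 bp downstream of the TSS
  first <- g$centers[!is.na(g$centers$gene_id) & g$centers$index == 1, ]
  gi <- g$genes[match(first$gene_id, g$genes$gene_id), ]
  expect_true(all(abs(first$pos - gi$tss) == 74))
  # NDR upstream of each TSS holds no centers at all
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    w <- ndr_window(gn$tss, gn$strand, 200)
    expect_false(any(g$centers$chrom == gn$chrom &
                       g$centers$pos >= w$start & g$centers$pos <= w$end))
  }
})

test_that("a 3000-bp gene holds 3000 %/% 165 = 18 nucleosomes", {
  g <- build_genome(genome_spec(n_chromosomes = 1, n_genes = 4,
                                gene_length_mean = 3000,
                                gene_length_sd = 0, seed = 2))
  expect_true(all(g$genes$end - g$genes$start + 1 == 3000))
  counts <- table(na.omit(g$centers$gene_id))
  expect_true(all(counts == 18))
})

test_that("generation is deterministic and truth lies inside the genome", {
  s <- genome_spec(n_chromosomes = 2, n_genes = 12, seed = 5)
  g1 <- build_genome(s)
  g2 <- build_genome(s)
  expect_identical(g1, g2)
  o1 <- simulate_occupancy(g1, noise_sd = 0.3, seed = 9)
  o2 <- simulate_occupancy(g1, noise_sd = 0.3, seed = 9)
  expect_identical(o1, o2)
  p1 <- simulate_readpairs(g1, seed = 9)
  expect_identical(p1, simulate_readpairs(g1, seed = 9))
  tr <- synthetic_truth(g1)
  lens <- g1$chrom_lengths[tr$true_centers$chrom]
  expect_true(all(tr$true_centers$pos >= 1 & tr$true_centers$pos <= lens))
  expect_true(all(p1$start >= 1 & p1$end <= g1$chrom_lengths[p1$chrom]))
})

test_that("infeasible geometry is rejected with a named parameter", {
  expect_error(genome_spec(gene_length_mean = 100), "core_width")
  expect_error(build_genome(genome_spec(n_chromosomes = 1, n_genes = 50,
                                        chrom_length = 10000, seed = 1)),
               "chrom_length")
  expect_error(genome_spec(chrom_length = 1001, probe_spacing = 4),
               "probe_spacing")
})

test_that("noise-free occupancy peaks sit on the true centers", {
  g <- tiny_genome(n_genes = 6, seed = 3)
  o <- simulate_occupancy(g, noise_sd = 0, n_replicates = 1, seed = 1)
  trk <- raw_log2_occ(o)
  genic <- g$centers[!is.na(g$centers$gene_id), ]
  for (i in seq_len(nrow(genic))) {
    sel <- which(abs(trk$pos - genic$pos[i]) <= 60)
    am <- trk$pos[sel][which.max(trk$value[sel])]
    expect_lte(abs(am - genic$pos[i]), 2)  # grid rounding only
  }
})

test_that("an injected +1 shift moves the noise-free argmax by the shift", {
  g <- tiny_genome(n_genes = 6, seed = 3)
  gid <- g$genes$gene_id[1]
  pert <- perturbation_spec(shift_map = data.frame(
    gene_id = gid, index = 1, shift_bp = 16))
  o0 <- simulate_occupancy(g, noise_sd = 0, n_replicates = 1, seed = 1)
  o1 <- simulate_occupancy(g, pert, noise_sd = 0, n_replicates = 1, seed = 1)
  t0 <- raw_log2_occ(o0)
  t1 <- raw_log2_occ(o1)
  cen <- g$centers$pos[!is.na(g$centers$gene_id) &
                         g$centers$gene_id == gid &
                         g$centers$index == 1]
  sel <- which(abs(t0$pos - cen) <= 60)
  a0 <- t0$pos[sel][which.max(t0$value[sel])]
  a1 <- t1$pos[sel][which.max(t1$value[sel])]
  dir <- strand_dir <- if (g$genes$strand[1] == "+") 1 else -1
  expect_lte(abs((a1 - a0) * dir - 16), 4)  # within one probe step
})

test_that("occupancy scaling by 0.5 drops the log2 signal by exactly 1", {
  g <- tiny_genome(n_genes = 4, seed = 3)
  iv <- data.frame(chrom = "chr1", start = 2000, end = 2600, factor = 0.5)
  pert <- perturbation_spec(occupancy_scale = iv)
  o0 <- raw_log2_occ(simulate_occupancy(g, noise_sd = 0, seed = 1))
  o1 <- raw_log2_occ(simulate_occupancy(g, pert, noise_sd = 0, seed = 1))
  sel <- o0$pos >= 2000 & o0$pos <= 2600
  expect_equal(o1$value[sel] - o0$value[sel], rep(-1, sum(sel)),
               tolerance = 1e-12)
  expect_equal(o1$value[!sel], o0$value[!sel], tolerance = 1e-12)
})

test_that("increasing an occupancy scale factor never lowers the signal", {
  g <- tiny_genome(n_genes = 4, seed = 3)
  iv <- function(f) perturbation_spec(occupancy_scale = data.frame(
    chrom = "chr1", start = 1500, end = 3500, factor = f))
  lo <- raw_log2_occ(simulate_occupancy(g, iv(0.6), noise_sd = 0, seed = 1))
  hi <- raw_log2_occ(simulate_occupancy(g, iv(1.4), noise_sd = 0, seed = 1))
  sel <- lo$pos >= 1500 & lo$pos <= 3500
  expect_true(all(hi$value[sel] >= lo$value[sel]))
})

test_that("shift validation names the offending nucleosome", {
  g <- tiny_genome(n_genes = 4, seed = 3)
  gid <- g$genes$gene_id[1]
  bad <- perturbation_spec(shift_map = data.frame(
    gene_id = gid, index = 1, shift_bp = -5000))
  expect_error(simulate_occupancy(g, bad, seed = 1), gid)
})

test_that("cryptic transcripts raise treatment on their own strand only", {
  g <- tiny_genome(n_genes = 6, seed = 3)
  cr <- data.frame(chrom = "chr1", start = 2000, end = 2400,
                   strand = "-", fold = 4)
  pert <- perturbation_spec(cryptic = cr)
  e <- simulate_expression(g, pert, noise_sd = 0, n_replicates = 1,
                           seed = 1)
  sel <- e$pos >= 2000 & e$pos <= 2400
  dminus <- log2(e$treat_rep1 / e$ctrl_rep1)[sel & e$strand == "-"]
  dplus <- log2(e$treat_rep1 / e$ctrl_rep1)[sel & e$strand == "+"]
  expect_equal(dminus, rep(2, length(dminus)), tolerance = 1e-12)
  expect_equal(dplus, rep(0, length(dplus)), tolerance = 1e-12)
  # no planted transcripts: treatment and control identical, noise-free
  e0 <- simulate_expression(g, noise_sd = 0, n_replicates = 1, seed = 1)
  expect_equal(e0$treat_rep1, e0$ctrl_rep1, tolerance = 1e-12)
  # interval outside the chromosome is rejected
  bad <- perturbation_spec(cryptic = data.frame(
    chrom = "chr1", start = 1, end = 10 * g$chrom_lengths[["chr1"]],
    strand = "+", fold = 4))
  expect_error(simulate_expression(g, bad, seed = 1), "outside")
})

test_that("read pairs center on true nucleosomes", {
  g <- tiny_genome(n_genes = 4, seed = 3)
  p0 <- simulate_readpairs(g, depth = 5, jitter_sd = 0, seed = 2)
  mids <- round((p0$start + p0$end) / 2)
  expect_true(all(mids %in% g$centers$pos))
  # Gaussian-smoothed midpoint-histogram modes recover the centers at
  # realistic depth and jitter (the raw per-bp histogram mode of ~50
  # draws with sd-10 jitter is itself several bp noisy, so the smoothed
  # mode is the meaningful center estimate)
  p <- simulate_readpairs(g, depth = 50, jitter_sd = 10, seed = 2)
  trk <- midpoint_track(p, g$chrom_lengths, step = 1)
  sc <- gaussian_score(trk)
  genic <- g$centers[!is.na(g$centers$gene_id), ]
  ok <- vapply(seq_len(nrow(genic)), function(i) {
    sel <- which(abs(sc$pos - genic$pos[i]) <= 60)
    mode_pos <- sc$pos[sel][which.max(sc$score[sel])]
    abs(mode_pos - genic$pos[i]) <= 5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
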