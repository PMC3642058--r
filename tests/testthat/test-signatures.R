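flat_docc <- function(value, n = 3000, step = 4) {
  data.frame(chrom = "chr1", pos = seq_len(n) * step, value = value)
}

test_that("NDR windows abut the TSS on the correct side", {
  w <- ndr_window(1000, "+")
  expect_equal(c(w$start, w$end), c(800, 999))
  wm <- ndr_window(5000, "-")
  expect_equal(c(wm$start, wm$end), c(5001, 5200))
  expect_equal(w$end - w$start + 1, 200)
})

test_that("NDR occupancy change averages the upstream window", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
                      end = 2000, strand = "+", tss = 1000, tes = 2000)
  d <- ndr_occupancy_change(genes, flat_docc(-1))
  expect_equal(d$mean_docc, -1)
  expect_false(d$truncated)
  # window truncated by the chromosome start is flagged
  g2 <- data.frame(gene_id = "g2", chrom = "chr1", start = 100,
                   end = 900, strand = "+", tss = 100, tes = 900)
  d2 <- ndr_occupancy_change(g2, flat_docc(-1))
  expect_true(d2$truncated)
})

test_that("the TCR rule needs up-regulation and a 1.5-fold occupancy drop", {
  mk_tf <- function(dir, docc_val) {
    tf <- data.frame(chrom = "chr1", strand = "+", start = 2000,
                     end = 2400, direction = dir, n_probes = 20,
                     mean_log2_fc = ifelse(dir == "up", 2, -2),
                     orientation_class = "intergenic",
                     stringsAsFactors = FALSE)
    detect_tcr(tf, flat_docc(docc_val), c(chr1 = 100000),
               subtel_dist = 100)
  }
  expect_equal(nrow(mk_tf("up", -0.8)), 1)   # -0.8 <= -log2(1.5)
  expect_equal(nrow(mk_tf("up", -0.4)), 0)   # -0.4 >  -log2(1.5)
  expect_equal(nrow(mk_tf("down", -2)), 0)   # direction rule
  hit <- mk_tf("up", -0.8)
  expect_equal(hit$category, "intergenic")
})

test_that("raising the occupancy fold requirement never adds hits", {
  set.seed(61)
  tf <- data.frame(chrom = "chr1", strand = "+",
                   start = seq(1000, by = 600, length.out = 12),
                   end = seq(1300, by = 600, length.out = 12),
                   direction = "up", n_probes = 20, mean_log2_fc = 2,
                   orientation_class = "intergenic",
                   stringsAsFactors = FALSE)
  docc <- flat_docc(0)
  docc$value <- rnorm(nrow(docc), -0.6, 0.3)
  lens <- c(chr1 = 100000)
  h15 <- detect_tcr(tf, docc, lens, occ_fold = 1.5, subtel_dist = 100)
  h20 <- detect_tcr(tf, docc, lens, occ_fold = 2.0, subtel_dist = 100)
  expect_true(all(paste(h20$start) %in% paste(h15$start)))
})

test_that("every TCR hit independently passes both sub-thresholds", {
  g <- tiny_genome(n_genes = 10, intergenic_length_mean = 1200, seed = 6)
  cr <- data.frame(chrom = "chr1", start = 3000, end = 3300,
                   strand = "+", fold = 4)
  os <- data.frame(chrom = "chr1", start = 2800, end = 2999, factor = 0.4)
  pert <- perturbation_spec(cryptic = cr, occupancy_scale = os)
  wt <- preprocess_array(simulate_occupancy(g, noise_sd = 0.2, seed = 1))
  cond <- preprocess_array(simulate_occupancy(g, pert, noise_sd = 0.2,
                                              seed = 2))
  docc <- occupancy_change(cond, wt)
  st <- probe_stats(simulate_expression(g, pert, noise_sd = 0.2, seed = 3))
  tf <- classify_transfrags(
    filter_annotated(merge_transfrags(detect_transfrags(st), st), g$genes),
    g$genes)
  hits <- detect_tcr(tf, docc, g$chrom_lengths, subtel_dist = 100)
  expect_gte(nrow(hits), 1)
  for (i in seq_len(nrow(hits))) {
    expect_equal(hits$direction[i], "up")
    expect_gte(abs(hits$mean_log2_fc[i]), 1)
    expect_gte(hits$end[i] - hits$start[i] + 1, 80)
    p5 <- if (hits$strand[i] == "+") hits$start[i] else hits$end[i]
    w <- ndr_window(p5, hits$strand[i])
    direct <- mean(docc$value[docc$pos >= w$start & docc$pos <= w$end])
    expect_lte(direct, -log2(1.5))
  }
})

test_that("PATs are anchored by their 5' end inside an NDR window", {
  genes <- data.frame(gene_id = c("up_nb", "anchor"), chrom = "chr1",
                      start = c(200, 2000), end = c(900, 3500),
                      strand = c("-", "+"), tss = c(900, 2000),
                      tes = c(200, 3500), stringsAsFactors = FALSE)
  mk_tf <- function(p5) data.frame(
    chrom = "chr1", strand = "-", start = p5 - 300, end = p5,
    direction = "up", n_probes = 20, mean_log2_fc = 2,
    orientation_class = "diverging", stringsAsFactors = FALSE)
  inw <- detect_pat(mk_tf(1950), genes)     # 50 bp upstream of the TSS
  expect_equal(nrow(inw$hits), 1)
  expect_equal(inw$hits$anchor_gene, "anchor")
  expect_equal(inw$hits$promoter_config, "diverging")
  out <- detect_pat(mk_tf(1700), genes)     # 300 bp upstream: outside
  expect_equal(nrow(out$hits), 0)
})

test_that("planted diverging-promoter PATs give a diverging fraction of 1", {
  # alternating -,+ genes create divergent promoter pairs
  g <- build_genome(genome_spec(n_chromosomes = 1, n_genes = 12,
                                strands = c("-", "+"),
                                intergenic_length_mean = 800, seed = 9))
  plus <- g$genes[g$genes$strand == "+", ]
  cr <- do.call(rbind, lapply(seq_len(min(5, nrow(plus))), function(i) {
    p5 <- plus$tss[i] - 100          # inside the NDR
    data.frame(chrom = plus$chrom[i], start = p5 - 250, end = p5,
               strand = "-", fold = 4)
  }))
  pert <- perturbation_spec(cryptic = cr)
  st <- probe_stats(simulate_expression(g, pert, noise_sd = 0.2, seed = 2))
  tf <- classify_transfrags(
    filter_annotated(merge_transfrags(detect_transfrags(st), st), g$genes),
    g$genes)
  pat <- detect_pat(tf, g$genes)
  expect_gte(nrow(pat$hits), 4)
  expect_equal(pat$frac_diverging, 1.0)
})

test_that("TSS-anchored profiles reflect the generator geometry", {
  g <- tiny_genome(n_genes = 30, seed = 10)
  o <- simulate_occupancy(g, noise_sd = 0.1, n_replicates = 1, seed = 4)
  trk <- raw_log2_occ(o)
  prof <- tss_profile(trk, g$genes, from = -400, to = 1000)
  ndr <- prof$mean[prof$offset >= -150 & prof$offset <= -50]
  body <- prof$mean[prof$offset >= 50 & prof$offset <= 400]
  expect_lt(mean(ndr), mean(body))
  # first peak near +74 (the +1 nucleosome center)
  peak1 <- prof$offset[prof$offset >= 0 & prof$offset <= 150]
  pm <- prof$mean[prof$offset >= 0 & prof$offset <= 150]
  expect_lte(abs(peak1[which.max(pm)] - 74), 12)
  # >= 3 oscillation peaks downstream at the 165-bp repeat
  for (k in 0:2) {
    at_peak <- mean(prof$mean[abs(prof$offset - (74 + k * 165)) <= 10])
    at_linker <- mean(prof$mean[abs(prof$offset - (156 + k * 165)) <= 10])
    expect_gt(at_peak, at_linker)
  }
})

test_that("single-gene profiles equal the gene's own track segment", {
  g1 <- data.frame(gene_id = "a", chrom = "chr1", start = 1000,
                   end = 2000, strand = "+", tss = 1000, tes = 2000)
  trk <- data.frame(chrom = "chr1", pos = seq(4, 4000, by = 4),
                    value = sin(seq(4, 4000, by = 4) / 50))
  prof <- tss_profile(trk, g1, from = 0, to = 400)
  sel <- trk$pos >= 1000 & trk$pos <= 1400
  expect_equal(prof$mean[prof$offset %in% (trk$pos[sel] - 1000)],
               trk$value[sel], tolerance = 1e-12)
  # a minus-strand mirror gene contributes identically
  g2 <- data.frame(gene_id = "b", chrom = "chr1", start = 2000,
                   end = 3000, strand = "-", tss = 3000, tes = 2000)
  trk2 <- trk
  trk2$value <- rev(trk$value)[seq_len(nrow(trk))]
  # reflect the track around position 4000 - pos + 4 and compare
  prof2 <- tss_profile(trk2, g2, from = 0, to = 400)
  ref <- vapply(0:400, function(o) {
    p <- 3000 - o
    v <- trk2$value[trk2$pos == p]
    if (length(v)) v else NA_real_
  }, numeric(1))
  expect_equal(prof2$mean[!is.na(ref)], ref[!is.na(ref)],
               tolerance = 1e-12)
})

test_that("NDR ranking recovers a planted occupancy-expression coupling", {
  set.seed(62)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40), chrom = "chr1",
                      start = seq(1000, by = 2000, length.out = 40),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 1000
  genes$strand <- "+"
  genes$tss <- genes$start
  genes$tes <- genes$end
  docc_per_gene <- rnorm(40, 0, 1)
  docc <- data.frame(chrom = "chr1", pos = seq(4, 90000, by = 4))
  docc$value <- 0
  for (i in 1:40) {
    w <- ndr_window(genes$tss[i], "+")
    sel <- docc$pos >= w$start & docc$pos <= w$end
    docc$value[sel] <- docc_per_gene[i]
  }
  gd <- ndr_occupancy_change(genes, docc)
  expr <- setNames(-docc_per_gene + rnorm(40, 0, 0.2), genes$gene_id)
  r <- rank_by_ndr(gd, expr)
  expect_lt(r$rho, -0.8)
  expect_equal(r$n_missing, 0)
  expect_equal(r$table$gene_id[1],
               genes$gene_id[which.min(docc_per_gene)])
  # three genes with ordered docc keep a fixed rank order
  g3 <- gd[1:3, ]
  g3$mean_docc <- c(0, -1, 1)
  r3 <- rank_by_ndr(g3, expr)
  expect_equal(r3$table$mean_docc, c(-1, 0, 1))
  # constant docc: correlation undefined, ties broken by gene id
  g0 <- gd
  g0$mean_docc <- 0
  r0 <- rank_by_ndr(g0, expr)
  expect_true(is.na(r0$rho))
  expect_equal(r0$table$gene_id, sort(genes$gene_id))
})
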