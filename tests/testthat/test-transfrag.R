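# Hand-built probe-stat tables: 4-bp grid, one strand.
stat_frame <- function(pos, lfc, p = 0.001, strand = "+") {
  data.frame(chrom = "chr1", pos = pos, strand = strand,
             log2_fc = lfc, p = p, stringsAsFactors = FALSE)
}

test_that("rank-sum p matches exact enumeration at complete separation", {
  x <- rep(8, 7)
  y <- rep(2, 7)
  expect_equal(ranksum_p(x, y), 2 / choose(14, 7), tolerance = 1e-12)
  expect_equal(ranksum_p(x, y), exact_ranksum_p(x, y), tolerance = 1e-12)
  # separation with distinct values agrees with the exact Wilcoxon
  set.seed(51)
  x2 <- rnorm(6) + 100
  y2 <- rnorm(8)
  expect_equal(ranksum_p(x2, y2),
               wilcox.test(x2, y2, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(ranksum_p(x2, y2), exact_ranksum_p(x2, y2),
               tolerance = 1e-12)
})

test_that("rank-sum p matches the tie-corrected normal approximation", {
  set.seed(52)
  for (rep in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(2:6, 15, replace = TRUE)
    if (min(x) > max(y) || max(x) < min(y)) next
    expect_equal(ranksum_p(x, y),
                 suppressWarnings(
                   wilcox.test(x, y, exact = FALSE,
                               correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
  # undersized windows are untestable
  expect_equal(ranksum_p(c(1, 2), c(3, 4, 5)), 1)
})

test_that("per-probe statistics find planted fold changes", {
  g <- tiny_genome(n_genes = 4, seed = 8)
  cr <- data.frame(chrom = "chr1", start = 2001, end = 2400,
                   strand = "+", fold = 4)
  e <- simulate_expression(g, perturbation_spec(cryptic = cr),
                           noise_sd = 0.1, seed = 3)
  st <- probe_stats(e)
  inside <- st$strand == "+" & st$pos >= 2100 & st$pos <= 2300
  expect_equal(mean(st$log2_fc[inside]), 2, tolerance = 0.15)
  expect_true(all(st$p[inside] < 0.01))
  outside <- st$strand == "-" & st$pos >= 2100 & st$pos <= 2300
  expect_lt(mean(abs(st$log2_fc[outside])), 0.1)
  # treatment == control: fc near 0 and p near 1 everywhere
  e0 <- simulate_expression(g, noise_sd = 0, seed = 3)
  st0 <- probe_stats(e0)
  expect_true(all(abs(st0$log2_fc) < 1e-9))
  expect_true(all(st0$p > 0.9))
})

test_that("detection applies span, probe-count and gap rules jointly", {
  # 12 consecutive passing probes span 45 bp: rejected on length
  s1 <- stat_frame(seq(100, by = 4, length.out = 12), 1.5)
  expect_equal(nrow(detect_transfrags(s1)), 0)
  # 21 consecutive passing probes span 81 bp: one transfrag
  s2 <- stat_frame(seq(100, by = 4, length.out = 21), 1.5)
  tf2 <- detect_transfrags(s2)
  expect_equal(nrow(tf2), 1)
  expect_equal(tf2$n_probes, 21)
  expect_equal(tf2$direction, "up")
  # runs separated by a 52-bp gap stay separate candidates
  pos3 <- c(seq(100, by = 4, length.out = 21),
            seq(100 + 20 * 4 + 52, by = 4, length.out = 21))
  s3 <- stat_frame(pos3, 1.5)
  expect_equal(nrow(detect_transfrags(s3)), 2)
  # gaps at exactly 48 bp stay joined
  pos4 <- c(seq(100, by = 4, length.out = 11),
            seq(100 + 10 * 4 + 48, by = 4, length.out = 11))
  s4 <- stat_frame(pos4, 1.5)
  expect_equal(nrow(detect_transfrags(s4)), 1)
  # opposite signs break a run
  s5 <- stat_frame(seq(100, by = 4, length.out = 42),
                   rep(c(1.5, -1.5), each = 21))
  tf5 <- detect_transfrags(s5)
  expect_equal(nrow(tf5), 2)
  expect_equal(sort(tf5$direction), c("down", "up"))
})

test_that("emitted transfrags always satisfy their invariants", {
  set.seed(53)
  n_emitted <- 0L
  for (rep in 1:5) {
    lfc <- rnorm(800, 0, 1.2)
    p <- runif(800, 0, 0.2)
    # embed signal blocks of varying width and sign among the noise
    for (b in seq(50, 750, by = 150)) {
      w <- sample(5:30, 1)
      s <- sample(c(-1, 1), 1)
      lfc[b:(b + w)] <- s * runif(w + 1, 1.2, 2.5)
      p[b:(b + w)] <- runif(w + 1, 0, 0.04)
    }
    st <- stat_frame(seq(4, by = 4, length.out = 800), lfc, p)
    tf <- detect_transfrags(st)
    n_emitted <- n_emitted + nrow(tf)
    if (!nrow(tf)) next
    expect_true(all(tf$end - tf$start + 1 >= 80))
    expect_true(all(tf$n_probes >= 10))
    expect_true(all((tf$mean_log2_fc > 0) == (tf$direction == "up")))
  }
  expect_gt(n_emitted, 5)
})

test_that("relaxing thresholds never yields fewer transfrags", {
  set.seed(54)
  st <- stat_frame(seq(4, by = 4, length.out = 2000),
                   rnorm(2000, 0, 1.3), runif(2000, 0, 0.1))
  strict <- nrow(detect_transfrags(st, fc_thresh = 2, p_thresh = 0.05))
  relaxed_p <- nrow(detect_transfrags(st, fc_thresh = 2, p_thresh = 0.2))
  relaxed_fc <- nrow(detect_transfrags(st, fc_thresh = 1.5,
                                       p_thresh = 0.05))
  expect_gte(relaxed_p, strict)
  expect_gte(relaxed_fc, strict)
})

test_that("merging requires all four criteria and is idempotent", {
  run1 <- seq(100, by = 4, length.out = 21)   # ends at 180
  run2 <- seq(300, by = 4, length.out = 21)   # 119-bp gap
  gap_pos <- seq(max(run1) + 4, 296, by = 4)
  mk <- function(gap_sign, dir2 = 1.5) {
    rbind(stat_frame(run1, 1.5),
          stat_frame(gap_pos, gap_sign * 0.2, p = 0.9),
          stat_frame(run2, dir2))
  }
  st_ok <- mk(1)
  tf <- detect_transfrags(st_ok)
  expect_equal(nrow(tf), 2)
  m <- merge_transfrags(tf, st_ok)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(min(run1), max(run2)))
  # merge is idempotent
  expect_equal(merge_transfrags(m, st_ok), m)
  # one intervening probe of the wrong sign blocks the merge
  st_bad <- mk(1)
  st_bad$log2_fc[st_bad$pos == gap_pos[5]] <- -0.2
  expect_equal(nrow(merge_transfrags(detect_transfrags(st_bad), st_bad)), 2)
  # opposite directions never merge
  st_dir <- mk(-1, dir2 = -1.5)
  expect_equal(nrow(merge_transfrags(detect_transfrags(st_dir), st_dir)), 2)
  # gaps beyond 250 bp never merge (even with consistent signs between)
  far <- rbind(stat_frame(run1, 1.5),
               stat_frame(run1 + 460, 1.5))
  expect_equal(nrow(merge_transfrags(detect_transfrags(far), far)), 2)
})

test_that("annotation filtering removes >20% same-strand overlap only", {
  tf <- data.frame(chrom = "chr1", strand = "+", start = 1001, end = 1100,
                   direction = "up", n_probes = 20, mean_log2_fc = 1.5,
                   stringsAsFactors = FALSE)
  ann20 <- data.frame(chrom = "chr1", start = 1081, end = 1100,
                      strand = "+")   # exactly 20 bp of 100
  expect_equal(nrow(filter_annotated(tf, ann20)), 1)
  ann21 <- data.frame(chrom = "chr1", start = 1080, end = 1100,
                      strand = "+")   # 21 bp: strictly more than 20%
  expect_equal(nrow(filter_annotated(tf, ann21)), 0)
  # full containment on the opposite strand is retained
  ann_anti <- data.frame(chrom = "chr1", start = 900, end = 1200,
                         strand = "-")
  expect_equal(nrow(filter_annotated(tf, ann_anti)), 1)
  # union of split overlaps counts, not each piece alone
  ann_split <- data.frame(chrom = "chr1", start = c(1001, 1090),
                          end = c(1011, 1100), strand = "+")  # 11 + 11
  expect_equal(nrow(filter_annotated(tf, ann_split)), 0)
})

test_that("orientation classes follow the strand-aware geometry", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 2000,
                      end = 4000, strand = "+", tss = 2000, tes = 4000,
                      stringsAsFactors = FALSE)
  mk_tf <- function(start, end, strand)
    data.frame(chrom = "chr1", strand = strand, start = start, end = end,
               direction = "up", n_probes = 20, mean_log2_fc = 1.5,
               stringsAsFactors = FALSE)
  # minus-strand transfrag whose 5' end sits 150 bp upstream of the TSS
  expect_equal(classify_transfrags(mk_tf(1500, 1850, "-"),
                                   genes)$orientation_class, "diverging")
  # antisense transfrag fully inside the gene
  expect_equal(classify_transfrags(mk_tf(2500, 2900, "-"),
                                   genes)$orientation_class,
               "intragenic-antisense")
  # same-strand transfrag inside the gene: nothing applies
  expect_equal(classify_transfrags(mk_tf(2500, 2900, "+"),
                                   genes)$orientation_class,
               "unclassified")
  # same strand, downstream of the TES: tandem-sense
  expect_equal(classify_transfrags(mk_tf(4200, 4600, "+"),
                                   genes)$orientation_class,
               "tandem-sense")
  # opposite strand past the TES transcribing back toward the gene
  expect_equal(classify_transfrags(mk_tf(4200, 4600, "-"),
                                   genes)$orientation_class, "converging")
  # beyond the 3-kb flank: unclassified
  expect_equal(classify_transfrags(mk_tf(8000, 8400, "-"),
                                   genes)$orientation_class,
               "unclassified")
})

test_that("union regions collapse same-strand overlaps across conditions", {
  tf1 <- data.frame(chrom = "chr1", strand = "+", start = c(100, 900),
                    end = c(300, 1100), direction = "up", n_probes = 20,
                    mean_log2_fc = c(1, 2), stringsAsFactors = FALSE)
  tf2 <- data.frame(chrom = "chr1", strand = "+", start = 250, end = 500,
                    direction = "up", n_probes = 20, mean_log2_fc = 3,
                    stringsAsFactors = FALSE)
  tf3 <- data.frame(chrom = "chr1", strand = "+", start = 450, end = 700,
                    direction = "up", n_probes = 20, mean_log2_fc = 4,
                    stringsAsFactors = FALSE)
  u <- union_regions(list(a = tf1, b = tf2, c = tf3))
  # chain 100-300 / 250-500 / 450-700 collapses into one region
  expect_equal(nrow(u), 2)
  expect_equal(u$start, c(100, 900))
  expect_equal(u$end, c(700, 1100))
  expect_equal(u$n_conditions, c(3, 1))
  expect_equal(u$fc_a, c(1, 2))
  expect_equal(u$fc_b[1], 3)
  expect_true(is.na(u$fc_b[2]))
  # identical sets collapse to a single region; disjoint sets concatenate
  u2 <- union_regions(list(x = tf2, y = tf2))
  expect_equal(nrow(u2), 1)
  expect_equal(u2$n_conditions, 2)
})
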