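# Shared scenario definitions for the analysis drivers.  Everything is
# deterministic, so each numbered script can rebuild exactly the pieces
# it needs in memory instead of passing large intermediates around.

library(nucshift)

SCENARIO_SEED <- 20260930L

# Yeast-like genome: 300 genes across 3 chromosomes, 165-bp nucleosome
# repeat, 200-bp promoter NDRs, 4-bp probe grid.  Intergenic gaps are
# widened (1.2 kb) so the co-repressor scenario has room to plant
# intergenic cryptic loci with clear 200-bp upstream windows.
scenario_genome <- function() {
  build_genome(genome_spec(n_chromosomes = 3, n_genes = 300,
                           intergenic_length_mean = 1200,
                           seed = SCENARIO_SEED))
}

# A remodeler-mutant-like condition: 150 genic nucleosomes displaced by
# 10-30 bp (both directions, like the shifts seen on loss of Chd1-class
# remodeler ATPases).
scenario_shift_map <- function(genome) {
  set.seed(SCENARIO_SEED + 1L)
  cen <- genome$centers[!is.na(genome$centers$gene_id), ]
  pick <- sample(nrow(cen), 150)
  data.frame(gene_id = cen$gene_id[pick], index = cen$index[pick],
             shift_bp = sample(c(-30:-10, 10:30), 150, replace = TRUE),
             true_pos = cen$pos[pick])
}

# A co-repressor-mutant-like condition: 15 cryptic transcripts (fold 4),
# ten of them coupled to a 2-fold nucleosome loss in the 200 bp upstream
# of their start (the de-repression signature), five expression-only.
scenario_corepressor <- function(genome) {
  set.seed(SCENARIO_SEED + 2L)
  loci <- list()
  tries <- 0L
  while (length(loci) < 15) {
    tries <- tries + 1L
    if (tries > 50000L)
      stop("could not place cryptic loci; widen the intergenic gaps")
    ch <- sample(names(genome$chrom_lengths), 1)
    len <- sample(250:400, 1)
    s <- sample(seq(2000, genome$chrom_lengths[[ch]] - 2000 - len), 1)
    st <- sample(c("+", "-"), 1)
    gg <- genome$genes[genome$genes$chrom == ch, ]
    if (any(gg$start <= s + len + 300 & gg$end >= s - 300)) next
    if (any(vapply(loci, function(q)
      q$chrom == ch && abs(q$start - s) < 1500, logical(1)))) next
    loci[[length(loci) + 1]] <- data.frame(
      chrom = ch, start = s, end = s + len - 1, strand = st, fold = 4)
  }
  loci <- do.call(rbind, loci)
  with_occ <- loci[1:10, ]
  p5 <- ifelse(with_occ$strand == "+", with_occ$start, with_occ$end)
  upwin <- data.frame(
    chrom = with_occ$chrom,
    start = ifelse(with_occ$strand == "+", p5 - 200, p5 + 1),
    end = ifelse(with_occ$strand == "+", p5 - 1, p5 + 200),
    factor = 0.5)
  list(cryptic = loci, occupancy_scale = upwin,
       coupled = with_occ, expression_only = loci[11:15, ])
}

scenario_perturbations <- function(genome) {
  co <- scenario_corepressor(genome)
  list(
    remodeler = perturbation_spec(
      shift_map = scenario_shift_map(genome)[, 1:3]),
    corepressor = perturbation_spec(
      cryptic = co$cryptic, occupancy_scale = co$occupancy_scale))
}

# Simulated hybridizations.  The wild-type reference and each condition
# get 2 replicates; the reference panel holds 31 independently grown
# wild-type cultures (one hybridization each), mirroring the compendium's
# 31 wild-type samples.
scenario_wt_probes <- function(genome)
  simulate_occupancy(genome, noise_sd = 0.2, n_replicates = 2,
                     seed = SCENARIO_SEED + 10L)

scenario_cond_probes <- function(genome, pert, offset)
  simulate_occupancy(genome, pert, noise_sd = 0.2, n_replicates = 2,
                     seed = SCENARIO_SEED + 20L + offset)

scenario_panel_probes <- function(genome, i)
  simulate_occupancy(genome, noise_sd = 0.2, n_replicates = 1,
                     seed = SCENARIO_SEED + 100L + i)

scenario_expression <- function(genome, pert)
  simulate_expression(genome, pert, noise_sd = 0.2, n_replicates = 2,
                      seed = SCENARIO_SEED + 30L)

results_dir <- function(sub) {
  d <- file.path("results", sub)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
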