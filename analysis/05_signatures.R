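#!/usr/bin/env Rscript
# Combines occupancy and expression evidence for the co-repressor-like
# condition: the TSS-anchored average occupancy profile, per-gene NDR
# occupancy changes and their ranking against expression, the scan for
# transcripts up-regulated together with upstream nucleosome loss
# (>=2-fold / p<=0.05 / >=80 nt expression change plus a 1.5-fold
# occupancy decrease in the 200 bp upstream), and promoter-associated
# transcript detection.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_scenario.R"))

out <- results_dir("signatures")
genome <- scenario_genome()
perts <- scenario_perturbations(genome)
co <- scenario_corepressor(genome)

wt_track <- preprocess_array(scenario_wt_probes(genome))
cond_track <- preprocess_array(
  scenario_cond_probes(genome, perts$corepressor, 2L))
docc <- occupancy_change(cond_track, wt_track)
write_bedgraph(docc, file.path(out, "occupancy_change.bedgraph"))

prof <- tss_profile(wt_track, genome$genes, from = -500, to = 2000)
data.table::fwrite(prof, file.path(out, "tss_profile.tsv"), sep = "\t")
trough <- prof$offset[which.min(prof$mean[prof$offset < 200]) ]
peak1 <- prof$offset[prof$offset >= 0 & prof$offset <= 150][
  which.max(prof$mean[prof$offset >= 0 & prof$offset <= 150])]
message(sprintf("TSS profile: NDR trough at %+d bp, +1 peak at %+d bp",
                trough, peak1))

expr <- scenario_expression(genome, perts$corepressor)
st <- probe_stats(expr)
tf <- classify_transfrags(
  filter_annotated(merge_transfrags(detect_transfrags(st), st),
                   genome$genes), genome$genes)

tcr <- detect_tcr(tf, docc, genome$chrom_lengths)
data.table::fwrite(tcr, file.path(out, "tcr_hits.tsv"), sep = "\t")
coupled_hit <- vapply(seq_len(nrow(co$coupled)), function(i)
  any(tcr$chrom == co$coupled$chrom[i] &
        tcr$strand == co$coupled$strand[i] &
        tcr$start <= co$coupled$end[i] & tcr$end >= co$coupled$start[i]),
  logical(1))
only_expr_hit <- vapply(seq_len(nrow(co$expression_only)), function(i)
  any(tcr$chrom == co$expression_only$chrom[i] &
        tcr$strand == co$expression_only$strand[i] &
        tcr$start <= co$expression_only$end[i] &
        tcr$end >= co$expression_only$start[i]), logical(1))
message(sprintf(
  "occupancy+expression scan: %d hits; %d/%d coupled plants found, %d/%d expression-only decoys excluded",
  nrow(tcr), sum(coupled_hit), nrow(co$coupled),
  sum(!only_expr_hit), nrow(co$expression_only)))

pat <- detect_pat(tf, genome$genes)
message(sprintf(
  "promoter-associated transcripts in the co-repressor condition: %d (its plants are intergenic, away from NDRs)",
  nrow(pat$hits)))

# dedicated promoter-transcript scenario: a genome of alternating -,+
# genes (divergent promoter pairs) with cryptic transcripts initiating
# inside the NDRs of the + genes
gp <- build_genome(genome_spec(n_chromosomes = 1, n_genes = 40,
                               strands = c("-", "+"),
                               intergenic_length_mean = 800,
                               seed = SCENARIO_SEED + 5L))
plus <- gp$genes[gp$genes$strand == "+", ]
plus <- plus[seq_len(min(12, nrow(plus))), ]
crp <- data.frame(chrom = plus$chrom, start = plus$tss - 350,
                  end = plus$tss - 100, strand = "-", fold = 4)
stp <- probe_stats(simulate_expression(
  gp, perturbation_spec(cryptic = crp), noise_sd = 0.2,
  seed = SCENARIO_SEED + 6L))
tfp <- classify_transfrags(
  filter_annotated(merge_transfrags(detect_transfrags(stp), stp),
                   gp$genes), gp$genes)
patp <- detect_pat(tfp, gp$genes)
data.table::fwrite(patp$hits, file.path(out, "pat_hits.tsv"), sep = "\t")
message(sprintf(
  "promoter-transcript scenario: %d/%d NDR-initiated plants detected as PATs, diverging fraction %.2f",
  nrow(patp$hits), nrow(crp), patp$frac_diverging))

gd <- ndr_occupancy_change(genome$genes, docc)
expr_change <- vapply(seq_len(nrow(genome$genes)), function(i) {
  g <- genome$genes[i, ]
  sel <- st$chrom == g$chrom & st$strand == g$strand &
    st$pos >= g$start & st$pos <= g$end
  mean(st$log2_fc[sel])
}, numeric(1))
names(expr_change) <- genome$genes$gene_id
rk <- rank_by_ndr(gd, expr_change)
data.table::fwrite(rk$table, file.path(out, "ndr_ranking.tsv"),
                   sep = "\t")
message(sprintf(
  "NDR ranking: %d genes, Spearman rho(NDR occupancy change, expression change) = %.3f",
  nrow(rk$table), rk$rho))

summary <- list(
  tss_trough_bp = trough, tss_plus1_peak_bp = peak1,
  n_tcr_hits = nrow(tcr), tcr_sensitivity = mean(coupled_hit),
  tcr_decoys_called = sum(only_expr_hit),
  n_pat_corepressor = nrow(pat$hits),
  n_pat_promoter_scenario = nrow(patp$hits),
  pat_frac_diverging = patp$frac_diverging,
  ndr_expression_rho = rk$rho)
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
message("summary written to ", file.path(out, "summary.json"))
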