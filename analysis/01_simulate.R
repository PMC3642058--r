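#!/usr/bin/env Rscript
# Builds the synthetic compendium: a yeast-like genome with known
# nucleosome positions, a remodeler-like condition carrying 150 planted
# genic nucleosome shifts, and a co-repressor-like condition carrying 15
# cryptic transcripts (10 coupled to upstream nucleosome loss).  Writes
# the annotation and ground-truth tables that later drivers are scored
# against.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_scenario.R"))

out <- results_dir("simulation")
genome <- scenario_genome()

write_genes_gff3(genome$genes, file.path(out, "genes.gff3"))
data.table::fwrite(genome$centers, file.path(out, "true_centers.tsv"),
                   sep = "\t")

shifts <- scenario_shift_map(genome)
data.table::fwrite(shifts, file.path(out, "planted_shifts.tsv"),
                   sep = "\t")

co <- scenario_corepressor(genome)
data.table::fwrite(co$cryptic, file.path(out, "planted_transcripts.tsv"),
                   sep = "\t")
data.table::fwrite(co$occupancy_scale,
                   file.path(out, "planted_ndr_loss.tsv"), sep = "\t")

genic_n <- sum(!is.na(genome$centers$gene_id))
message(sprintf(
  "genome: %d genes on %d chromosomes (%.2f Mb), %d genic + %d intergenic nucleosomes",
  nrow(genome$genes), length(genome$chrom_lengths),
  sum(genome$chrom_lengths) / 1e6, genic_n,
  sum(is.na(genome$centers$gene_id))))
message(sprintf("planted: %d genic shifts (10-30 bp), %d cryptic transcripts (%d with upstream nucleosome loss)",
                nrow(shifts), nrow(co$cryptic), nrow(co$coupled)))
message("tables written under ", out)
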