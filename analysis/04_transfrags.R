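#!/usr/bin/env Rscript
# Segments strand-specific differentially transcribed regions in the
# co-repressor-like condition: windowed per-probe statistics, the
# 2-fold / p<=0.05 / >=80 nt / >=10 probes / 48-nt gap rule, 250-bp
# merging, the 20% same-strand annotation filter, and orientation
# classification relative to neighboring genes.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_scenario.R"))

out <- results_dir("transfrags")
genome <- scenario_genome()
perts <- scenario_perturbations(genome)
co <- scenario_corepressor(genome)

expr <- scenario_expression(genome, perts$corepressor)
message(sprintf("computing per-probe statistics over %d probe/strand positions ...",
                nrow(expr)))
st <- probe_stats(expr)
raw <- detect_transfrags(st)
merged <- merge_transfrags(raw, st)
kept <- filter_annotated(merged, genome$genes)
tf <- classify_transfrags(kept, genome$genes)
data.table::fwrite(tf, file.path(out, "transfrags.tsv"), sep = "\t")

hit <- vapply(seq_len(nrow(co$cryptic)), function(i)
  any(tf$chrom == co$cryptic$chrom[i] & tf$strand == co$cryptic$strand[i] &
        tf$start <= co$cryptic$end[i] & tf$end >= co$cryptic$start[i]),
  logical(1))
fp <- vapply(seq_len(nrow(tf)), function(i)
  !any(co$cryptic$chrom == tf$chrom[i] &
         co$cryptic$strand == tf$strand[i] &
         co$cryptic$start <= tf$end[i] & co$cryptic$end >= tf$start[i]),
  logical(1))
classes <- as.data.frame(table(tf$orientation_class))
names(classes) <- c("orientation_class", "n")
data.table::fwrite(classes, file.path(out, "orientation_classes.tsv"),
                   sep = "\t")
summary <- data.frame(
  n_raw = nrow(raw), n_merged = nrow(merged), n_kept = nrow(kept),
  n_planted = nrow(co$cryptic), n_recovered = sum(hit),
  sensitivity = mean(hit),
  false_per_mb = sum(fp) / (2 * sum(genome$chrom_lengths) / 1e6))
data.table::fwrite(summary, file.path(out, "recovery_summary.tsv"),
                   sep = "\t")
message(sprintf(
  "%d raw -> %d merged -> %d after annotation filter; recovered %d/%d planted transcripts (%.2f), %.3f false transfrags/Mb",
  nrow(raw), nrow(merged), nrow(kept), sum(hit), nrow(co$cryptic),
  mean(hit), summary$false_per_mb))
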