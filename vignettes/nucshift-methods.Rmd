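---
title: "Methods: nucleosome positioning, shift statistics and cryptic transcription signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome positioning, shift statistics and cryptic transcription signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In budding yeast, genes carry a stereotyped chromatin architecture: a
nucleosome-depleted region (NDR) directly upstream of the transcription
start site (TSS), then a regularly phased array of nucleosomes across the
gene body with an average repeat of ~165 bp (147-bp cores separated by
~18-bp linkers). Perturbing chromatin factors — remodeler ATPases,
histone chaperones, co-repressors, general transcription factors — moves
genic nucleosomes laterally, changes NDR occupancy, and can de-repress
cryptic transcripts. `nucshift` implements the analysis chain that turns
raw chromatin-profiling tracks into those three read-outs:

1. **preprocess** — probe-level tiling-array intensities (or paired-end
   mononucleosome fragment midpoints) into comparable log2 occupancy
   tracks;
2. **nuccall** — nucleosome center positions from a Gaussian-filtered
   occupancy score;
3. **shiftstats** — signed per-nucleosome displacements of a condition
   relative to a wild-type reference, tested against a panel of
   independent wild-type samples;
4. **transfrag** — strand-specific differentially transcribed regions
   from expression tracks;
5. **signatures** — combined occupancy + expression scans (upstream
   nucleosome loss coupled to de-repression; promoter-associated
   transcripts), NDR rankings and TSS-anchored profiles.

Because the deposited microarray data cannot be shipped with the
package, a first-class synthetic-data module (**synthio**) generates
genomes, occupancy and expression tracks, and fragment midpoints with
known ground truth. Every downstream stage is tested against those
planted truths.

# The synthetic-data generator

`genome_spec()` / `build_genome()` lay non-overlapping genes along each
chromosome. Within a gene, the +1 nucleosome center sits
`ceiling(core_width/2)` = 74 bp downstream of the TSS and consecutive
centers are `core_width + linker_length` = 165 bp apart, as long as a
whole core fits inside the gene. Each promoter has a 200-bp NDR with no
nucleosomes. Intergenic space outside NDRs is also nucleosomal (filler
nucleosomes at the same repeat, with a safety margin around genes and
NDRs), as in real chromatin — this matters when occupancy changes are
planted in intergenic regions, since an occupancy *loss* needs occupancy
to lose.

`simulate_occupancy()` emits linear probe intensities whose expected
log2 is the occupancy signal:

* per-nucleosome signal: a triangular kernel of half-width 73 bp over
  each center (a smooth, compact, analytically checkable approximation
  of MNase protection of a 147-bp core), summed, plus a flat background;
* probe noise: i.i.d. Gaussian on the log2 scale (`noise_sd`, default
  0.2), the simplest model compatible with downstream log-ratio
  analysis;
* probe affinity: a multiplicative per-probe effect (log2 sd 1.2) shared
  by *all* hybridizations of a genome, emulating the sequence-dependent
  intensity spread of short-oligo arrays. Four flat genomic-DNA control
  hybridizations carry the same affinity field, so the sample/control
  ratio cancels it — exactly why real pipelines divide by gDNA.

Two defaults deserve justification because they are conventions, not
published estimates. The **background** (0.35) sets the NDR-trough to
array-peak dynamic range to ~2 log2 units, matching the amplitude of
published yeast MNase log2-ratio tracks. The **affinity sd** (1.2
log2 units) makes probe effects dominate every hybridization's raw
intensity distribution, as on real arrays; with a much smaller value the
MNase and gDNA distributions differ in shape and quantile normalization
(which pools both array types) systematically attenuates localized
occupancy changes by ~40% — an artifact of an unrealistic simulation,
not of the pipeline.

Perturbations are declared with `perturbation_spec()`: targeted genic
shifts (signed bp, positive = away from the TSS; validated to stay
inside the gene body), interval occupancy scale factors (applied
position-wise to total occupancy, so a factor *f* moves the expected
log2 signal by exactly `log2(f)`), cryptic transcripts (interval,
strand, fold), and global histone depletion. `simulate_expression()`
adds baseline expression over genes on their own strand plus the planted
cryptic signal in the treatment channel only. `simulate_readpairs()`
draws ~147-bp fragments per nucleosome with discretized Gaussian
midpoint jitter (default sd 10 bp); the raw per-bp histogram mode of ~50
such draws is itself several bp noisy, so center recovery is asserted on
the Gaussian-smoothed midpoint histogram, which is also what the
sequencing branch of the pipeline uses.

What the generator does **not** emulate: sequence (no FASTA, no MNase
sequence bias), probe-level cross-hybridization structure, correlated
(wavy) array artifacts beyond a smooth baseline, or biological
replicate-to-replicate variation beyond probe noise. Passing tests
therefore demonstrate that the algorithms recover what they claim from
signals of realistic shape and noise level — not that the thresholds are
optimal for any particular real data set.

# Preprocessing

Array mode (`preprocess_array()`) chains:

1. `quantile_normalize()` across all sample and gDNA control columns
   (delegated to `limma::normalizeQuantiles`, ties averaged);
2. `median_smooth()` with a 30-bp bandwidth (truncated windows at track
   edges);
3. `rescale_common_range()` — each array affinely mapped so its 1st/99th
   percentiles meet the group mean (robust to outliers, order
   preserving). Rescaling is done *within* array groups (samples
   together, controls together): after quantile normalization the map is
   near-identity within a group, whereas mapping structured MNase arrays
   onto the flat controls' range would distort the subsequent ratios;
4. per-replicate `log_ratio()` against the mean of the gDNA controls;
5. `detrend_baseline()` — subtraction of a 5-kb running median.

The running-median detrend replaces a wavelet-based baseline-removal
step used in the original processing: both remove only chromosome-scale
drifts far wider than any nucleosome-scale feature, and the running
median is transparent and exactly testable (constant offsets cancel; a
50-kb sinusoid is attenuated by more than 80% while 1-probe spikes
survive).

Sequencing mode bins read-pair midpoints on the genome grid
(`midpoint_track()`, count-conserving) and forms
`log2((count + 1)/(control + 1))` (`seq_occupancy()`), converging on the
same track type as the array branch.

The stage order (quantile → smooth → rescale → ratio → detrend) follows
the narrative order of the original processing; the original does not
pin down every ordering, so the order here is part of this package's
specification and is held fixed by the determinism tests.

# Nucleosome calling

`gaussian_score()` convolves the occupancy track with a discretized
normal kernel (sd 25 bp, support ±50 bp, renormalized to unit sum;
truncated and renormalized at edges). "Bandwidth 50" is read as the
half-support — ±2 sd at sd 25. `call_positions()` then assigns centers
sequentially: the highest remaining local maximum of the score is
called, all candidates within 100 bp of a called center are excluded,
and the process repeats until no candidate remains. Local maxima are
defined on the probe grid (strictly greater than both neighbors;
plateaus take their leftmost point); score ties break to the leftmost
coordinate, making the caller fully deterministic. An exhaustive greedy
reference implementation double-checks the caller on 5-kb tracks in the
test suite, and a cell-hashing implementation keeps the production path
O(n log n).

`filter_low_scores()` drops the `floor(0.10 N)` lowest-scoring calls,
pooled globally across chromosomes (ties at the cutoff exclude the
leftmost first, keeping the count exact). `assign_genic()` numbers
retained calls +1, +2, … by strand-aware distance downstream of each
curated TSS, up to 100 bp past the TES; a call may serve two genes that
overlap on opposite strands.

On noise-free synthetic tracks the chain recovers every true center
within 4 bp (grid + kernel discretization). At the study noise level the
median genic center-to-center spacing is 164 bp — the 165-bp generator
repeat snapped to the 4-bp probe grid.

# Shift statistics

`match_shift()` maps each wild-type center to the nearest condition
center within a 100-bp window; the window is deliberately tight so a
lost nucleosome is reported missing instead of being matched to a
flanking neighbor. Equidistant ties resolve toward the TSS — the
deterministic, conservative choice against inflating "away" shifts.
Deltas are strand-aware (positive = away from the TSS).

`shift_records()` assembles, per genic wild-type nucleosome, the matched
center in each condition replicate and in each of the wild-type panel
conditions (the study design carries 31 independently grown wild-type
samples). `shift_significance()` flags a nucleosome when

* every replicate moved ≥ 10 bp, all in the same direction, and
* a two-sample t-test of the replicate centers against the panel centers
  gives p < 0.05.

The t-test is pooled-variance with df = n1 + n2 − 2 and the panel sd
floored at 1 bp. A Welch test was considered and rejected: with two
replicates its degrees of freedom collapse to ~1, leaving essentially no
power — a +12/+15-bp shift against a tightly clustered 31-sample panel
would not reach p < 0.05, which contradicts the intended behaviour of
the rule. Pooling borrows the panel's degrees of freedom; the magnitude
and direction rules carry the burden of guarding against small-sample
variance artifacts, and on unperturbed replicate pairs fewer than 5% of
nucleosomes pass the full rule.

Position-level behaviour is summarized by `position_summary()`
(median/quartiles of the shift at each genic index) with
`flag_condition()` marking conditions whose median reaches 4 bp at some
index, `neighbor_profiles()` (mean ± 95% CI of shifts at every index for
genes grouped by the significant-shift status at a focal index — the
propagation read-out), and `smoothed_profile()` (sliding 25-bp mean with
a normal-approximation 95% CI).

Under the study conditions (noise sd 0.2, 2 replicates, 4-bp grid) a
single called position carries ~3–6 bp of stochastic error, so
individual recovered shifts scatter by a few bp around the planted value
(median |error| ~6 bp, and MAE ~4 bp after replicate averaging in the
analysis drivers); the *mean* recovered shift is unbiased to well within
4 bp and the direction is recovered for ≥ 95% of planted 10–30-bp
shifts. Claims about single nucleosomes should therefore rest on the
significance rule, not on a lone delta.

# Transfrag detection

`probe_stats()` pools, per probe, all replicate values within a 30-bp
window on the same strand and reports the log2 ratio of window means
plus a two-sided Wilcoxon rank-sum p-value. The rank-sum statistic
replaces the closed-source array software used originally: it is the
standard nonparametric two-group test and is exactly testable — at
complete separation the implementation returns the exact permutation
tail `2/choose(n+m, n)` (valid under ties), elsewhere the tie- and
continuity-corrected normal approximation, matching
`stats::wilcox.test`. Absolute p-values differ from the original
software's; the thresholded behaviour is the tested contract. Windows
with fewer than 3 values per group return p = 1.

`detect_transfrags()` emits maximal runs of passing probes
(|fold| ≥ 2, p ≤ 0.05, consistent sign, inter-probe gaps ≤ 48 nt) that
span ≥ 80 nt and contain ≥ 10 passing probes; bounds are the first and
last passing probe. `merge_transfrags()` joins neighbours iteratively
(to a fixed point) when the gap is ≤ 250 bp, strands and directions
match, and *every* intervening probe's fold change has the transfrag's
sign (p unconstrained — "consistent change" is a sign condition).
`filter_annotated()` removes transfrags whose same-strand overlap with
annotation (union of overlaps) exceeds 20% of their length — strictly
more than, so exactly 20% survives.

`classify_transfrags()` assigns orientation relative to genes within
3 kb of the transfrag's 5′ end, nearest gene first: overlap with an
opposite-strand gene ⇒ *intragenic-antisense*; an opposite-strand gene
whose TSS-proximal end faces the 5′ end ⇒ *diverging* (shared promoter
region); opposite-strand, TES-proximal end facing, transfrag pointing at
the gene ⇒ *converging*, pointing away ⇒ *tandem-antisense*; same-strand
gene with the transfrag downstream of its TES ⇒ *tandem-sense*;
otherwise *unclassified*. The tandem-sense/tandem-antisense distinction
is not fully pinned down in the original description; the rule above is
this package's documented convention, with non-overlapping gene
geometries making *tandem-antisense* rare by construction.

`union_regions()` collapses same-strand overlapping transfrags across
conditions into a non-redundant union and reports each condition's mean
fold change per union region.

# Signatures

The NDR is operationalized as the 200-bp window directly upstream of the
TSS, abutting but excluding it (`ndr_window()`; minus-strand genes are
mirrored). `ndr_occupancy_change()` averages a Δlog2-occupancy track
(condition − wild type) over that window, flagging windows truncated by
a chromosome end.

`detect_tcr()` implements the co-repressor de-repression signature: an
*up* transfrag whose 200-bp upstream window (anchored at the transfrag's
own 5′ end, since these are novel transcripts without curated TSSs)
shows a mean occupancy decrease of at least 1.5-fold
(Δlog2 ≤ −log2 1.5 ≈ −0.585). Hits are categorized *subtelomeric* (5′
end within 25 kb of a chromosome end — a configurable convention; the
original asserts subtelomeric identity without a numeric rule), else
*antisense* (intragenic-antisense class), else *intergenic*. The
occupancy change is measured on the fully preprocessed Δ track.
Raising the fold requirement can only remove hits (monotonicity is
tested), and every hit re-passes both sub-thresholds when re-measured
directly.

`detect_pat()` calls a transfrag a promoter-associated transcript when
its 5′ end lies inside some gene's NDR window (ties between two genes'
windows go to the nearer TSS) and reports the fraction of hits at
diverging versus tandem promoters, where a promoter's configuration is
the orientation of its nearest upstream neighbor gene (opposite strand ⇒
diverging, same strand ⇒ tandem).

`tss_profile()` aligns occupancy to the TSS (strand-aware, minus-strand
genes reflected) and averages per offset; on the default generator
geometry it shows the NDR trough upstream of the TSS and phased peaks at
+74, +239, +404, … `rank_by_ndr()` orders genes by mean NDR occupancy
change, pairs them with expression changes, and reports the Spearman
correlation (declared undefined for degenerate inputs rather than
guessed).

# Orchestration and numerical choices

`pipeline_config()` carries every threshold with its study default
(kernel sd 25 / support 50 bp; 100-bp separation and matching window;
10% score exclusion; 10-bp minimum shift at α 0.05; 4-bp median flag;
30-bp probe bandwidth; 2-fold / p 0.05 / 80-nt / 10-probe / 48-nt
transfrag rule; 250-bp merge; 20% overlap; 3-kb flank; 200-bp NDR;
1.5-fold occupancy decrease; 25-bp profile smoothing; 5-kb baseline
window) and round-trips losslessly through YAML. `run_pipeline()` wires
preprocess → call → shifts → transfrags → signatures, halts with the
stage name on failure, and writes a manifest of output checksums;
reruns on identical inputs are bit-identical.

Numerical conventions, in one place: coordinates are 1-based fully
closed internally and converted only at I/O boundaries (BED/bedGraph
0-based half-open); all randomness flows through explicitly passed
seeds, and generators save/restore the global RNG state; kernel and
window discretizations happen on each track's own grid; degenerate
inputs (empty tracks, zero-spread samples, too-small panels or windows)
return flagged or neutral results rather than errors wherever the
downstream contract allows.

# Problem sizes

The test-suite scenarios use 4–500-gene genomes (up to ~1 Mb at 4-bp
probe spacing): 500 genes for the spacing recovery, 200 genes with a
31-sample wild-type panel for shift recovery and specificity, 100 genes
with 20 planted transcripts for transfrag recovery, and 60-gene genomes
for the signature scans. The analysis drivers run a 300-gene compendium
scenario. These sizes give thousands of nucleosomes and dozens of
planted events per property while keeping any single script's runtime in
the minutes range on one CPU.

# Known limitations

* The simulators share one noise family (log2 Gaussian); real arrays
  have heavier-tailed artifacts and spatially correlated noise that the
  baseline detrend only partially emulates.
* Single called positions carry a few bp of stochastic error at the
  default noise level; per-nucleosome shift estimates inherit that and
  should be read through the significance rule.
* The orientation-classification convention and the subtelomeric
  distance are package conventions where the original text is silent;
  both are parameters, not hard-coded.
* The caller does not model nucleosome fuzziness or occupancy classes;
  a call is a center estimate with a score, nothing more.
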