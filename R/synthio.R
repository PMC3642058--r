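#' Specify a synthetic yeast-like genome
#'
#' Defines the geometry used by [build_genome()]: non-overlapping genes laid
#' down along each chromosome, every gene carrying a nucleosome-depleted
#' region (NDR) directly upstream of its TSS followed by a regularly phased
#' array of nucleosomes across the gene body.  Defaults emulate budding
#' yeast: 147-bp nucleosome cores separated by ~18-bp linkers (165-bp
#' repeat), 200-bp promoter NDRs, and a tiling-array probe grid with 4-bp
#' spacing.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp, or `NULL` to size each
#'   chromosome automatically to fit its genes.  When given it must be a
#'   multiple of `probe_spacing`.
#' @param n_genes total number of genes (split evenly across chromosomes).
#' @param gene_length_mean mean gene length in bp (lengths are drawn from a
#'   truncated normal).
#' @param intergenic_length_mean mean intergenic gap in bp (floored at
#'   `ndr_width` so promoter NDRs always fit).
#' @param gene_length_sd,intergenic_length_sd spread of the length draws in
#'   bp; defaults are 20% / 25% of the respective means, 0 makes lengths
#'   deterministic.
#' @param ndr_width promoter NDR width in bp.
#' @param core_width nucleosome core width in bp.
#' @param linker_length linker DNA length in bp; the nucleosome repeat is
#'   `core_width + linker_length`.
#' @param probe_spacing probe grid step in bp.
#' @param strands optional explicit strand vector (recycled over genes);
#'   `NULL` draws strands at random.
#' @param seed integer seed making the genome reproducible.
#' @return an object of class `genome_spec` (a validated list).
#' @export
genome_spec <- function(n_chromosomes = 2L, chrom_length = NULL,
                        n_genes = 100L, gene_length_mean = 1500,
                        gene_length_sd = NULL,
                        intergenic_length_mean = 600,
                        intergenic_length_sd = NULL, ndr_width = 200,
                        core_width = 147, linker_length = 18,
                        probe_spacing = 4, strands = NULL, seed = 1L) {
  stopifnot_scalar(n_chromosomes, "n_chromosomes")
  stopifnot_scalar(n_genes, "n_genes")
  stopifnot_scalar(gene_length_mean, "gene_length_mean")
  stopifnot_scalar(intergenic_length_mean, "intergenic_length_mean")
  stopifnot_scalar(ndr_width, "ndr_width")
  stopifnot_scalar(core_width, "core_width")
  stopifnot_scalar(linker_length, "linker_length")
  stopifnot_scalar(probe_spacing, "probe_spacing")
  if (gene_length_mean < core_width)
    stop("gene_length_mean too small: a gene must hold at least one ",
         "nucleosome core (core_width)", call. = FALSE)
  if (!is.null(chrom_length)) {
    stopifnot_scalar(chrom_length, "chrom_length")
    if (chrom_length %% probe_spacing != 0)
      stop("chrom_length must be a multiple of probe_spacing", call. = FALSE)
  }
  if (!is.null(strands) && !all(strands %in% c("+", "-")))
    stop("strands must be '+' or '-'", call. = FALSE)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length,
    n_genes = as.integer(n_genes),
    gene_length_mean = gene_length_mean,
    gene_length_sd = gene_length_sd %||% 0.2 * gene_length_mean,
    intergenic_length_mean = intergenic_length_mean,
    intergenic_length_sd = intergenic_length_sd %||%
      0.25 * intergenic_length_mean,
    ndr_width = ndr_width, core_width = core_width,
    linker_length = linker_length, probe_spacing = probe_spacing,
    strands = strands, seed = as.integer(seed)
  ), class = "genome_spec")
}

#' Describe a perturbation with known ground truth
#'
#' Bundles the injectable effects the simulators understand: targeted
#' nucleosome shifts, interval-wise occupancy scaling, cryptic transcripts,
#' and global histone depletion.
#'
#' @param shift_map data.frame with columns `gene_id`, `index` (genic
#'   nucleosome index, +1 = first downstream of the TSS) and `shift_bp`
#'   (signed; positive = away from the TSS).
#' @param occupancy_scale data.frame with columns `chrom`, `start`, `end`,
#'   `factor` (> 0); occupancy on the interval is multiplied by `factor`.
#' @param cryptic data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `fold` (> 0); treatment expression on the interval/strand is multiplied
#'   by `fold`.
#' @param histone_depletion fraction in \[0, 1\] by which nucleosomal signal
#'   is globally reduced.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(shift_map = NULL, occupancy_scale = NULL,
                              cryptic = NULL, histone_depletion = 0) {
  if (!is.null(shift_map))
    stopifnot(all(c("gene_id", "index", "shift_bp") %in% names(shift_map)))
  if (!is.null(occupancy_scale)) {
    stopifnot(all(c("chrom", "start", "end", "factor") %in%
                    names(occupancy_scale)))
    if (any(occupancy_scale$factor <= 0))
      stop("occupancy scale factors must be > 0", call. = FALSE)
  }
  if (!is.null(cryptic)) {
    stopifnot(all(c("chrom", "start", "end", "strand", "fold") %in%
                    names(cryptic)))
    if (any(cryptic$fold <= 0))
      stop("cryptic fold changes must be > 0", call. = FALSE)
  }
  if (histone_depletion < 0 || histone_depletion > 1)
    stop("histone_depletion must be in [0, 1]", call. = FALSE)
  structure(list(shift_map = shift_map, occupancy_scale = occupancy_scale,
                 cryptic = cryptic, histone_depletion = histone_depletion),
            class = "perturbation_spec")
}

#' Build a synthetic genome with known nucleosome positions
#'
#' Lays genes along each chromosome separated by intergenic gaps.  Each gene
#' gets a promoter NDR (no nucleosomes) directly upstream of its TSS and a
#' phased array: the +1 nucleosome center sits `ceiling(core_width/2)` bp
#' downstream of the TSS and consecutive centers are spaced by
#' `core_width + linker_length` bp, as long as a full core fits inside the
#' gene body.  Minus-strand genes are mirror images (TSS at the right end).
#'
#' Intergenic space outside NDRs is also nucleosomal, as in real
#' chromatin: filler nucleosomes at the same repeat length occupy the gaps
#' (rows with `gene_id = NA`, `index = 0` in `centers`), keeping a clear
#' margin around gene bodies and NDR windows.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `nuc_genome`: a list with `genes` (data.frame:
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, `tes`), `centers`
#'   (data.frame: `gene_id`, `chrom`, `index`, `pos`; genic rows plus
#'   intergenic filler rows), `chrom_lengths` (named integer) and the
#'   originating `spec`.  All coordinates are 1-based and fully closed.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  rep_len_ <- spec$core_width + spec$linker_length
  off1 <- ceiling(spec$core_width / 2)       # +1 center offset from the TSS
  half_down <- floor(spec$core_width / 2)    # core half-width downstream
  min_gene <- off1 + half_down               # shortest gene with 1 nucleosome

  with_seed(spec$seed, {
    per_chrom <- diff(round(seq(0, spec$n_genes,
                                length.out = spec$n_chromosomes + 1)))
    strands_all <- if (is.null(spec$strands)) {
      sample(c("+", "-"), spec$n_genes, replace = TRUE)
    } else rep_len(spec$strands, spec$n_genes)

    genes <- vector("list", spec$n_chromosomes)
    centers <- vector("list", spec$n_chromosomes)
    chrom_lengths <- integer(spec$n_chromosomes)
    names(chrom_lengths) <- paste0("chr", seq_len(spec$n_chromosomes))
    gid <- 0L
    for (ci in seq_len(spec$n_chromosomes)) {
      chrom <- names(chrom_lengths)[ci]
      ng <- per_chrom[ci]
      if (ng == 0L) next
      gl <- pmax(min_gene, round(rnorm(ng, spec$gene_length_mean,
                                       spec$gene_length_sd)))
      ig <- pmax(spec$ndr_width, round(rnorm(ng, spec$intergenic_length_mean,
                                             spec$intergenic_length_sd)))
      start <- cumsum(ig) + cumsum(c(0, head(gl, -1))) + 1L
      end <- start + gl - 1L
      need <- end[ng] + spec$intergenic_length_mean
      if (!is.null(spec$chrom_length) && need > spec$chrom_length)
        stop("geometry infeasible: genes do not fit on chrom_length ",
             spec$chrom_length, " (need ", need, " bp); increase ",
             "chrom_length or reduce n_genes/gene_length_mean",
             call. = FALSE)
      clen <- spec$chrom_length %||%
        (ceiling(need / spec$probe_spacing) * spec$probe_spacing)
      chrom_lengths[ci] <- as.integer(clen)

      str <- strands_all[gid + seq_len(ng)]
      tss <- ifelse(str == "+", start, end)
      tes <- ifelse(str == "+", end, start)
      ids <- sprintf("g%04d", gid + seq_len(ng))
      genes[[ci]] <- data.frame(
        gene_id = ids, chrom = chrom, start = start, end = end,
        strand = str, tss = tss, tes = tes, stringsAsFactors = FALSE)

      cl <- lapply(seq_len(ng), function(i) {
        n_nuc <- (gl[i] - half_down - off1) %/% rep_len_ + 1L
        if (n_nuc < 1L) return(NULL)
        offs <- off1 + (seq_len(n_nuc) - 1L) * rep_len_
        pos <- if (str[i] == "+") tss[i] + offs else tss[i] - offs
        data.frame(gene_id = ids[i], chrom = chrom,
                   index = seq_len(n_nuc), pos = as.integer(pos),
                   stringsAsFactors = FALSE)
      })
      genic_cen <- do.call(rbind, cl)

      # nucleosomal filler in intergenic space, clear of gene bodies,
      # NDR windows and a protection margin
      margin <- half_down + 17L
      blocked <- cbind(start - margin,  end + margin)
      ndr_lo <- ifelse(str == "+", tss - spec$ndr_width, tss + 1L)
      ndr_hi <- ifelse(str == "+", tss - 1L, tss + spec$ndr_width)
      blocked <- rbind(blocked, cbind(ndr_lo - margin, ndr_hi + margin))
      blocked <- blocked[order(blocked[, 1]), , drop = FALSE]
      free <- list()
      cursor <- 1L
      for (bi in seq_len(nrow(blocked))) {
        if (blocked[bi, 1] > cursor)
          free[[length(free) + 1L]] <- c(cursor, blocked[bi, 1] - 1L)
        cursor <- max(cursor, blocked[bi, 2] + 1L)
      }
      if (cursor <= clen)
        free[[length(free) + 1L]] <- c(cursor, clen)
      filler_pos <- unlist(lapply(free, function(iv) {
        lo <- iv[1] + half_down
        hi <- iv[2] - half_down
        if (hi < lo) return(integer())
        seq.int(lo, hi, by = rep_len_)
      }))
      filler <- if (length(filler_pos))
        data.frame(gene_id = NA_character_, chrom = chrom, index = 0L,
                   pos = as.integer(filler_pos), stringsAsFactors = FALSE)
      else NULL
      centers[[ci]] <- rbind(genic_cen, filler)
      gid <- gid + ng
    }
    structure(list(
      genes = do.call(rbind, genes),
      centers = do.call(rbind, centers),
      chrom_lengths = chrom_lengths,
      spec = spec
    ), class = "nuc_genome")
  })
}

# Resolve perturbed center positions: apply the shift map (strand-aware,
# positive = away from the TSS) and attach per-center occupancy scale
# factors.  Errors if a shift pushes a center outside its gene body or off
# the chromosome.  `interval_scale` controls whether occupancy_scale
# factors are folded into the per-center scale (used for read-pair depth);
# the array simulator applies interval factors position-wise instead.
perturbed_centers <- function(genome, perturbation = NULL,
                              interval_scale = TRUE) {
  cen <- genome$centers
  cen$scale <- 1
  if (is.null(perturbation)) return(cen)
  stopifnot(inherits(perturbation, "perturbation_spec"))
  sm <- perturbation$shift_map
  if (!is.null(sm) && nrow(sm)) {
    genes <- genome$genes
    key <- paste(cen$gene_id, cen$index)
    for (i in seq_len(nrow(sm))) {
      j <- match(paste(sm$gene_id[i], sm$index[i]), key)
      if (is.na(j))
        stop("shift_map refers to unknown nucleosome ", sm$gene_id[i],
             ":+", sm$index[i], call. = FALSE)
      g <- genes[genes$gene_id == sm$gene_id[i], ]
      newpos <- cen$pos[j] + strand_dir(g$strand) * sm$shift_bp[i]
      if (newpos < 1 || newpos > genome$chrom_lengths[[g$chrom]])
        stop("shift pushes nucleosome ", sm$gene_id[i], ":+", sm$index[i],
             " off the chromosome", call. = FALSE)
      if (newpos < g$start || newpos > g$end)
        stop("shift pushes nucleosome ", sm$gene_id[i], ":+", sm$index[i],
             " outside its gene body", call. = FALSE)
      cen$pos[j] <- newpos
    }
  }
  os <- perturbation$occupancy_scale
  if (interval_scale && !is.null(os) && nrow(os)) {
    for (i in seq_len(nrow(os))) {
      hit <- cen$chrom == os$chrom[i] & cen$pos >= os$start[i] &
        cen$pos <= os$end[i]
      cen$scale[hit] <- cen$scale[hit] * os$factor[i]
    }
  }
  if (perturbation$histone_depletion > 0)
    cen$scale <- cen$scale * (1 - perturbation$histone_depletion)
  cen
}

# Expected linear-scale occupancy on one chromosome's probe grid: a
# triangular kernel of half-width floor(core_width/2) over each center plus
# a flat background; interval scale factors multiply the total.
expected_occupancy <- function(genome, cen, chrom, positions,
                               background = 0.1, perturbation = NULL) {
  hw <- floor(genome$spec$core_width / 2)
  occ <- rep(background, length(positions))
  cc <- cen[cen$chrom == chrom, ]
  step <- genome$spec$probe_spacing
  p0 <- positions[1]
  n <- length(positions)
  for (i in seq_len(nrow(cc))) {
    lo <- max(1L, ceiling((cc$pos[i] - hw - p0) / step) + 1L)
    hi <- min(n, floor((cc$pos[i] + hw - p0) / step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    occ[idx] <- occ[idx] +
      cc$scale[i] * (1 - abs(positions[idx] - cc$pos[i]) / hw)
  }
  os <- if (!is.null(perturbation)) perturbation$occupancy_scale else NULL
  if (!is.null(os) && nrow(os)) {
    for (i in seq_len(nrow(os))) {
      if (os$chrom[i] != chrom) next
      hit <- positions >= os$start[i] & positions <= os$end[i]
      occ[hit] <- occ[hit] * os$factor[i]
    }
  }
  occ
}

probe_grid <- function(genome, chrom) {
  step <- genome$spec$probe_spacing
  seq.int(step, genome$chrom_lengths[[chrom]], by = step)
}

#' Simulate tiling-array nucleosome occupancy intensities
#'
#' Produces probe-level linear intensities whose expected log2 equals the
#' synthetic occupancy signal: a triangular kernel of half-width
#' `floor(core_width/2)` over each (possibly perturbed) nucleosome center,
#' summed, plus a flat background.  Probe noise is i.i.d. Gaussian on the
#' log2 scale.  Each probe additionally carries a multiplicative affinity
#' effect shared by all hybridizations of that probe (sequence-dependent
#' hybridization efficiency), and a genomic-DNA control column per
#' replicate measures affinity alone — forming the sample/control ratio in
#' preprocessing cancels the affinity, as on real arrays.
#'
#' NDR probes therefore have expected signal below genic probes, and scaling
#' occupancy on an interval by a factor `f` moves its expected log2 signal
#' by `log2(f)`.
#'
#' @param genome a [build_genome()] result.
#' @param perturbation optional [perturbation_spec()].
#' @param noise_sd probe noise sd in log2 units.
#' @param n_replicates number of MNase sample replicates.
#' @param seed integer seed.
#' @param background flat background occupancy added under every probe
#'   (incomplete MNase digestion / cross-hybridization floor; the default
#'   gives an NDR-trough to array-peak range of ~2 log2 units, matching
#'   the dynamic range of yeast MNase tiling tracks).
#' @param affinity_sd sd (log2 units) of the per-probe affinity effect;
#'   the default reflects the order-of-magnitude probe-to-probe intensity
#'   spread of short-oligo tiling arrays, which dominates the raw
#'   intensity distribution of every hybridization.
#'   The affinity field is a fixed property of the array design: it is
#'   drawn from `genome$spec$seed`, not from `seed`, so all conditions
#'   simulated on one genome share it.
#' @param n_controls number of genomic-DNA control hybridizations (the
#'   array batch carries four independent gDNA controls).
#' @return a `probe_matrix`: data.frame with `chrom`, `pos`, `strand` (`.`)
#'   and one intensity column per sample (`nuc_rep1..n`, `gdna_rep1..n`).
#'   Attribute `sample_cols`/`control_cols` name the two groups.
#' @export
simulate_occupancy <- function(genome, perturbation = NULL, noise_sd = 0.2,
                               n_replicates = 2L, seed = 1L,
                               background = 0.35, affinity_sd = 1.2,
                               n_controls = 4L) {
  stopifnot(inherits(genome, "nuc_genome"), noise_sd >= 0, n_replicates >= 1)
  cen <- perturbed_centers(genome, perturbation, interval_scale = FALSE)
  chroms <- names(genome$chrom_lengths)
  affinity <- with_seed(genome$spec$seed + 10000L, {
    lapply(chroms, function(ch)
      2^rnorm(length(probe_grid(genome, ch)), 0, affinity_sd))
  })
  names(affinity) <- chroms
  with_seed(seed, {
    per_chrom <- lapply(chroms, function(ch) {
      pos <- probe_grid(genome, ch)
      occ <- expected_occupancy(genome, cen, ch, pos,
                                background = background,
                                perturbation = perturbation)
      aff <- affinity[[ch]]
      df <- data.frame(chrom = ch, pos = pos, strand = ".",
                       stringsAsFactors = FALSE)
      for (r in seq_len(n_replicates))
        df[[paste0("nuc_rep", r)]] <-
          occ * aff * 2^rnorm(length(pos), 0, noise_sd)
      for (r in seq_len(n_controls))
        df[[paste0("gdna_rep", r)]] <- aff * 2^rnorm(length(pos), 0, noise_sd)
      df
    })
    out <- do.call(rbind, per_chrom)
    rownames(out) <- NULL
    attr(out, "sample_cols") <- paste0("nuc_rep", seq_len(n_replicates))
    attr(out, "control_cols") <- paste0("gdna_rep", seq_len(n_controls))
    class(out) <- c("probe_matrix", "data.frame")
    out
  })
}

#' Simulate strand-specific expression intensities
#'
#' Baseline expression covers each annotated gene on its own strand on top
#' of a flat background; planted cryptic transcripts multiply treatment
#' intensity on their stated interval and strand by their fold change.
#' Noise is i.i.d. Gaussian on the log2 scale, so in the noise-free limit
#' the mean treatment-minus-control log2 difference over a planted interval
#' equals `log2(fold)` on its strand and 0 elsewhere.
#'
#' @inheritParams simulate_occupancy
#' @param gene_level linear expression level over gene bodies.
#' @param background linear background level.
#' @return a `probe_matrix` with rows for both strands and columns
#'   `treat_rep1..n` / `ctrl_rep1..n`.
#' @export
simulate_expression <- function(genome, perturbation = NULL, noise_sd = 0.2,
                                n_replicates = 2L, seed = 1L,
                                gene_level = 8, background = 1) {
  stopifnot(inherits(genome, "nuc_genome"), noise_sd >= 0)
  cr <- if (!is.null(perturbation)) perturbation$cryptic else NULL
  if (!is.null(cr) && nrow(cr)) {
    for (i in seq_len(nrow(cr))) {
      L <- genome$chrom_lengths[[cr$chrom[i]]]
      if (is.null(L) || cr$start[i] < 1 || cr$end[i] > L)
        stop("cryptic transcript interval ", cr$chrom[i], ":",
             cr$start[i], "-", cr$end[i], " lies outside the chromosome",
             call. = FALSE)
    }
  }
  chroms <- names(genome$chrom_lengths)
  with_seed(seed, {
    per_chrom <- lapply(chroms, function(ch) {
      pos <- probe_grid(genome, ch)
      gg <- genome$genes[genome$genes$chrom == ch, ]
      per_strand <- lapply(c("+", "-"), function(s) {
        base <- rep(background, length(pos))
        for (i in which(gg$strand == s)) {
          hit <- pos >= gg$start[i] & pos <= gg$end[i]
          base[hit] <- gene_level
        }
        treat <- base
        if (!is.null(cr) && nrow(cr)) {
          for (i in seq_len(nrow(cr))) {
            if (cr$chrom[i] != ch || cr$strand[i] != s) next
            hit <- pos >= cr$start[i] & pos <= cr$end[i]
            treat[hit] <- treat[hit] * cr$fold[i]
          }
        }
        df <- data.frame(chrom = ch, pos = pos, strand = s,
                         stringsAsFactors = FALSE)
        for (r in seq_len(n_replicates))
          df[[paste0("treat_rep", r)]] <-
            treat * 2^rnorm(length(pos), 0, noise_sd)
        for (r in seq_len(n_replicates))
          df[[paste0("ctrl_rep", r)]] <-
            base * 2^rnorm(length(pos), 0, noise_sd)
        df
      })
      do.call(rbind, per_strand)
    })
    out <- do.call(rbind, per_chrom)
    rownames(out) <- NULL
    attr(out, "sample_cols") <- paste0("treat_rep", seq_len(n_replicates))
    attr(out, "control_cols") <- paste0("ctrl_rep", seq_len(n_replicates))
    class(out) <- c("probe_matrix", "data.frame")
    out
  })
}

#' Simulate paired-end mononucleosome fragments
#'
#' Draws fragments per true (possibly perturbed) nucleosome; each fragment's
#' midpoint is the nucleosome center plus discretized Gaussian jitter and
#' its length is ~147 bp, so the fragment midpoint estimates the nucleosome
#' center.
#'
#' @inheritParams simulate_occupancy
#' @param depth mean fragment count per nucleosome (Poisson).
#' @param jitter_sd sd of the midpoint jitter in bp.
#' @param len_mean,len_sd fragment length distribution (rounded normal).
#' @return data.frame `chrom`, `start`, `end` (1-based closed), sorted by
#'   chromosome and start.
#' @export
simulate_readpairs <- function(genome, perturbation = NULL, depth = 50,
                               jitter_sd = 10, len_mean = 147, len_sd = 0,
                               seed = 1L) {
  stopifnot(inherits(genome, "nuc_genome"), depth > 0, jitter_sd >= 0)
  cen <- perturbed_centers(genome, perturbation)
  with_seed(seed, {
    n_frag <- rpois(nrow(cen), depth * cen$scale)
    tot <- sum(n_frag)
    mids <- rep(cen$pos, n_frag) +
      as.integer(round(rnorm(tot, 0, jitter_sd)))
    lens <- pmax(50L, as.integer(round(rnorm(tot, len_mean, len_sd))))
    start <- mids - lens %/% 2L
    end <- start + lens - 1L
    chrom <- rep(cen$chrom, n_frag)
    keep <- start >= 1L & end <= genome$chrom_lengths[chrom]
    out <- data.frame(chrom = chrom[keep], start = start[keep],
                      end = end[keep], stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$end), ]
    rownames(out) <- NULL
    out
  })
}

#' Ground truth for a simulated scenario
#'
#' Collects the true nucleosome centers, planted cryptic-transcript
#' intervals and planted signature loci implied by a genome plus
#' perturbation, for use as the reference in recovery tests.
#'
#' @param genome a [build_genome()] result.
#' @param perturbation optional [perturbation_spec()].
#' @return list with `true_centers` (data.frame as in `genome$centers`,
#'   after shifts), `true_transfrags` (the planted cryptic intervals) and
#'   `true_signature_loci` (cryptic intervals that also have an occupancy
#'   scale factor < 1 within 200 bp upstream of their 5' end).
#' @export
synthetic_truth <- function(genome, perturbation = NULL) {
  cen <- perturbed_centers(genome, perturbation)
  tf <- if (!is.null(perturbation)) perturbation$cryptic else NULL
  sig <- NULL
  if (!is.null(tf) && nrow(tf) &&
      !is.null(perturbation$occupancy_scale) &&
      nrow(perturbation$occupancy_scale)) {
    os <- perturbation$occupancy_scale
    up_hit <- vapply(seq_len(nrow(tf)), function(i) {
      p5 <- if (tf$strand[i] == "+") tf$start[i] else tf$end[i]
      win <- if (tf$strand[i] == "+") c(p5 - 200, p5 - 1) else c(p5 + 1, p5 + 200)
      any(os$chrom == tf$chrom[i] & os$factor < 1 &
            os$start <= win[2] & os$end >= win[1])
    }, logical(1))
    sig <- tf[up_hit, , drop = FALSE]
  }
  list(true_centers = cen[, c("gene_id", "chrom", "index", "pos")],
       true_transfrags = tf, true_signature_loci = sig)
}
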