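#' Pipeline configuration with study defaults
#'
#' Every tunable threshold of the pipeline in one validated object.  The
#' defaults are the analysis constants used throughout: Gaussian kernel
#' sd 25 bp with 50-bp half-support, 100-bp peak separation and matching
#' window, 10% low-score exclusion, 10-bp minimum shift at alpha 0.05,
#' 4-bp median-shift condition flag, 30-bp probe bandwidth, 2-fold /
#' p 0.05 expression thresholds over >= 80 nt and >= 10 probes with 48-nt
#' probe gaps and 250-bp merging, 20% annotation overlap, 3-kb
#' classification flank, 200-bp NDR, 1.5-fold upstream occupancy decrease,
#' 25-bp profile smoothing and 5-kb baseline window.
#'
#' @param ... named overrides of any default.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    kernel_sd = 25, kernel_half_support = 50,
    min_separation = 100, score_exclusion = 0.10,
    match_window = 100, min_shift = 10, alpha = 0.05,
    median_flag = 4, probe_bandwidth = 30,
    fc_thresh = 2, p_thresh = 0.05,
    min_len = 80, min_probes = 10, max_gap = 48,
    merge_gap = 250, overlap_frac = 0.20,
    flank = 3000, ndr_width = 200, occ_fold = 1.5,
    smoothing = 25, baseline_window = 5000,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration
#'
#' YAML round-trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full occupancy + expression pipeline
#'
#' Wires the stages end to end on one condition versus its wild-type
#' reference: array preprocessing of both occupancy probe matrices,
#' Gaussian-filter nucleosome calling (per condition and per condition
#' replicate), genic assignment, shift records against an optional
#' wild-type panel, transfrag detection / merging / annotation filtering /
#' classification on the expression matrix, and the combined signature
#' scans.  When `outdir` is given, results and a manifest with config and
#' output checksums are written; a rerun on identical inputs and config is
#' bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @param inputs list with `occ_wt`, `occ_cond` (occupancy
#'   `probe_matrix`es), `expr` (expression `probe_matrix`), `genes` (gene
#'   table), `chrom_lengths` (named vector) and optionally `panel` (list
#'   of occupancy probe matrices of independent wild-type conditions).
#' @param outdir optional output directory.
#' @return list with `wt_track`, `cond_track`, `wt_calls`, `cond_calls`,
#'   `wt_genic`, `shifts`, `summary`, `flagged`, `transfrags`, `tcr`,
#'   `pat`, `docc`, and `manifest` when written.
#' @export
run_pipeline <- function(config, inputs, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("occ_wt", "occ_cond", "expr", "genes", "chrom_lengths")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("missing pipeline inputs: ", paste(miss, collapse = ", "),
         call. = FALSE)

  pp <- function(x) preprocess_array(
    x, bandwidth = config$probe_bandwidth,
    baseline_window = config$baseline_window)
  wt_track <- run_stage("preprocess", pp(inputs$occ_wt))
  cond_track <- run_stage("preprocess", pp(inputs$occ_cond))

  caller <- function(track, col = "value") call_nucleosomes(
    track, sd = config$kernel_sd,
    half_support = config$kernel_half_support,
    min_separation = config$min_separation,
    score_fraction = config$score_exclusion, value_col = col)
  wt_calls <- run_stage("nuccall", caller(wt_track))
  cond_calls <- run_stage("nuccall", caller(cond_track))
  occ_cols <- grep("^occ_rep", names(cond_track), value = TRUE)
  cond_rep_calls <- run_stage("nuccall", lapply(occ_cols, function(cl)
    caller(cond_track, col = cl)))

  wt_genic <- run_stage("genic", assign_genic(wt_calls, inputs$genes))

  shifts <- summary_tab <- NULL
  flagged <- NA
  if (nrow(wt_genic)) {
    panel_calls <- if (!is.null(inputs$panel))
      run_stage("panel", lapply(inputs$panel, function(x) caller(pp(x))))
    else list()
    shifts <- run_stage("shiftstats", {
      r <- shift_records(wt_genic, cond_rep_calls, panel_calls,
                         window = config$match_window)
      if (length(panel_calls))
        r <- shift_significance(r, min_shift = config$min_shift,
                                alpha = config$alpha)
      r
    })
    summary_tab <- position_summary(shifts)
    flagged <- flag_condition(summary_tab, threshold = config$median_flag)
  }

  tf <- run_stage("transfrag", {
    st <- probe_stats(inputs$expr, bandwidth = config$probe_bandwidth)
    x <- detect_transfrags(st, fc_thresh = config$fc_thresh,
                           p_thresh = config$p_thresh,
                           min_len = config$min_len,
                           min_probes = config$min_probes,
                           max_gap = config$max_gap)
    x <- merge_transfrags(x, st, max_gap = config$merge_gap)
    x <- filter_annotated(x, inputs$genes,
                          max_overlap_frac = config$overlap_frac)
    classify_transfrags(x, inputs$genes, flank = config$flank)
  })

  docc <- run_stage("signatures", occupancy_change(cond_track, wt_track))
  tcr <- run_stage("signatures", detect_tcr(
    tf, docc, inputs$chrom_lengths, occ_fold = config$occ_fold,
    upstream_width = config$ndr_width))
  pat <- run_stage("signatures", detect_pat(tf, inputs$genes,
                                            ndr_width = config$ndr_width))

  res <- list(wt_track = wt_track, cond_track = cond_track,
              wt_calls = wt_calls, cond_calls = cond_calls,
              wt_genic = wt_genic, shifts = shifts,
              summary = summary_tab, flagged = flagged,
              transfrags = tf, tcr = tcr, pat = pat, docc = docc)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      wt_track = "wt_track.bedgraph", cond_track = "cond_track.bedgraph",
      docc = "docc.bedgraph")
    write_bedgraph(wt_track, file.path(outdir, files["wt_track"]))
    write_bedgraph(cond_track, file.path(outdir, files["cond_track"]))
    write_bedgraph(docc, file.path(outdir, files["docc"]))
    tabs <- list(wt_calls = wt_calls, cond_calls = cond_calls,
                 wt_genic = wt_genic, transfrags = tf, tcr = tcr,
                 pat_hits = pat$hits, summary = summary_tab)
    if (!is.null(shifts)) {
      sh <- shifts
      sh$panel_positions <- NULL
      tabs$shifts <- sh
    }
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]])) next
      f <- paste0(nm, ".tsv")
      data.table::fwrite(as.data.frame(tabs[[nm]]),
                         file.path(outdir, f), sep = "\t")
      files[nm] <- f
    }
    cfg_file <- file.path(outdir, "config.yaml")
    write_config(config, cfg_file)
    files["config"] <- "config.yaml"
    paths <- file.path(outdir, files)
    manifest <- list(
      package_version = as.character(utils::packageVersion("nucshift")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      outputs = lapply(stats::setNames(paths, names(files)), function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }
  res
}
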