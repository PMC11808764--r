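# Stage orchestration: simulate -> series -> fit -> trend -> fragstats ->
# perf -> report, each stage reading only the previous stage's files.

PIPELINE_STAGES <- c("simulate", "series", "fit", "trend", "fragstats",
                     "perf", "report", "all")

#' Pipeline configuration
#'
#' A plain list with validated keys; unknown keys are rejected so typos in
#' config files surface immediately.
#'
#' @param enzymes Enzyme names to simulate/analyse.
#' @param seed Integer seed forwarded to the generator.
#' @param engine Search-engine label whose filter defaults apply.
#' @param reference Reference [ce_method()].
#' @param grid Offset grid.
#' @param synth Named list of overrides forwarded to [synthetic_config()].
#' @param criteria [modality_criteria()] for the fit stage.
#' @param mz_range,n_grid Class-comparison options (see
#'   [compare_classes()]).
#' @param nce [nce_params()] for the report.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(enzymes = c("trypsin", "glu_c"), seed = 1L,
                            engine = "MASCOT",
                            reference = default_reference_method(),
                            grid = offset_grid(), synth = list(),
                            criteria = modality_criteria(),
                            mz_range = c(300, 1300), n_grid = 101L,
                            nce = nce_params()) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$enzymes %in% names(builtin_enzymes())))
  structure(cfg, class = "pipeline_config")
}

stage_paths <- function(outdir, enzyme) {
  list(psms = file.path(outdir, sprintf("psms_%s.tsv", enzyme)),
       truth = file.path(outdir, sprintf("truth_%s.tsv", enzyme)),
       proteome = file.path(outdir, sprintf("proteome_%s.fasta", enzyme)),
       series = file.path(outdir, sprintf("series_%s.tsv", enzyme)),
       fits = file.path(outdir, sprintf("fits_%s.tsv", enzyme)),
       optima = file.path(outdir, sprintf("optima_%s.tsv", enzyme)),
       curves = file.path(outdir, sprintf("fragcurves_%s.tsv", enzyme)))
}

# Short hash of the effective configuration, so logs make reruns auditable.
config_fingerprint <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 251)) %%
            .Machine$integer.max)
}

manifest_entry <- function(path) {
  n <- if (file.exists(path))
    length(readLines(path, warn = FALSE)) - 1L else NA_integer_
  data.frame(file = basename(path), rows = n, stringsAsFactors = FALSE)
}

require_upstream <- function(path, stage_needed) {
  if (!file.exists(path))
    stop(sprintf("missing input '%s': run stage '%s' first",
                 basename(path), stage_needed), call. = FALSE)
}

synth_cfg_for <- function(config, enzyme) {
  args <- utils::modifyList(
    list(enzyme = enzyme, reference = config$reference, grid = config$grid,
         engine = config$engine, seed = config$seed),
    config$synth)
  do.call(synthetic_config, args)
}

run_simulate <- function(config, outdir) {
  files <- character(0)
  for (enzyme in config$enzymes) {
    p <- stage_paths(outdir, enzyme)
    sim <- simulate_series(synth_cfg_for(config, enzyme))
    write_psm_tsv(sim$psms, p$psms)
    write_truth_tsv(sim$truth, p$truth)
    write_protein_fasta(sim$proteome, p$proteome)
    files <- c(files, p$psms, p$truth, p$proteome)
  }
  files
}

run_series <- function(config, outdir) {
  params <- filter_params(config$engine)
  files <- character(0)
  for (enzyme in config$enzymes) {
    p <- stage_paths(outdir, enzyme)
    require_upstream(p$psms, "simulate")
    psms <- read_psm_tsv(p$psms)
    accepted <- filter_series(build_series(psms), params, config$grid)
    write_series_tsv(accepted, p$series)
    files <- c(files, p$series)
  }
  files
}

run_fit <- function(config, outdir) {
  files <- character(0)
  for (enzyme in config$enzymes) {
    p <- stage_paths(outdir, enzyme)
    require_upstream(p$series, "series")
    series <- read_series_tsv(p$series)
    fits <- fit_all_series(series, config$grid, config$criteria)
    write_fits_tsv(fits, p$fits)
    files <- c(files, p$fits)
  }
  files
}

run_trend <- function(config, outdir) {
  files <- character(0)
  class_points <- list()
  for (enzyme in config$enzymes) {
    p <- stage_paths(outdir, enzyme)
    require_upstream(p$fits, "fit")
    fits <- utils::read.delim(p$fits, stringsAsFactors = FALSE)
    pts <- optimum_points(fits, config$reference, enzyme)
    utils::write.table(pts, p$optima, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, p$optima)
    cls <- enzyme_class(enzyme)
    class_points[[cls]] <- rbind(class_points[[cls]],
                                 select_points(pts, cls))
  }
  trend_rows <- list(); methods <- list()
  for (cls in names(class_points)) {
    trends <- fit_trends(class_points[[cls]])
    tab <- trends_table(trends); tab$class <- cls
    trend_rows[[cls]] <- tab
    methods[[cls]] <- build_method(trends, floor = config$reference$floor)
    mpath <- file.path(outdir, sprintf("method_%s.yaml", tolower(cls)))
    write_ce_method(methods[[cls]], mpath)
    files <- c(files, mpath)
  }
  tpath <- file.path(outdir, "trends.tsv")
  utils::write.table(do.call(rbind, trend_rows), tpath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, tpath)
  if (all(c("TRYPTIC_LIKE", "ALTERNATIVE") %in% names(class_points))) {
    tt <- fit_trends(class_points$TRYPTIC_LIKE)
    ta <- fit_trends(class_points$ALTERNATIVE)
    cmp <- do.call(rbind, lapply(c("2", "3"), function(z) {
      cc <- compare_classes(tt[[z]], ta[[z]], config$mz_range, config$n_grid)
      data.frame(charge = as.integer(z), mean_delta_ev = cc$mean_delta_ev,
                 percent_lower = cc$percent_lower)
    }))
    cpath <- file.path(outdir, "class_comparison.tsv")
    utils::write.table(cmp, cpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, cpath)
  }
  files
}

run_fragstats <- function(config, outdir) {
  files <- character(0)
  for (enzyme in config$enzymes) {
    p <- stage_paths(outdir, enzyme)
    require_upstream(p$psms, "simulate")
    curves <- average_curves(read_psm_tsv(p$psms))
    write_curves_tsv(curves, p$curves)
    files <- c(files, p$curves)
  }
  files
}

run_perf <- function(config, outdir) {
  ma_path <- file.path(outdir, "method_alternative.yaml")
  require_upstream(ma_path, "trend")
  method_opt <- read_ce_method(ma_path)
  alt <- intersect(config$enzymes, ALTERNATIVE)
  if (length(alt) == 0L)
    stop("perf stage needs an alternative-class enzyme in the config",
         call. = FALSE)
  cfg <- synth_cfg_for(config, alt[1L])
  sim <- simulate_performance_experiment(cfg, method_opt, config$reference)
  params <- accept_params(config$engine)
  acc_a <- lapply(sim$runs_a, accept_peptides, params = params)
  acc_b <- lapply(sim$runs_b, accept_peptides, params = params)
  counts <- function(runs) vapply(runs, function(r)
    length(unique(r$peptide)), integer(1))
  cov <- coverage_comparison(acc_a, acc_b, sim$protein_lengths)
  wf <- winner_fractions(acc_a, acc_b)
  out <- data.frame(
    metric = c("mean_hits_optimized", "mean_hits_reference",
               "hit_gain_percent", "mean_coverage_optimized",
               "mean_coverage_reference", "frac_optimized_higher",
               "frac_reference_higher", "frac_tie"),
    value = c(mean(counts(acc_a)), mean(counts(acc_b)),
              hit_gain(counts(acc_a), counts(acc_b)),
              cov$mean_coverage_a, cov$mean_coverage_b,
              wf$frac_a_higher, wf$frac_b_higher, wf$frac_tie))
  ppath <- file.path(outdir, "perf.tsv")
  utils::write.table(out, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ppath
}

#' Run one pipeline stage
#'
#' Stages communicate only through files under `outdir`, so any stage can
#' be rerun from the previous stage's serialized outputs.
#'
#' @param name Stage name: one of `simulate`, `series`, `fit`, `trend`,
#'   `fragstats`, `perf`, `report`, or `all`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a manifest data.frame (file, rows) of files written.
#' @export
run_stage <- function(name, config, outdir) {
  if (!name %in% PIPELINE_STAGES)
    stop("unknown stage '", name, "'; valid stages: ",
         paste(PIPELINE_STAGES, collapse = ", "), call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") return(run_pipeline(config, outdir))
  files <- switch(name,
                  simulate = run_simulate(config, outdir),
                  series = run_series(config, outdir),
                  fit = run_fit(config, outdir),
                  trend = run_trend(config, outdir),
                  fragstats = run_fragstats(config, outdir),
                  perf = run_perf(config, outdir),
                  report = { rpath <- file.path(outdir, "report.txt")
                             writeLines(ce_report(outdir, config), rpath)
                             rpath })
  manifest <- do.call(rbind, lapply(files, manifest_entry))
  message(sprintf("[%s] seed %d, config %s: wrote %d file(s) under %s",
                  name, config$seed, config_fingerprint(config),
                  nrow(manifest), outdir))
  invisible(manifest)
}

#' Run the full pipeline
#'
#' @inheritParams run_stage
#' @return Invisibly, the combined manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stages <- c("simulate", "series", "fit", "trend", "fragstats", "perf",
              "report")
  invisible(do.call(rbind, lapply(stages, run_stage, config = config,
                                  outdir = outdir)))
}

#' Summarize a pipeline run directory
#'
#' Produces a human-readable summary of the fitted trend lines, the
#' enzyme-class comparison (eV and percent), NCE% equivalents of the
#' fitted methods, the fraction of bimodal peptides with a taller
#' lower-energy peak, the fragment-curve apex offsets, and the
#' performance table when present. Sections whose inputs are missing are
#' omitted with a note.
#'
#' @param outdir Pipeline output directory.
#' @param config The [pipeline_config()] used for the run.
#' @return Character vector of report lines.
#' @export
ce_report <- function(outdir, config = pipeline_config()) {
  lines <- c("Collision-energy optimization report",
             strrep("=", 38))
  tpath <- file.path(outdir, "trends.tsv")
  if (file.exists(tpath)) {
    tr <- utils::read.delim(tpath, stringsAsFactors = FALSE)
    lines <- c(lines, "", "Per-charge trend lines (CE = slope*mz + intercept):")
    lines <- c(lines, sprintf("  %s z=%d: slope %.4f eV/Th, intercept %.2f eV (n=%d, sd %.2f)",
                              tr$class, tr$charge, tr$slope, tr$intercept,
                              tr$n_points, tr$residual_sd))
    for (cls in unique(tr$class)) {
      mpath <- file.path(outdir, sprintf("method_%s.yaml", tolower(cls)))
      if (!file.exists(mpath)) next
      nce <- method_nce_range(read_ce_method(mpath), config$mz_range,
                              config$nce)
      lines <- c(lines, sprintf("  %s NCE%% over m/z %g-%g: z=%d: %.1f-%.1f",
                                cls, nce$mz_lo, nce$mz_hi, nce$charge,
                                nce$nce_lo, nce$nce_hi))
    }
  } else lines <- c(lines, "", "(no trend output; run stage 'trend')")
  cpath <- file.path(outdir, "class_comparison.tsv")
  if (file.exists(cpath)) {
    cmp <- utils::read.delim(cpath)
    lines <- c(lines, "", "Enzyme-class comparison (tryptic minus alternative):",
               sprintf("  z=%d: %.1f eV lower (%.1f%%)", cmp$charge,
                       cmp$mean_delta_ev, cmp$percent_lower),
               sprintf("  pooled: %.1f eV (%.1f%%)", mean(cmp$mean_delta_ev),
                       mean(cmp$percent_lower)))
  }
  # lower-taller fraction over all enzymes with fits
  bi_taller <- integer(0); bi_total <- integer(0)
  for (enzyme in config$enzymes) {
    fpath <- stage_paths(outdir, enzyme)$fits
    if (!file.exists(fpath)) next
    fits <- utils::read.delim(fpath, stringsAsFactors = FALSE)
    bi <- fits[fits$modality == "BIMODAL", , drop = FALSE]
    bi_taller <- c(bi_taller, sum(bi$taller == "LOWER"))
    bi_total <- c(bi_total, nrow(bi))
  }
  if (sum(bi_total) > 0L)
    lines <- c(lines, "",
               sprintf("Bimodal peptides with taller lower-energy peak: %.1f%% (n=%d)",
                       100 * sum(bi_taller) / sum(bi_total), sum(bi_total)))
  any_curves <- FALSE
  for (enzyme in config$enzymes) {
    cpath <- stage_paths(outdir, enzyme)$curves
    if (!file.exists(cpath)) next
    curves <- utils::read.delim(cpath, stringsAsFactors = FALSE)
    if (nrow(curves) == 0L) next
    if (!any_curves) {
      lines <- c(lines, "", "Fragment-curve apex offsets (eV):")
      any_curves <- TRUE
    }
    for (tp in unique(curves$ion_type)) for (st in unique(curves$statistic)) {
      cv <- curves[curves$ion_type == tp & curves$statistic == st, ,
                   drop = FALSE]
      if (nrow(cv) >= 3L)
        lines <- c(lines, sprintf("  %s %s %s: apex at %+g eV", enzyme, tp,
                                  st, curve_peak_offset(cv)))
    }
  }
  if (!any_curves)
    lines <- c(lines, "", "(no fragment statistics; run stage 'fragstats')")
  ppath <- file.path(outdir, "perf.tsv")
  if (file.exists(ppath)) {
    perf <- utils::read.delim(ppath)
    lines <- c(lines, "", "Performance test (optimized vs reference method):",
               sprintf("  %s: %.4g", perf$metric, perf$value))
  }
  lines
}
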