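# Aggregation of PSM tables across the CE grid into per-(peptide, charge)
# score series, and the engine-specific inclusion filters.

PSM_COLUMNS <- c("run_id", "offset", "peptide", "charge", "precursor_mz",
                 "precursor_intensity", "score", "engine", "fragments")

check_psm_table <- function(psms) {
  missing <- setdiff(setdiff(PSM_COLUMNS, "fragments"), names(psms))
  if (length(missing) > 0L)
    stop("PSM table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"fragments" %in% names(psms)) psms$fragments <- ""
  if (any(psms$charge < 1L)) stop("PSM charge must be >= 1", call. = FALSE)
  if (any(psms$score < 0)) stop("PSM scores must be >= 0", call. = FALSE)
  psms
}

#' Read / write PSM tables
#'
#' The PSM dialect is a TSV with header columns `run_id`, `offset`
#' (eV, relative to the reference method), `peptide`, `charge`,
#' `precursor_mz`, `precursor_intensity`, `score`, `engine`
#' (`MASCOT` or `BYONIC`), and optional `fragments` (semicolon-joined
#' `type:index:intensity`, e.g. `"y:3:1200;b:2:90"`).
#'
#' @param path File path.
#' @param psms A PSM data.frame.
#' @return `read_psm_tsv()` returns the PSM data.frame.
#' @export
read_psm_tsv <- function(path) {
  psms <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if ("fragments" %in% names(psms)) {
    psms$fragments <- as.character(psms$fragments)
    psms$fragments[is.na(psms$fragments)] <- ""
  }
  check_psm_table(psms)
}

#' @rdname read_psm_tsv
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score series for one peptide ion
#'
#' @param peptide Peptide sequence.
#' @param charge Precursor charge.
#' @param precursor_mz Precursor m/z in Th.
#' @param engine Search engine label.
#' @param offsets,scores Parallel numeric vectors: the CE offsets at which
#'   the ion was identified and the best score at each.
#' @return Object of class `score_series`.
#' @export
score_series <- function(peptide, charge, precursor_mz, engine,
                         offsets, scores) {
  stopifnot(length(offsets) == length(scores),
            !anyDuplicated(offsets))
  o <- order(offsets)
  structure(list(peptide = peptide, charge = as.integer(charge),
                 precursor_mz = precursor_mz, engine = engine,
                 offsets = offsets[o], scores = scores[o]),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series> %s z=%d (m/z %.2f, %s): %d offsets, max %.1f\n",
              x$peptide, x$charge, x$precursor_mz, x$engine,
              length(x$offsets), max(x$scores)))
  invisible(x)
}

#' Build per-(peptide, charge) score series from a PSM table
#'
#' Different charge states of the same sequence are treated as distinct
#' ions. Duplicate PSMs at one offset (repeated elution, chimeric re-hits)
#' collapse to the maximum score — the best spectrum represents
#' identifiability. The reported precursor m/z is the median over
#' contributing PSMs.
#'
#' @param psms PSM data.frame from one engine (see [read_psm_tsv()]).
#' @return List of [score_series()] objects.
#' @export
build_series <- function(psms) {
  psms <- check_psm_table(psms)
  if (length(unique(psms$engine)) > 1L)
    stop("build_series: PSMs mix search engines; split by engine first",
         call. = FALSE)
  key <- paste(psms$peptide, psms$charge, sep = "\r")
  lapply(split(psms, key), function(g) {
    best <- tapply(g$score, g$offset, max)
    score_series(peptide = g$peptide[1L], charge = g$charge[1L],
                 precursor_mz = stats::median(g$precursor_mz),
                 engine = g$engine[1L],
                 offsets = as.numeric(names(best)),
                 scores = as.numeric(best))
  })
}

#' Longest run of adjacent identified collision energies
#'
#' Counts the longest run of *consecutive grid offsets* at which the series
#' score strictly exceeds `floor_score`. A grid offset with no
#' identification (or a score at/below the floor) breaks the run.
#'
#' @param series A [score_series()].
#' @param floor_score Presence threshold on the engine score.
#' @param grid The experiment's offset grid (default [offset_grid()]).
#' @return Integer run length (0 for an empty series).
#' @export
longest_adjacent_run <- function(series, floor_score, grid = offset_grid()) {
  present <- grid %in% series$offsets[series$scores > floor_score]
  if (!any(present)) return(0L)
  r <- rle(present)
  max(r$lengths[r$values])
}

#' Inclusion-filter parameters
#'
#' Engine-specific criteria deciding which score series are confident
#' enough for the energy-dependent analysis. The defaults reproduce the
#' study criteria: Mascot requires a score above 15 at >= 6 adjacent
#' collision energies and above 25 at least once; Byonic analogously with
#' 100 and 300. Both require peptide length >= 6 and exclude singly charged
#' species (they fragment less efficiently and often are not peptides).
#'
#' @param engine `"MASCOT"` or `"BYONIC"` to get that engine's defaults.
#' @param floor_score Presence threshold (score must exceed it).
#' @param peak_score The series maximum must exceed it at least once.
#' @param min_adjacent Minimum adjacent-run length (see
#'   [longest_adjacent_run()]).
#' @param min_length Minimum peptide length.
#' @param excluded_charges Charges dropped outright.
#' @return Object of class `filter_params`.
#' @export
filter_params <- function(engine = c("MASCOT", "BYONIC"),
                          floor_score = NULL, peak_score = NULL,
                          min_adjacent = 6L, min_length = 6L,
                          excluded_charges = 1L) {
  engine <- match.arg(engine)
  defaults <- switch(engine,
                     MASCOT = c(floor = 15, peak = 25),
                     BYONIC = c(floor = 100, peak = 300))
  if (is.null(floor_score)) floor_score <- defaults[["floor"]]
  if (is.null(peak_score)) peak_score <- defaults[["peak"]]
  if (peak_score < floor_score)
    stop("peak_score must be >= floor_score", call. = FALSE)
  stopifnot(min_adjacent >= 1L)
  structure(list(engine = engine, floor_score = floor_score,
                 peak_score = peak_score, min_adjacent = as.integer(min_adjacent),
                 min_length = as.integer(min_length),
                 excluded_charges = as.integer(excluded_charges)),
            class = "filter_params")
}

#' Apply the inclusion filter to one score series
#'
#' Criteria are checked in a fixed order and the first failure is reported:
#' peptide length, charge, adjacency, peak score.
#'
#' @param series A [score_series()].
#' @param params A [filter_params()].
#' @param grid The experiment offset grid.
#' @return List with `pass` (logical) and `reason` (`"OK"`, `"LENGTH"`,
#'   `"CHARGE"`, `"ADJACENCY"`, or `"PEAK"`).
#' @export
passes_filter <- function(series, params, grid = offset_grid()) {
  if (nchar(series$peptide) < params$min_length)
    return(list(pass = FALSE, reason = "LENGTH"))
  if (series$charge %in% params$excluded_charges)
    return(list(pass = FALSE, reason = "CHARGE"))
  if (longest_adjacent_run(series, params$floor_score, grid) <
      params$min_adjacent)
    return(list(pass = FALSE, reason = "ADJACENCY"))
  if (!any(series$scores > params$peak_score))
    return(list(pass = FALSE, reason = "PEAK"))
  list(pass = TRUE, reason = "OK")
}

#' Filter a list of score series
#'
#' @param series_list List of [score_series()].
#' @inheritParams passes_filter
#' @return The accepted subset, with an attribute `"rejections"` — a table
#'   of rejection reasons.
#' @export
filter_series <- function(series_list, params, grid = offset_grid()) {
  verdicts <- lapply(series_list, passes_filter, params = params, grid = grid)
  keep <- vapply(verdicts, `[[`, logical(1), "pass")
  out <- series_list[keep]
  attr(out, "rejections") <-
    table(vapply(verdicts[!keep], `[[`, character(1), "reason"))
  out
}

#' Serialize score series to / from a long TSV
#'
#' One row per (peptide, charge, offset) with the best score.
#'
#' @param series_list List of [score_series()].
#' @param path File path.
#' @return `read_series_tsv()` returns a list of [score_series()].
#' @export
write_series_tsv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(peptide = s$peptide, charge = s$charge,
               precursor_mz = s$precursor_mz, engine = s$engine,
               offset = s$offsets, score = s$scores,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  rows <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  key <- paste(rows$peptide, rows$charge, sep = "\r")
  unname(lapply(split(rows, key), function(g) {
    score_series(g$peptide[1L], g$charge[1L], g$precursor_mz[1L],
                 g$engine[1L], g$offset, g$score)
  }))
}
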