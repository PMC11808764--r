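# Performance comparison of two CE methods: accepted peptide counts,
# protein sequence coverage, and peptide-level score winners.

#' Acceptance thresholds for performance-test identifications
#'
#' Defaults follow the usual reporting thresholds: Mascot score > 25;
#' Byonic score > 200 together with log Prob > 2. All comparisons are
#' strict.
#'
#' @param engine `"MASCOT"` or `"BYONIC"`.
#' @param min_score Score threshold (strictly exceeded).
#' @param min_logprob Byonic log-probability threshold, or `NULL` to skip.
#' @return Object of class `accept_params`.
#' @export
accept_params <- function(engine = c("MASCOT", "BYONIC"),
                          min_score = NULL, min_logprob = NULL) {
  engine <- match.arg(engine)
  if (is.null(min_score)) min_score <- if (engine == "MASCOT") 25 else 200
  if (engine == "BYONIC" && is.null(min_logprob)) min_logprob <- 2
  structure(list(engine = engine, min_score = min_score,
                 min_logprob = min_logprob),
            class = "accept_params")
}

#' Accept peptides from one run
#'
#' Peptide charges are merged: acceptance is decided on the best score a
#' sequence achieved in the run (and, for Byonic, the best log Prob).
#'
#' @param psms One run's PSM data.frame; may carry `logprob`, `parent_id`,
#'   `start`, `end` columns, which are propagated.
#' @param params An [accept_params()].
#' @return Data.frame with one row per accepted sequence: `peptide`,
#'   `score` (best), plus any mapping columns present.
#' @export
accept_peptides <- function(psms, params = accept_params()) {
  best <- tapply(psms$score, psms$peptide, max)
  ok <- best > params$min_score
  if (!is.null(params$min_logprob)) {
    if (!"logprob" %in% names(psms))
      stop("accept_peptides: log Prob threshold set but no 'logprob' column",
           call. = FALSE)
    best_lp <- tapply(psms$logprob, psms$peptide, max)
    ok <- ok & best_lp[names(best)] > params$min_logprob
  }
  accepted <- names(best)[ok]
  keep_cols <- intersect(c("peptide", "parent_id", "start", "end"),
                         names(psms))
  rows <- psms[psms$peptide %in% accepted, keep_cols, drop = FALSE]
  rows <- rows[!duplicated(rows), , drop = FALSE]
  rows$score <- as.numeric(best[rows$peptide])
  rownames(rows) <- NULL
  rows
}

#' Mean accepted-peptide hit gain of method A over method B
#'
#' `100 * (mean_A - mean_B) / mean_B`, where each mean is the average
#' accepted-peptide count over a method's repeated runs.
#'
#' @param counts_a,counts_b Accepted-peptide counts per repetition.
#' @return Percent gain (positive when A yields more hits).
#' @export
hit_gain <- function(counts_a, counts_b) {
  mb <- mean(counts_b)
  if (mb == 0) stop("hit_gain: method B mean count is zero", call. = FALSE)
  100 * (mean(counts_a) - mb) / mb
}

#' Protein sequence coverage from identified intervals
#'
#' The covered fraction is the size of the union of identified residue
#' positions over the protein length.
#'
#' @param protein_length Protein length in residues (> 0).
#' @param intervals Data.frame with 0-based half-open `start`, `end`
#'   columns (may be empty).
#' @return Fraction in [0, 1].
#' @export
sequence_coverage <- function(protein_length, intervals) {
  if (protein_length <= 0) stop("zero-length protein", call. = FALSE)
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  if (any(intervals$start < 0L | intervals$end > protein_length))
    stop("interval outside protein bounds", call. = FALSE)
  covered <- logical(protein_length)
  for (i in seq_len(nrow(intervals)))
    covered[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
  mean(covered)
}

#' Map accepted peptides onto a protein set
#'
#' Exact substring matching; a peptide matching multiple positions (or
#' multiple proteins) contributes every occurrence.
#'
#' @param peptides Character vector of accepted sequences.
#' @param proteome Named character vector of protein sequences.
#' @return Data.frame (`parent_id`, `start`, `end`) of 0-based half-open
#'   intervals.
#' @export
map_peptides <- function(peptides, proteome) {
  out <- list()
  for (pid in names(proteome)) {
    for (pep in unique(peptides)) {
      hits <- gregexpr(pep, proteome[[pid]], fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        parent_id = pid, start = as.integer(hits) - 1L,
        end = as.integer(hits) - 1L + nchar(pep), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

#' Mean sequence coverage of two CE methods over repeated runs
#'
#' Only proteins identified at least once by *both* methods enter the
#' comparison. Per run, coverage is averaged over those proteins; per
#' method, the run means are averaged over repetitions.
#'
#' @param runs_a,runs_b Lists of per-run accepted-peptide data.frames
#'   carrying `parent_id`, `start`, `end` (e.g. from [accept_peptides()]
#'   on runs of [simulate_performance_experiment()]).
#' @param protein_lengths Named integer vector of protein lengths.
#' @return List with `mean_coverage_a`, `mean_coverage_b`, and `proteins`
#'   (the compared set).
#' @export
coverage_comparison <- function(runs_a, runs_b, protein_lengths) {
  ids <- function(runs) unique(unlist(lapply(runs, `[[`, "parent_id")))
  shared <- intersect(ids(runs_a), ids(runs_b))
  if (length(shared) == 0L)
    stop("coverage_comparison: no protein identified by both methods",
         call. = FALSE)
  run_mean <- function(run) {
    mean(vapply(shared, function(pid) {
      sequence_coverage(protein_lengths[[pid]],
                        run[run$parent_id == pid, , drop = FALSE])
    }, numeric(1)))
  }
  list(mean_coverage_a = mean(vapply(runs_a, run_mean, numeric(1))),
       mean_coverage_b = mean(vapply(runs_b, run_mean, numeric(1))),
       proteins = shared)
}

#' Peptide-level score winner fractions between two CE methods
#'
#' For every peptide identified at least once by both methods, the scores
#' across each method's repetitions are summarised (mean by default, or
#' max) and the method with the larger summary wins that peptide. Exact
#' ties count for neither and are reported separately.
#'
#' @param runs_a,runs_b Lists of per-run accepted-peptide data.frames with
#'   `peptide` and `score`.
#' @param stat `"mean"` or `"max"` score summary across repetitions.
#' @return List with `frac_a_higher`, `frac_b_higher`, `frac_tie`, and
#'   `n_shared`.
#' @export
winner_fractions <- function(runs_a, runs_b, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else max
  summarise <- function(runs) {
    df <- do.call(rbind, lapply(runs, function(r) r[, c("peptide", "score")]))
    tapply(df$score, df$peptide, fun)
  }
  sa <- summarise(runs_a); sb <- summarise(runs_b)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L)
    stop("winner_fractions: no peptide identified by both methods",
         call. = FALSE)
  a_wins <- sum(sa[shared] > sb[shared])
  b_wins <- sum(sb[shared] > sa[shared])
  list(frac_a_higher = a_wins / length(shared),
       frac_b_higher = b_wins / length(shared),
       frac_tie = (length(shared) - a_wins - b_wins) / length(shared),
       n_shared = length(shared))
}
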