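# Seedable generator of complete synthetic CE-series experiments:
# proteome, digestion, PSM tables across the offset grid, fragment
# annotations, and exported ground truth.

# Average amino-acid frequencies (UniProt-style background), used to draw
# random protein sequences.
AA_FREQ <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Configuration of a synthetic CE-series experiment
#'
#' Every distributional choice of the generator is collected here. The
#' defaults describe a plausible bottom-up experiment on a QTof-style
#' instrument with a 21-point CE-offset grid: per-peptide optimum offsets
#' scatter around the enzyme class's shift with 2 eV jitter; the
#' alternative enzyme class (Glu-C, Asp-N, chymotrypsin) sits 10 eV below
#' the tryptic reference; a configurable fraction of peptides is bimodal
#' with the lower-energy peak taller 85% of the time; fragment b/y
#' statistics encode C-terminal basic-residue stabilization of y-ions and
#' a shifted apex for peptides without a basic C-terminus. See the methods
#' vignette for the rationale behind each default.
#'
#' @param enzyme Enzyme name (see [builtin_enzymes()]).
#' @param n_proteins,protein_length_mean,protein_length_sd Proteome size
#'   and length distribution (lengths truncated at >= 50 residues).
#' @param max_missed Missed cleavages allowed in the in-silico digest.
#' @param min_peptide_length Shortest peptide retained.
#' @param mz_window Precursor m/z window in Th.
#' @param charge_probs Named probabilities of precursor charges.
#' @param reference Reference [ce_method()] defining offset 0.
#' @param class_shift Mean optimum offset in eV; `NULL` derives it from
#'   the enzyme class (0 for trypsin/Arg-C, -10 for the others).
#' @param peptide_jitter_sd Per-peptide scatter of the true optimum (eV).
#' @param bimodal_fraction Probability a peptide ion is bimodal.
#' @param bimodal_separation_mean,bimodal_separation_sd Distance between
#'   the two optima (eV; the higher-energy peak sits above the lower).
#' @param lower_taller_prob Probability the lower-energy peak is taller.
#' @param second_amp_range Relative amplitude range of the shorter peak.
#' @param width_mean,width_sd Gaussian peak width distribution (eV),
#'   truncated to [3, 10].
#' @param score_max_meanlog,score_max_sdlog Log-normal peak raw score.
#' @param noise_sd Multiplicative score noise on the normalized scale.
#' @param engine Simulated search engine label.
#' @param detection_floor Minimum score for a PSM to be reported.
#' @param with_fragments Emit b/y fragment annotations?
#' @param y_dominance Fold preference of y- over b-ions for peptides with
#'   a basic C-terminal residue.
#' @param frag_apex_shift Apex of the fragment-detectability curve (eV
#'   offset) for peptides without a basic C-terminus.
#' @param frag_width Width of the fragment-detectability curve (eV).
#' @param grid CE offset grid.
#' @param seed Integer seed; the whole experiment is a pure function of
#'   the config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(enzyme = "trypsin",
                             n_proteins = 12L,
                             protein_length_mean = 350,
                             protein_length_sd = 80,
                             max_missed = 2L,
                             min_peptide_length = 6L,
                             mz_window = c(150, 2200),
                             charge_probs = c(`2` = 0.6, `3` = 0.3,
                                              `4` = 0.1),
                             reference = default_reference_method(),
                             class_shift = NULL,
                             peptide_jitter_sd = 2,
                             bimodal_fraction = 0.3,
                             bimodal_separation_mean = 12,
                             bimodal_separation_sd = 2,
                             lower_taller_prob = 0.85,
                             second_amp_range = c(0.4, 0.85),
                             width_mean = 5, width_sd = 1,
                             score_max_meanlog = log(150),
                             score_max_sdlog = 0.6,
                             noise_sd = 0.1,
                             engine = "MASCOT",
                             detection_floor = 15,
                             with_fragments = TRUE,
                             y_dominance = 2.5,
                             frag_apex_shift = -9,
                             frag_width = 12,
                             grid = offset_grid(),
                             seed = 1L) {
  if (!enzyme %in% names(builtin_enzymes()))
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  if (is.null(class_shift))
    class_shift <- if (enzyme_class(enzyme) == "TRYPTIC_LIKE") 0 else -10
  stopifnot(bimodal_fraction >= 0, bimodal_fraction <= 1,
            lower_taller_prob >= 0, lower_taller_prob <= 1,
            peptide_jitter_sd >= 0, noise_sd >= 0, all(mz_window > 0),
            abs(sum(charge_probs) - 1) < 1e-8)
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

draw_protein_lengths <- function(n, mean, sd) {
  len <- round(stats::rnorm(n, mean, sd))
  pmax(len, 50L)
}

r_proteome <- function(cfg) {
  len <- draw_protein_lengths(cfg$n_proteins, cfg$protein_length_mean,
                              cfg$protein_length_sd)
  seqs <- vapply(len, function(L)
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = ""), character(1))
  names(seqs) <- sprintf("protein_%03d", seq_along(seqs))
  seqs
}

#' Generate a random proteome
#'
#' Sequences are drawn residue-by-residue from a fixed average amino-acid
#' frequency table; lengths are normal, truncated at 50. The output is a
#' deterministic function of the config (including its seed).
#'
#' @param cfg A [synthetic_config()].
#' @return Named character vector of protein sequences.
#' @export
generate_proteome <- function(cfg) {
  set.seed(cfg$seed)
  r_proteome(cfg)
}

# Digest, deduplicate to unique sequences, assign charge, compute m/z and
# apply the length / m/z windows. Returns one row per simulated peptide
# ion plus the full interval table for coverage use.
r_peptide_ions <- function(cfg, charges_allowed = NULL) {
  proteome <- r_proteome(cfg)
  enz <- builtin_enzymes()[[cfg$enzyme]]
  pep <- digest_proteome(proteome, enz, cfg$max_missed)
  pep <- pep[nchar(pep$sequence) >= cfg$min_peptide_length, , drop = FALSE]
  if (nrow(pep) == 0L)
    stop("synthetic digest is empty after filters", call. = FALSE)
  intervals <- pep[, c("sequence", "parent_id", "start", "end")]
  uniq <- pep[!duplicated(pep$sequence), , drop = FALSE]
  charge <- as.integer(sample(names(cfg$charge_probs), nrow(uniq),
                              replace = TRUE, prob = cfg$charge_probs))
  mz <- peptide_mz(uniq$sequence, charge)
  keep <- mz >= cfg$mz_window[1L] & mz <= cfg$mz_window[2L]
  if (!is.null(charges_allowed)) keep <- keep & charge %in% charges_allowed
  ions <- data.frame(peptide = uniq$sequence[keep], charge = charge[keep],
                     mz = mz[keep], length = nchar(uniq$sequence[keep]),
                     stringsAsFactors = FALSE)
  if (nrow(ions) == 0L)
    stop("no peptide ion survives the m/z / charge filters", call. = FALSE)
  list(proteome = proteome, ions = ions, intervals = intervals)
}

# A two-component mixture only deserves the "bimodal" label when the
# resulting curve really has two maxima; heavily overlapping components
# produce a single-maximum (shoulder) curve, which is unimodal by
# definition.
has_two_maxima <- function(a1, a2, sep, w) {
  x <- seq(-2 * w, sep + 2 * w, by = 0.1)
  y <- a1 * exp(-x^2 / (2 * w^2)) + a2 * exp(-(x - sep)^2 / (2 * w^2))
  d <- diff(y)
  sum(d[-length(d)] > 0 & d[-1L] <= 0) >= 2L
}

# Draw a separation conditioned on the mixture having two maxima;
# falls back to a clearly resolved separation if rejection fails.
draw_separation <- function(a1, a2, w, cfg) {
  for (i in 1:30) {
    sep <- abs(stats::rnorm(1L, cfg$bimodal_separation_mean,
                            cfg$bimodal_separation_sd))
    if (has_two_maxima(a1, a2, sep, w)) return(sep)
  }
  4 * w
}

r_truth <- function(cfg, ions) {
  n <- nrow(ions)
  bimodal <- stats::runif(n) < cfg$bimodal_fraction
  center_lower <- cfg$class_shift +
    stats::rnorm(n, 0, cfg$peptide_jitter_sd)
  taller <- ifelse(bimodal,
                   ifelse(stats::runif(n) < cfg$lower_taller_prob,
                          "LOWER", "HIGHER"), NA_character_)
  amp2 <- stats::runif(n, cfg$second_amp_range[1L], cfg$second_amp_range[2L])
  amp_lower <- ifelse(!bimodal | taller == "LOWER", 1, amp2)
  amp_higher <- ifelse(bimodal, ifelse(taller == "HIGHER", 1, amp2),
                       NA_real_)
  width <- pmin(pmax(stats::rnorm(n, cfg$width_mean, cfg$width_sd), 3), 10)
  center_higher <- rep(NA_real_, n)
  for (i in which(bimodal))
    center_higher[i] <- center_lower[i] +
      draw_separation(amp_lower[i], amp_higher[i], width[i], cfg)
  data.frame(
    peptide = ions$peptide, charge = ions$charge, mz = ions$mz,
    enzyme = cfg$enzyme, class = enzyme_class(cfg$enzyme),
    modality = ifelse(bimodal, "BIMODAL", "UNIMODAL"),
    center_lower = center_lower, center_higher = center_higher,
    taller = taller, amp_lower = amp_lower, amp_higher = amp_higher,
    width = width,
    score_max = stats::rlnorm(n, cfg$score_max_meanlog, cfg$score_max_sdlog),
    basicity = vapply(ions$peptide, classify_basicity, character(1),
                      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

truth_curve <- function(truth_row, offsets) {
  y <- truth_row$amp_lower *
    exp(-(offsets - truth_row$center_lower)^2 / (2 * truth_row$width^2))
  if (truth_row$modality == "BIMODAL")
    y <- y + truth_row$amp_higher *
      exp(-(offsets - truth_row$center_higher)^2 / (2 * truth_row$width^2))
  y
}

# Detectability / intensity model of the b and y series for one peptide:
# a Gaussian in offset with per-type amplitude and apex. Peptides with a
# basic C-terminal residue (tryptic/Arg-C products) have y-ions dominating
# b-ions at every offset with the apex at the reference optimum; other
# peptides have comparable b/y with the apex shifted below it.
frag_profile <- function(basicity, cfg) {
  if (basicity == "CTERM_BASIC") {
    list(apex = c(b = 0, y = 0),
         amp = c(b = 0.9 / cfg$y_dominance, y = 0.9))
  } else {
    list(apex = c(b = cfg$frag_apex_shift, y = cfg$frag_apex_shift),
         amp = c(b = 0.65, y = 0.6))
  }
}

r_fragment_string <- function(L, offset, profile, cfg) {
  parts <- character(0)
  for (tp in c("b", "y")) {
    p <- profile$amp[[tp]] *
      exp(-(offset - profile$apex[[tp]])^2 / (2 * cfg$frag_width^2))
    n_ions <- stats::rbinom(1L, L - 1L, min(p, 1))
    if (n_ions == 0L) next
    idx <- sort(sample.int(L - 1L, n_ions))
    # per-ion relative intensities; summed intensity tracks the same
    # detectability curve so count and intensity statistics agree in shape
    total <- p * exp(stats::rnorm(1L, 0, 0.3))
    w <- stats::runif(n_ions); w <- w / sum(w)
    parts <- c(parts, sprintf("%s:%d:%.6g", tp, idx, total * w))
  }
  paste(parts, collapse = ";")
}

#' Simulate a full CE-series experiment
#'
#' Digests a random proteome, assigns charges, draws per-peptide-ion
#' ground-truth score curves (uni- or bimodal Gaussians in offset space),
#' and emits one PSM per grid offset wherever the noisy score exceeds the
#' detection floor, with optional b/y fragment annotations. The PSM table
#' uses the dialect of [read_psm_tsv()].
#'
#' @param cfg A [synthetic_config()].
#' @return List with `psms` (PSM data.frame), `truth` (ground-truth
#'   data.frame, one row per simulated series), and `proteome`.
#' @export
simulate_series <- function(cfg) {
  set.seed(cfg$seed)
  base <- r_peptide_ions(cfg)
  truth <- r_truth(cfg, base$ions)
  offsets <- cfg$grid
  n_off <- length(offsets)
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    curve <- truth_curve(tr, offsets)
    score <- tr$score_max * curve * (1 + stats::rnorm(n_off, 0, cfg$noise_sd))
    score <- pmax(score, 0)
    keep <- score > cfg$detection_floor
    if (!any(keep)) next
    prec_int <- stats::rlnorm(sum(keep), log(1e5), 0.5)
    frags <- if (cfg$with_fragments) {
      prof <- frag_profile(tr$basicity, cfg)
      L <- base$ions$length[i]
      vapply(offsets[keep], function(o)
        r_fragment_string(L, o, prof, cfg), character(1))
    } else ""
    rows[[i]] <- data.frame(
      run_id = sprintf("%s_off%+03d", cfg$enzyme, offsets[keep]),
      offset = offsets[keep], peptide = tr$peptide, charge = tr$charge,
      precursor_mz = tr$mz, precursor_intensity = prec_int,
      score = score[keep], engine = cfg$engine, fragments = frags,
      stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(psms))
    stop("simulate_series: no PSM exceeded the detection floor",
         call. = FALSE)
  rownames(psms) <- NULL
  list(psms = psms, truth = truth, proteome = base$proteome)
}

#' Simulate a performance-test experiment comparing two CE methods
#'
#' Each peptide ion has a true optimal absolute CE (reference line +
#' class shift + jitter). For every method and repetition the applied CE
#' is the method's clamped setting at the ion's m/z, and the score decays
#' as a Gaussian in the distance between applied and optimal CE. Runs
#' differ only through the noise stream.
#'
#' @param cfg A [synthetic_config()].
#' @param method_a,method_b The two [ce_method()]s to compare; only
#'   charges present in both methods are simulated.
#' @param n_repeats Repetitions per method (default 3).
#' @return List with `runs_a`, `runs_b` (lists of per-run data.frames
#'   with `run_id`, `peptide`, `charge`, `score`, `parent_id`, `start`,
#'   `end`), `truth`, `proteome`, and `protein_lengths`.
#' @export
simulate_performance_experiment <- function(cfg, method_a, method_b,
                                            n_repeats = 3L) {
  set.seed(cfg$seed)
  zz <- intersect(names(method_a$lines), names(method_b$lines))
  if (!all(c("2", "3") %in% zz))
    stop("both methods must cover charges 2 and 3", call. = FALSE)
  base <- r_peptide_ions(cfg, charges_allowed = as.integer(zz))
  ions <- base$ions
  n <- nrow(ions)
  opt_ce <- vapply(seq_len(n), function(i)
    reference_ce_unclamped(cfg$reference, ions$mz[i], ions$charge[i]),
    numeric(1)) + cfg$class_shift + stats::rnorm(n, 0, cfg$peptide_jitter_sd)
  width <- pmin(pmax(stats::rnorm(n, cfg$width_mean, cfg$width_sd), 3), 10)
  score_max <- stats::rlnorm(n, cfg$score_max_meanlog, cfg$score_max_sdlog)
  truth <- data.frame(peptide = ions$peptide, charge = ions$charge,
                      mz = ions$mz, opt_ce = opt_ce, width = width,
                      score_max = score_max, stringsAsFactors = FALSE)
  one_run <- function(method, label, rep) {
    applied <- vapply(seq_len(n), function(i)
      applied_ce(method, ions$mz[i], ions$charge[i], 0), numeric(1))
    score <- score_max * exp(-(applied - opt_ce)^2 / (2 * width^2)) *
      (1 + stats::rnorm(n, 0, cfg$noise_sd))
    score <- pmax(score, 0)
    df <- data.frame(run_id = sprintf("%s_rep%d", label, rep),
                     peptide = ions$peptide, charge = ions$charge,
                     score = score, stringsAsFactors = FALSE)
    merge(df, base$intervals, by.x = "peptide", by.y = "sequence")
  }
  runs_a <- lapply(seq_len(n_repeats), function(r) one_run(method_a, "A", r))
  runs_b <- lapply(seq_len(n_repeats), function(r) one_run(method_b, "B", r))
  list(runs_a = runs_a, runs_b = runs_b, truth = truth,
       proteome = base$proteome,
       protein_lengths = vapply(base$proteome, nchar, integer(1)))
}

#' Write the ground-truth table as TSV
#'
#' @param truth Data.frame from [simulate_series()].
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
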