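# Shared fixtures and independent oracles used across the test files.

GRID <- offset_grid()

# Independent brute-force digestion oracle: enumerate every pair of valid
# fragment boundaries and count the cleavage sites strictly inside each
# candidate interval. Site finding is regex-based, unlike the package's
# character-vector implementation.
oracle_digest <- function(sequence, enzyme, max_missed) {
  L <- nchar(sequence)
  pat <- paste0("[", paste(enzyme$target_residues, collapse = ""), "]")
  hits <- gregexpr(pat, sequence)[[1L]]
  hits <- if (hits[1L] == -1L) integer(0) else as.integer(hits)
  sites <- if (enzyme$cut_side == "C_TERMINAL") hits else hits - 1L
  sites <- sites[sites >= 1L & sites <= L - 1L]
  bounds <- c(0L, sites, L)
  pairs <- expand.grid(start = bounds, end = bounds)
  pairs <- pairs[pairs$start < pairs$end, , drop = FALSE]
  pairs$missed <- vapply(seq_len(nrow(pairs)), function(i)
    sum(sites > pairs$start[i] & sites < pairs$end[i]), integer(1))
  pairs <- pairs[pairs$missed <= max_missed, , drop = FALSE]
  pairs[order(pairs$start, pairs$end), , drop = FALSE]
}

random_sequence <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# A score series living on the full grid, generated from a Gaussian
# mixture with multiplicative noise.
make_series <- function(centers, amps, widths, score_max = 100,
                        noise_sd = 0, peptide = "SAMPLEPEP", charge = 2L,
                        mz = 600, engine = "MASCOT", grid = GRID) {
  y <- 0
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(grid - centers[i])^2 / (2 * widths[i]^2))
  scores <- pmax(score_max * y * (1 + rnorm(length(grid), 0, noise_sd)), 0)
  score_series(peptide, charge, mz, engine, grid, scores)
}

# Series with given scores at given offsets (defaults elsewhere).
series_at <- function(offsets, scores, peptide = "SAMPLEPEP", charge = 2L,
                      mz = 600, engine = "MASCOT") {
  score_series(peptide, charge, mz, engine, offsets, scores)
}

# Minimal PSM data.frame constructor for series/fragstats tests.
psm_rows <- function(peptide, charge, offset, score, mz = 600,
                     intensity = 1000, engine = "MASCOT", fragments = "") {
  data.frame(run_id = paste0("run", offset), offset = offset,
             peptide = peptide, charge = charge, precursor_mz = mz,
             precursor_intensity = intensity, score = score,
             engine = engine, fragments = fragments,
             stringsAsFactors = FALSE)
}
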