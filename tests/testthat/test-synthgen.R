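small_cfg <- function(...) {
  synthetic_config(n_proteins = 3, protein_length_mean = 200,
                   with_fragments = FALSE, ...)
}

test_that("the generator is a pure function of its seed", {
  cfg <- small_cfg(seed = 61)
  expect_identical(generate_proteome(cfg), generate_proteome(cfg))
  s1 <- simulate_series(cfg)
  s2 <- simulate_series(cfg)
  expect_identical(s1$psms, s2$psms)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_series(small_cfg(seed = 62))
  expect_false(identical(s1$psms, s3$psms))
})

test_that("proteome respects size, length floor and residue alphabet", {
  cfg <- synthetic_config(n_proteins = 10, protein_length_mean = 60,
                          protein_length_sd = 30, seed = 63)
  prot <- generate_proteome(cfg)
  expect_length(prot, 10L)
  expect_true(all(nchar(prot) >= 50))
  expect_true(all(strsplit(paste(prot, collapse = ""), "")[[1]] %in%
                    c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V")))
})

test_that("emitted PSMs live on the grid and respect the detection floor", {
  cfg <- small_cfg(seed = 64)
  sim <- simulate_series(cfg)
  expect_true(all(sim$psms$offset %in% cfg$grid))
  expect_true(all(sim$psms$score > cfg$detection_floor))
  expect_true(all(nchar(sim$psms$peptide) >= cfg$min_peptide_length))
  expect_true(all(sim$psms$charge %in% as.integer(names(cfg$charge_probs))))
})

test_that("bimodal_fraction 0 produces only unimodal ground truth", {
  sim <- simulate_series(small_cfg(seed = 65, bimodal_fraction = 0))
  expect_true(all(sim$truth$modality == "UNIMODAL"))
  expect_true(all(is.na(sim$truth$center_higher)))
})

test_that("noiseless series peak at the grid point nearest the true optimum", {
  cfg <- small_cfg(seed = 66, noise_sd = 0, detection_floor = 0,
                   bimodal_fraction = 0)
  sim <- simulate_series(cfg)
  ser <- build_series(sim$psms)
  for (s in ser) {
    tr <- sim$truth[sim$truth$peptide == s$peptide &
                      sim$truth$charge == s$charge, ]
    argmax <- s$offsets[which.max(s$scores)]
    nearest <- cfg$grid[which.min(abs(cfg$grid - tr$center_lower))]
    expect_equal(argmax, nearest)
  }
})

test_that("tryptic peptides end in K/R except protein C-terminal products", {
  cfg <- small_cfg(seed = 67)
  sim <- simulate_series(cfg)
  last <- substr(sim$psms$peptide, nchar(sim$psms$peptide),
                 nchar(sim$psms$peptide))
  cterm <- vapply(sim$proteome, function(p)
    substr(p, nchar(p) - 30, nchar(p)), character(1))
  ok <- last %in% c("K", "R") |
    vapply(sim$psms$peptide, function(pep)
      any(endsWith(unname(cterm), substr(pep, nchar(pep) - 2, nchar(pep)))),
      logical(1))
  expect_true(all(ok))
})

test_that("generator marginals recover the configured probabilities", {
  cfg <- synthetic_config(n_proteins = 12, protein_length_mean = 350,
                          with_fragments = FALSE, seed = 68)
  sim <- simulate_series(cfg)
  n <- nrow(sim$truth)
  # 3-sigma binomial bands so a single fixed seed is a reliable check
  frac_bi <- mean(sim$truth$modality == "BIMODAL")
  band <- 3 * sqrt(cfg$bimodal_fraction * (1 - cfg$bimodal_fraction) / n)
  expect_lt(abs(frac_bi - cfg$bimodal_fraction), band)
  bi <- sim$truth[sim$truth$modality == "BIMODAL", ]
  frac_lower <- mean(bi$taller == "LOWER")
  band2 <- 3 * sqrt(cfg$lower_taller_prob * (1 - cfg$lower_taller_prob) /
                      nrow(bi))
  expect_lt(abs(frac_lower - cfg$lower_taller_prob), band2)
  # higher bimodal component sits above the lower one
  expect_true(all(bi$center_higher > bi$center_lower))
})

test_that("performance experiment repeats differ only in noise", {
  cfg <- small_cfg(seed = 69)
  m <- default_reference_method()
  pe <- simulate_performance_experiment(cfg, m, m, n_repeats = 3)
  expect_length(pe$runs_a, 3L)
  expect_length(pe$runs_b, 3L)
  expect_equal(pe$runs_a[[1]]$peptide, pe$runs_a[[2]]$peptide)
  expect_false(identical(pe$runs_a[[1]]$score, pe$runs_a[[2]]$score))
  # deterministic per seed
  pe2 <- simulate_performance_experiment(cfg, m, m, n_repeats = 3)
  expect_identical(pe$runs_a[[1]]$score, pe2$runs_a[[1]]$score)
})
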