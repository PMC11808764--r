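test_that("normalization divides by the maximum and is idempotent", {
  s <- series_at(c(-2, 0, 2), c(10, 20, 40))
  n <- normalize_series(s)
  expect_equal(n$scores, c(0.25, 0.5, 1.0))
  expect_equal(normalize_series(n)$scores, n$scores)
  expect_equal(normalize_series(series_at(0, 7))$scores, 1.0)
  expect_error(normalize_series(series_at(c(0, 2), c(0, 0))), "positive")
})

test_that("one-component fit recovers noiseless Gaussian parameters", {
  v <- exp(-(GRID - (-4))^2 / (2 * 5^2))
  f <- fit_gaussians(GRID, v, 1)
  expect_equal(f$components$center, -4, tolerance = 0.05)
  expect_equal(f$components$width, 5, tolerance = 0.1)
  expect_false(f$edge_flag)
  # symmetry forces the center
  vs <- exp(-(GRID - 6)^2 / (2 * 16))
  expect_equal(fit_gaussians(GRID, vs, 1)$components$center, 6,
               tolerance = 1e-4)
  expect_error(fit_gaussians(GRID[1:3], v[1:3], 1), ">= 4 points")
})

test_that("two-component fit recovers well-separated noiseless peaks", {
  v <- exp(-(GRID - (-8))^2 / (2 * 16)) + 0.7 * exp(-(GRID - 6)^2 / (2 * 16))
  f <- fit_gaussians(GRID, v, 2)
  expect_equal(f$components$center, c(-8, 6), tolerance = 0.2)
  expect_equal(f$components$amplitude, c(1, 0.7), tolerance = 0.05)
  # components come back ordered by center
  expect_true(diff(f$components$center) > 0)
})

test_that("a center beyond the acquisition grid is edge-flagged", {
  v <- exp(-(GRID - 24)^2 / (2 * 36))
  f <- fit_gaussians(GRID, v, 1)
  expect_true(f$edge_flag)
  expect_true(f$components$center > max(GRID))
})

test_that("modality selection accepts real second peaks and rejects noise", {
  # clean single Gaussian: k = 2 gives no significant improvement
  v <- exp(-(GRID - 2)^2 / (2 * 25))
  f1 <- fit_gaussians(GRID, v, 1)
  f2 <- fit_gaussians(GRID, v, 2)
  expect_equal(classify_modality(f1, f2)$modality, "UNIMODAL")
  # well-separated equal peaks
  vb <- exp(-(GRID - (-7))^2 / (2 * 16)) + exp(-(GRID - 7)^2 / (2 * 16))
  fb1 <- fit_gaussians(GRID, vb, 1)
  fb2 <- fit_gaussians(GRID, vb, 2)
  expect_equal(classify_modality(fb1, fb2)$modality, "BIMODAL")
  # separation below the threshold is called unimodal
  crit <- modality_criteria(sep_min = 4)
  fake2 <- fb2
  fake2$components$center <- c(0, 1)
  expect_equal(classify_modality(fb1, fake2, crit)$modality, "UNIMODAL")
  # a missing two-component fit falls back to unimodal
  expect_equal(classify_modality(f1, NULL)$modality, "UNIMODAL")
})

test_that("optimal offsets report centers and the taller peak", {
  v <- exp(-(GRID - (-6))^2 / (2 * 25))
  f <- fit_gaussians(GRID, v, 1)
  f$modality <- "UNIMODAL"
  expect_equal(optimal_offsets(f)$unimodal, -6, tolerance = 0.05)
  vb <- exp(-(GRID - (-8))^2 / (2 * 16)) + 0.6 * exp(-(GRID - 4)^2 / (2 * 16))
  fb <- fit_gaussians(GRID, vb, 2)
  fb$modality <- "BIMODAL"
  oo <- optimal_offsets(fb)
  expect_equal(oo$lower, -8, tolerance = 0.2)
  expect_equal(oo$higher, 4, tolerance = 0.2)
  expect_equal(oo$taller, "LOWER")
  # exact amplitude tie resolves to the lower-energy peak
  fb$components$amplitude <- c(0.8, 0.8)
  expect_equal(optimal_offsets(fb)$taller, "LOWER")
})

test_that("fits are invariant to rescaling the raw scores", {
  set.seed(31)
  s <- make_series(-5, 1, 6, score_max = 80, noise_sd = 0.05)
  s10 <- s
  s10$scores <- s$scores * 17.3
  f <- fit_series(s)
  f10 <- fit_series(s10)
  expect_equal(f$components, f10$components, tolerance = 1e-8)
  expect_equal(f$modality, f10$modality)
})

test_that("fit_all_series tabulates unimodal and bimodal rows", {
  set.seed(32)
  ser <- list(make_series(-4, 1, 6, noise_sd = 0.05, peptide = "AAAAAAK"),
              make_series(c(-9, 5), c(1, 0.7), c(5, 5), noise_sd = 0.05,
                          peptide = "CCCCCCK", charge = 3L))
  fits <- fit_all_series(ser)
  expect_equal(nrow(fits), 2L)
  uni <- fits[fits$peptide == "AAAAAAK", ]
  expect_equal(uni$modality, "UNIMODAL")
  expect_true(is.na(uni$center_higher))
  bi <- fits[fits$peptide == "CCCCCCK", ]
  expect_equal(bi$modality, "BIMODAL")
  expect_equal(bi$center_lower, -9, tolerance = 1)
  expect_equal(bi$taller, "LOWER")
})
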