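make_points <- function(n, charge, enzyme, slope, intercept, jitter = 0,
                        peak_role = "UNIMODAL", mz = NULL, edge = FALSE) {
  if (is.null(mz)) mz <- runif(n, 300, 1300)
  data.frame(peptide = replicate(n, random_sequence(8)), charge = charge,
             mz = mz, enzyme = enzyme,
             modality = ifelse(peak_role == "UNIMODAL", "UNIMODAL", "BIMODAL"),
             peak_role = peak_role, offset = 0,
             ce = slope * mz + intercept + rnorm(n, 0, jitter),
             edge_flag = edge, taller = NA_character_,
             below_floor = FALSE, stringsAsFactors = FALSE)
}

test_that("offset-to-absolute conversion is the reference plus the offset", {
  m <- ce_method(list(ce_line(2, 0, 30), ce_line(3, 0, 40)), floor = 5)
  expect_equal(to_absolute(-6, m, 700, 2), 24)
  expect_equal(to_absolute(0, m, 700, 3), 40)
  # round trip against the reference line
  m2 <- default_reference_method()
  abs_ce <- to_absolute(-3.5, m2, 812, 2)
  expect_equal(abs_ce - (0.05 * 812 + 10), -3.5)
  expect_error(to_absolute(0, m2, 700, 6), "no CE line")
})

test_that("class point selection keeps the documented peak roles and charges", {
  set.seed(41)
  pts <- rbind(make_points(5, 2L, "trypsin", 0.05, 10),
               make_points(5, 2L, "trypsin", 0.05, 5, peak_role = "LOWER"),
               make_points(5, 2L, "trypsin", 0.05, 18, peak_role = "HIGHER"),
               make_points(5, 4L, "trypsin", 0.05, 10))
  sel <- select_points(pts)
  expect_setequal(unique(sel$peak_role), "UNIMODAL")
  expect_true(all(sel$charge %in% c(2L, 3L)))

  alt <- rbind(make_points(5, 3L, "glu_c", 0.04, 0),
               make_points(5, 3L, "glu_c", 0.04, -3, peak_role = "LOWER"),
               make_points(5, 3L, "glu_c", 0.04, 9, peak_role = "HIGHER"))
  sel_alt <- select_points(alt)
  expect_setequal(unique(sel_alt$peak_role), c("UNIMODAL", "LOWER"))
  # idempotent and never grows
  expect_equal(select_points(sel_alt), sel_alt)
  expect_lte(nrow(sel_alt), nrow(alt))
  # edge-flagged points are censored out
  edge <- make_points(4, 2L, "trypsin", 0.05, 10, edge = TRUE)
  expect_equal(nrow(select_points(rbind(pts, edge))), nrow(sel))
  expect_error(enzyme_class("pepsin"), "unknown enzyme")
})

test_that("trend line fitting is exact on two points and unbiased on noise", {
  p2 <- data.frame(peptide = c("a", "b"), charge = 2L, mz = c(500, 1000),
                   enzyme = "trypsin", modality = "UNIMODAL",
                   peak_role = "UNIMODAL", offset = 0, ce = c(20, 30),
                   edge_flag = FALSE, taller = NA, below_floor = FALSE)
  line <- fit_line(p2)
  expect_equal(line$slope, 0.02)
  expect_equal(line$intercept, 10)
  set.seed(42)
  pts <- make_points(200, 2L, "trypsin", 0.05, 10, jitter = 2)
  l <- fit_line(pts)
  expect_lt(abs(l$slope - 0.05), 3 * l$slope_se)
  expect_lt(abs(l$intercept - 10), 3 * l$intercept_se)
  # adding a constant shifts the intercept only
  pts_c <- pts; pts_c$ce <- pts$ce + 7
  l_c <- fit_line(pts_c)
  expect_equal(l_c$slope, l$slope)
  expect_equal(l_c$intercept, l$intercept + 7)
  expect_error(fit_line(pts[1, ]), ">= 2 points")
  same_mz <- pts[1:5, ]; same_mz$mz <- 700
  expect_error(fit_line(same_mz), "distinct")
})

test_that("class comparison reports mean eV and percent differences", {
  lt <- structure(list(slope = 0, intercept = 50, charge = 2L), class = "trend_line")
  la <- structure(list(slope = 0, intercept = 40, charge = 2L), class = "trend_line")
  cc <- compare_classes(lt, la)
  expect_equal(cc$mean_delta_ev, 10)
  expect_equal(cc$percent_lower, 20)
  self <- compare_classes(lt, lt)
  expect_equal(self$mean_delta_ev, 0)
  expect_equal(self$percent_lower, 0)
  la$charge <- 3L
  expect_error(compare_classes(lt, la), "different charges")
})

test_that("lower-taller fraction counts bimodal fits", {
  fits <- data.frame(modality = c("BIMODAL", "BIMODAL", "BIMODAL", "BIMODAL",
                                  "UNIMODAL"),
                     taller = c("LOWER", "LOWER", "LOWER", "HIGHER", NA))
  expect_equal(fraction_lower_taller(fits), 0.75)
  all_lower <- data.frame(modality = "BIMODAL", taller = "LOWER")
  expect_equal(fraction_lower_taller(all_lower), 1.0)
  expect_error(fraction_lower_taller(fits[5, ]), "no bimodal")
})

test_that("basicity classification follows the C-terminal K/R rule", {
  expect_equal(classify_basicity("GGGK"), "CTERM_BASIC")
  expect_equal(classify_basicity("GKGG"), "INTERNAL_BASIC")
  expect_equal(classify_basicity("GGGG"), "NO_BASIC")
  # histidine is basic internally but not a tryptic terminus
  expect_equal(classify_basicity("GGHG"), "INTERNAL_BASIC")
  expect_equal(classify_basicity("GGGH"), "INTERNAL_BASIC")
  expect_equal(classify_basicity("GGGR"), "CTERM_BASIC")
})

test_that("build_method assembles fitted lines with the instrument floor", {
  set.seed(43)
  trends <- fit_trends(rbind(make_points(50, 2L, "trypsin", 0.05, 10, 1),
                             make_points(50, 3L, "trypsin", 0.044, 15, 1)))
  m <- build_method(trends, floor = 5)
  expect_s3_class(m, "ce_method")
  expect_equal(reference_ce(m, 700, 2), 0.05 * 700 + 10, tolerance = 1)
  expect_true(reference_ce(m, 1, 2) >= m$floor)
  expect_error(build_method(trends["2"], floor = 5), "charges 2 and 3")
})

test_that("basicity groups separate by intercept on constructed optima", {
  set.seed(44)
  # generator-style structure: C-terminal basic highest, no-basic lowest
  pts <- rbind(make_points(60, 2L, "trypsin", 0.05, 12, jitter = 2),
               make_points(60, 2L, "glu_c", 0.05, 4, jitter = 2),
               make_points(60, 2L, "glu_c", 0.05, 0, jitter = 2))
  pts$basicity <- rep(c("CTERM_BASIC", "INTERNAL_BASIC", "NO_BASIC"),
                      each = 60)
  ints <- vapply(split(pts, pts$basicity), function(g)
    fit_line(g)$intercept, numeric(1))
  expect_true(ints[["CTERM_BASIC"]] > ints[["INTERNAL_BASIC"]])
  expect_true(ints[["INTERNAL_BASIC"]] > ints[["NO_BASIC"]])
})
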