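test_that("build_series keeps the best duplicate score and splits charges", {
  psms <- rbind(
    psm_rows("PEPTIDEK", 2L, 0, 20),
    psm_rows("PEPTIDEK", 2L, 0, 30),   # duplicate at the same offset
    psm_rows("PEPTIDEK", 2L, 2, 25),
    psm_rows("PEPTIDEK", 2L, 4, 18),
    psm_rows("PEPTIDEK", 3L, 0, 40, mz = 400))
  ser <- build_series(psms)
  expect_length(ser, 2L)
  z2 <- ser[[which(vapply(ser, `[[`, integer(1), "charge") == 2L)]]
  expect_equal(z2$scores[z2$offsets == 0], 30)
  expect_length(z2$offsets, 3L)
  # median precursor m/z over contributing PSMs
  psms2 <- rbind(psm_rows("AAAAAA", 2L, 0, 20, mz = 500),
                 psm_rows("AAAAAA", 2L, 2, 20, mz = 501),
                 psm_rows("AAAAAA", 2L, 4, 20, mz = 509))
  expect_equal(build_series(psms2)[[1]]$precursor_mz, 501)
  psms$engine[1] <- "BYONIC"
  expect_error(build_series(psms), "mix")
})

test_that("longest adjacent run counts consecutive grid offsets only", {
  s <- series_at(c(-2, 0, 2, 4, 10), c(20, 20, 20, 20, 20))
  expect_equal(longest_adjacent_run(s, 15), 4L)
  # a sub-threshold point breaks the run even if identified
  s2 <- series_at(c(-2, 0, 2, 4), c(20, 14, 20, 20))
  expect_equal(longest_adjacent_run(s2, 15), 2L)
  expect_equal(longest_adjacent_run(series_at(0, 10), 15), 0L)
  full <- series_at(GRID, rep(20, 21))
  expect_equal(longest_adjacent_run(full, 15), 21L)
})

test_that("default Mascot and Byonic filters reproduce the inclusion criteria", {
  mascot <- filter_params("MASCOT")
  expect_equal(mascot$floor_score, 15)
  expect_equal(mascot$peak_score, 25)
  byonic <- filter_params("BYONIC")
  expect_equal(byonic$floor_score, 100)
  expect_equal(byonic$peak_score, 300)

  # 6 adjacent offsets above 15, one score above 25, length 8, z 2: accepted
  ok <- series_at(GRID[1:6], c(16, 16, 16, 16, 16, 30), peptide = "AAAAAAAA")
  expect_true(passes_filter(ok, mascot)$pass)
  # singly charged species are excluded
  z1 <- series_at(GRID[1:6], c(16, 16, 16, 16, 16, 30),
                  peptide = "AAAAAAAA", charge = 1L)
  expect_equal(passes_filter(z1, mascot)$reason, "CHARGE")
  # minimum peptide length is 6
  short <- series_at(GRID[1:6], c(16, 16, 16, 16, 16, 30), peptide = "AAAAA")
  expect_equal(passes_filter(short, mascot)$reason, "LENGTH")
  # only 5 adjacent energies: rejected
  adj5 <- series_at(GRID[1:5], c(16, 16, 16, 16, 30), peptide = "AAAAAAAA")
  expect_equal(passes_filter(adj5, mascot)$reason, "ADJACENCY")
  # never above 25: rejected even with a long run
  lowpeak <- series_at(GRID[1:8], rep(24, 8), peptide = "AAAAAAAA")
  expect_equal(passes_filter(lowpeak, mascot)$reason, "PEAK")
  # thresholds are strict: a maximum of exactly 25 does not pass
  at25 <- series_at(GRID[1:6], c(16, 16, 16, 16, 16, 25),
                    peptide = "AAAAAAAA")
  expect_equal(passes_filter(at25, mascot)$reason, "PEAK")

  # Byonic analogues
  bok <- series_at(GRID[1:6], c(150, 150, 150, 150, 150, 400),
                   peptide = "AAAAAAAA", engine = "BYONIC")
  expect_true(passes_filter(bok, byonic)$pass)
  bfloor <- series_at(GRID[1:6], c(150, 100, 150, 150, 150, 400),
                      peptide = "AAAAAAAA", engine = "BYONIC")
  expect_equal(passes_filter(bfloor, byonic)$reason, "ADJACENCY")
})

test_that("raising scores never flips an accepted series to rejected", {
  set.seed(21)
  params <- filter_params("MASCOT")
  for (i in 1:50) {
    n <- sample(4:21, 1)
    offs <- sort(sample(GRID, n))
    sc <- runif(n, 0, 60)
    s <- series_at(offs, sc, peptide = "AAAAAAAA")
    if (!passes_filter(s, params)$pass) next
    bumped <- s
    bumped$scores <- s$scores + runif(n, 0, 30)
    expect_true(passes_filter(bumped, params)$pass)
  }
})

test_that("PSM and series TSV round trips preserve the data", {
  psms <- rbind(psm_rows("PEPTIDEK", 2L, 0, 20, fragments = "y:3:120;b:2:45"),
                psm_rows("PEPTIDEK", 2L, 2, 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_tsv(psms, path)
  back <- read_psm_tsv(path)
  expect_equal(back$score, psms$score)
  expect_equal(back$fragments, psms$fragments)
  ser <- build_series(psms)
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_series_tsv(ser, spath)
  back2 <- read_series_tsv(spath)
  expect_length(back2, 1L)
  expect_equal(back2[[1]]$scores, ser[[1]]$scores)
})
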