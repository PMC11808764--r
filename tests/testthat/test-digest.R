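test_that("built-in enzyme specificities match the documented cleavage rules", {
  enz <- builtin_enzymes()
  expect_setequal(names(enz),
                  c("trypsin", "arg_c", "glu_c", "asp_n", "chymotrypsin"))
  expect_setequal(enz$trypsin$target_residues, c("K", "R"))
  expect_equal(enz$trypsin$cut_side, "C_TERMINAL")
  expect_setequal(enz$arg_c$target_residues, "R")
  expect_setequal(enz$glu_c$target_residues, c("E", "D"))
  expect_equal(enz$asp_n$cut_side, "N_TERMINAL")
  expect_setequal(enz$asp_n$target_residues, "D")
  expect_length(enz$chymotrypsin$target_residues, 8L)
  expect_setequal(enz$chymotrypsin$target_residues,
                  c("A", "D", "E", "L", "M", "F", "Y", "W"))
})

test_that("cleavage sites follow the cut-side convention", {
  enz <- builtin_enzymes()
  expect_equal(cleavage_sites("AKRGG", enz$trypsin), c(2L, 3L))
  expect_equal(cleavage_sites("GGDAA", enz$asp_n), 2L)
  expect_equal(cleavage_sites("GGGGG", enz$glu_c), integer(0))
  # terminal matches produce no cut
  expect_equal(cleavage_sites("KGGGG", enz$asp_n), integer(0))
  expect_equal(cleavage_sites("GGGGK", enz$trypsin), integer(0))
  expect_error(cleavage_sites("GGXGG", enz$trypsin), "non-standard")
})

test_that("digest enumerates missed-cleavage windows", {
  try_ <- builtin_enzymes()$trypsin
  d1 <- digest("AKGGRCC", try_, max_missed = 1)
  expect_setequal(d1$sequence, c("AK", "GGR", "CC", "AKGGR", "GGRCC"))
  expect_equal(sort(d1$missed_cleavages), c(0, 0, 0, 1, 1))
  d0 <- digest("AKGGRCC", try_, max_missed = 0)
  expect_setequal(d0$sequence, c("AK", "GGR", "CC"))
  # no cleavage site: the whole chain is the only product
  d <- digest("GGGGG", try_, max_missed = 2)
  expect_equal(d$sequence, "GGGGG")
  expect_equal(d$missed_cleavages, 0)
  # sequence slices are consistent with the reported intervals
  expect_equal(d1$sequence,
               substring("AKGGRCC", d1$start + 1, d1$end))
})

test_that("fully cleaved products concatenate to the parent", {
  set.seed(11)
  enz <- builtin_enzymes()
  for (i in 1:20) {
    s <- random_sequence(sample(5:100, 1))
    e <- enz[[sample(length(enz), 1)]]
    d0 <- digest(s, e, max_missed = 0)
    expect_equal(paste(d0$sequence[order(d0$start)], collapse = ""), s)
  }
})

test_that("digest agrees with the brute-force window oracle", {
  set.seed(12)
  enz <- builtin_enzymes()
  for (i in 1:40) {
    s <- random_sequence(sample(5:100, 1))
    for (e in enz) for (mm in 0:2) {
      d <- digest(s, e, mm)
      o <- oracle_digest(s, e, mm)
      expect_equal(d$start, o$start)
      expect_equal(d$end, o$end)
      expect_equal(d$missed_cleavages, o$missed)
    }
  }
})

test_that("each peptide contains exactly its tagged number of internal sites", {
  set.seed(13)
  enz <- builtin_enzymes()
  for (i in 1:10) {
    s <- random_sequence(sample(20:80, 1))
    e <- enz[[sample(length(enz), 1)]]
    d <- digest(s, e, 2)
    sites <- cleavage_sites(s, e)
    internal <- vapply(seq_len(nrow(d)), function(j)
      sum(sites > d$start[j] & sites < d$end[j]), integer(1))
    expect_equal(internal, d$missed_cleavages)
  }
})

test_that("monoisotopic mass and m/z follow the standard residue table", {
  expect_equal(peptide_mz("G", 1), 76.0393, tolerance = 1e-3)
  expect_equal(peptide_mz("GG", 2), 67.0340, tolerance = 1e-3)
  # z = 1 minus one proton recovers the neutral mass
  m <- mass_table()
  expect_equal(peptide_mz("PEPTIDE", 1) - m$proton_mass,
               peptide_mass("PEPTIDE"))
  # m/z strictly decreasing in charge
  mzs <- vapply(1:4, function(z) peptide_mz("ELVISLIVESK", z), numeric(1))
  expect_true(all(diff(mzs) < 0))
  expect_error(peptide_mass("GXG"), "unknown residue")
})

test_that("FASTA round trip and proteome digestion work", {
  seqs <- c(p1 = "MKAAARGGDDK", p2 = "GGEEKRLLM")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(seqs, path)
  back <- read_protein_fasta(path)
  expect_equal(back, seqs)
  pep <- digest_proteome(seqs, builtin_enzymes()$trypsin, 1)
  expect_true(all(pep$parent_id %in% names(seqs)))
  expect_true(all(pep$mass > 0))
  expect_equal(pep$sequence[pep$parent_id == "p1" & pep$missed_cleavages == 0 &
                              pep$start == 0], "MK")
})
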