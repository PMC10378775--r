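test_that("canonical metal-binding domain carries the expected residues", {
  wt <- ab16_peptide("WT")
  expect_equal(paste(wt$residues, collapse = ""), "DAEFRHDSGYEVHHQK")
  expect_equal(peptide_residue(wt, c(6, 11, 13, 14)), c("H", "E", "H", "H"))
  d7h <- ab16_peptide("D7H")
  expect_equal(peptide_residue(d7h, 7), "H")
  ## applying the substitution to an already-substituted sequence is idempotent
  again <- build_peptide(paste(d7h$residues, collapse = ""), "D7H")
  expect_equal(again$residues, d7h$residues)
})

test_that("invalid peptide inputs are rejected", {
  expect_error(build_peptide("", "WT"), "non-empty")
  expect_error(build_peptide("DAEB", "WT"), "unknown residue")
  expect_error(build_peptide("DAEFRHDSGYEVHHQK", "isoD7",
                             point_mutations = c("7" = "A")),
               "isomerized")
  expect_error(build_peptide("AAAAAAAA", "isoD7"), "requires Asp")
  expect_error(build_peptide("DAEFRH", "WT", point_mutations = c("9" = "A")),
               "within the sequence")
})

test_that("monoisotopic masses follow residue-table arithmetic", {
  gg <- build_peptide("GG", c_terminal_amide = FALSE)
  expect_equal(monoisotopic_mass(gg), 132.05349, tolerance = 1e-4 / 132)
  ## amidation replaces OH by NH2
  x_free <- build_peptide("DAEFRH", c_terminal_amide = FALSE)
  x_amid <- build_peptide("DAEFRH", c_terminal_amide = TRUE)
  expect_equal(monoisotopic_mass(x_amid) - monoisotopic_mass(x_free),
               -0.98402, tolerance = 1e-5)
  ## isoaspartate is isobaric
  expect_equal(monoisotopic_mass(ab16_peptide("isoD7")),
               monoisotopic_mass(ab16_peptide("WT")))
  ## phosphorylation adds the phospho group
  expect_equal(monoisotopic_mass(ab16_peptide("pS8")) -
                 monoisotopic_mass(ab16_peptide("WT")),
               79.96633, tolerance = 1e-5)
})

test_that("peptide masses agree with the elemental-composition oracle", {
  set.seed(11)
  for (i in 1:30) {
    seqc <- random_peptide_seq(sample(2:25, 1))
    p <- build_peptide(seqc, c_terminal_amide = FALSE)
    want <- oracle_fragment_neutral(strsplit(seqc, "")[[1]], "M")
    expect_equal(monoisotopic_mass(p), want, tolerance = 1e-4 / want)
  }
})

test_that("chelation-capable positions follow the capability rules", {
  d7h <- ab16_peptide("D7H")
  pos <- chelation_capable_positions(d7h)
  expect_true(all(c(1, 3, 6, 7, 11, 13, 14) %in% pos))
  expect_true(0 %in% pos)  # free N-terminal amine
  expect_false(any(c(2, 5, 9, 12) %in% pos))
  ## N-terminus switch
  expect_false(0 %in% chelation_capable_positions(d7h, include_nterm = FALSE))
  ## poly-Ala has no capable side chains
  ala <- build_peptide("AAAAAA")
  expect_length(chelation_capable_positions(ala, include_nterm = FALSE), 0)
  ## restricting the capable set to His
  expect_equal(chelation_capable_positions(ab16_peptide("WT"),
                                           capable_set = "H",
                                           include_nterm = FALSE),
               c(6L, 13L, 14L))
  ## Gly/Ala can never be declared capable
  expect_error(chelation_capable_positions(d7h, capable_set = c("G", "H")),
               "cannot")
  ## isoaspartate flagging does not change capability
  expect_equal(chelation_capable_positions(ab16_peptide("isoD7")),
               chelation_capable_positions(ab16_peptide("WT")))
})

test_that("absorbance converts to concentration by Beer-Lambert", {
  expect_equal(concentration_from_absorbance(1.45, 1.0), 1e-3)
  expect_equal(concentration_from_absorbance(0, 1.0), 0)
  expect_equal(concentration_from_absorbance(0.725, 0.5), 1e-3)
  expect_error(concentration_from_absorbance(1, 0), "positive")
  expect_error(concentration_from_absorbance(-1, 1), "non-negative")
})

test_that("FASTA round trip preserves sequences and config flags", {
  skip_if_not_installed("Biostrings")
  f <- tempfile(fileext = ".fasta")
  peps <- list(wt = ab16_peptide("WT"), d7h = ab16_peptide("D7H"))
  write_peptide_fasta(peps, f)
  back <- read_peptide_fasta(f, config = list(d7h = list(variant = "custom")))
  expect_equal(vapply(back, function(p) paste(p$residues, collapse = ""), ""),
               vapply(peps, function(p) paste(p$residues, collapse = ""), ""))
  expect_equal(back$d7h$variant, "custom")
})
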