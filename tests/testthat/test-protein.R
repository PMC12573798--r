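# Sequence-level protein properties and buffer calculations.

test_that("molecular weight handles free amino acids and peptide bonds", {
  expect_equal(molecular_weight(protein_sequence("gly", "G")), 75.07,
               tolerance = 1e-4)
  expect_equal(molecular_weight(protein_sequence("digly", "GG")), 132.12,
               tolerance = 1e-4)
  # additivity: concatenation loses one water per junction
  a <- protein_sequence("a", "ACDEFGHIKLMNPQRSTVWY")
  b <- protein_sequence("b", "WYWY")
  ab <- protein_sequence("ab", paste0("ACDEFGHIKLMNPQRSTVWY", "WYWY"))
  expect_equal(molecular_weight(ab),
               molecular_weight(a) + molecular_weight(b) - 18.01524,
               tolerance = 1e-9)
})

test_that("apomyoglobin mass matches an independent residue summation", {
  skip_if_not_installed("seqinr")
  seq <- apomb_sequence()
  expect_equal(nchar(seq$residues), 153)
  # independent oracle: seqinr's protein mass calculator
  oracle <- seqinr::pmw(strsplit(seq$residues, "")[[1]])
  expect_equal(molecular_weight(seq), oracle, tolerance = 1e-4)
  expect_equal(molecular_weight(seq), 16951, tolerance = 1e-4)
})

test_that("extinction coefficients follow the Pace convention", {
  expect_equal(extinction_280(protein_sequence("x", "GAVL"))$epsilon, 0)
  expect_equal(extinction_280(protein_sequence("w", "W"))$epsilon, 5500)
  seq <- apomb_sequence()
  ext <- extinction_280(seq)
  expect_equal(ext$epsilon, 2 * 5500 + 2 * 1490)
  expect_equal(round(ext$E_1pct, 2), 8.25)
  # additivity of the chromophore count
  ww <- extinction_280(protein_sequence("ww", "WW"))$epsilon
  expect_equal(ww, 2 * 5500)
  expect_error(extinction_280(protein_sequence("c", "CC"), n_cystine = 2),
               "n_cystine")
})

test_that("mass-molar conversion reproduces the working concentrations", {
  expect_identical(mass_to_molar(0, 17000), 0)
  mw <- molecular_weight(apomb_sequence())
  expect_equal(round(mass_to_molar(7, mw), 1), 0.4)
  expect_equal(round(mass_to_molar(0.9, mw), 2), 0.05)
})

test_that("net charge has the full-protonation limit and zwitterion symmetry", {
  seq <- apomb_sequence()
  counts <- table(strsplit(seq$residues, "")[[1]])
  # pH 0: all basic groups protonated, acids neutral
  expect_equal(net_charge(seq, 0),
               sum(counts[c("K", "R", "H")]) + 1, tolerance = 0.05)
  # glycine at the midpoint of its two pKas is neutral by symmetry
  pka <- default_pka_set()
  mid <- (pka[["N_term"]] + pka[["C_term"]]) / 2
  expect_equal(net_charge(protein_sequence("g", "G"), mid), 0,
               tolerance = 1e-12)
})

test_that("net charge decreases monotonically with pH", {
  seq <- apomb_sequence()
  q <- net_charge(seq, seq(0, 14, by = 0.25))
  expect_true(all(diff(q) < 0))
  q3 <- net_charge(seq, c(2, 4, 6))
  expect_true(q3[1] > q3[2] && q3[2] > q3[3])
})

test_that("the isoelectric point is the root of the titration curve", {
  seq <- apomb_sequence()
  pI <- isoelectric_point(seq)
  expect_lt(abs(net_charge(seq, pI)), 1e-6)
  # the paper's protein: literature pI 7.2; value depends on the pKa set
  expect_gt(pI, 6.8)
  expect_lt(pI, 7.8)
  # polyglycine: midpoint of the terminal pKas
  pka <- default_pka_set()
  expect_equal(isoelectric_point(protein_sequence("g5", "GGGGG")),
               (pka[["N_term"]] + pka[["C_term"]]) / 2, tolerance = 1e-4)
  # root property over random sequences
  set.seed(41)
  aas <- names(tdfrs:::.RESIDUE_MASS)
  for (k in 1:20) {
    s <- protein_sequence(paste0("r", k),
                          paste(sample(aas, 30, replace = TRUE),
                                collapse = ""))
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 1e-6)
  }
})

test_that("speciation fractions are exact and sum to one", {
  sp <- speciation(pH = 7.21, pKa = 7.21)
  expect_equal(unname(sp), c(0.5, 0.5))
  # phosphate at pH 6: dominated by the dihydrogen form
  sp6 <- speciation(pH = 6, pKa = 7.21)
  expect_equal(unname(sp6[1]), 0.9419, tolerance = 1e-4)
  expect_equal(round(unname(sp6[1]), 1), 0.9)
  # acetate at pH 4: mostly acetic acid
  sp4 <- speciation(pH = 4, pKa = 4.76)
  expect_equal(unname(sp4[1]), 0.8519, tolerance = 1e-4)
  expect_equal(sum(sp4), 1)
  expect_equal(sum(speciation(2.3, 9.1)), 1)
})

test_that("hydration indices are mole-fraction weighted means", {
  one <- buffer_spec("x", list(buffer_component("only", 1, 7)))
  expect_equal(hydration_index(one), 7)
  expect_equal(hydration_index(naac_buffer()), 1.8)
  # phosphate composition: the weighted mean of the printed inputs is 4.7
  expect_equal(hydration_index(nap_buffer()), 4.7)
  expect_error(buffer_spec("bad", list(buffer_component("a", 0.5, 1))),
               "sum to 1")
})

test_that("sequence and pKa inputs are validated", {
  expect_error(protein_sequence("bad", "ACDEFGB"), "non-standard")
  expect_error(protein_sequence("empty", ""), "empty")
  seq <- protein_sequence("s", "ACD")
  expect_error(net_charge(seq, 7, pka = c(D = 3.65)), "missing entries")
  bad_pka <- default_pka_set(); bad_pka[["K"]] <- 15
  expect_error(net_charge(seq, 7, pka = bad_pka), "in \\(0, 14\\)")
})

test_that("FASTA parsing preserves sequence identity", {
  seqs <- read_protein_fasta(system.file("extdata",
                                         "apomyoglobin_P68082.fasta",
                                         package = "tdfrs"))
  expect_length(seqs, 1)
  expect_match(seqs[[1]]$residues, "^GLSDGEWQ")
  expect_match(seqs[[1]]$residues, "GFQG$")
})
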