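test_that("tokenizer handles all three dialects and the mod grammar", {
  expect_identical(tokenize("PEPS(ph)IDE"),
                   c("<START>", "P", "E", "P", "S-ph", "I", "D", "E", "<END>"))
  expect_identical(tokenize("_(ac)AAK_", "maxquant"),
                   c("<START-ac>", "A", "A", "K", "<END>"))
  expect_identical(tokenize("_(ac)M(ox)AAK_", "maxquant"),
                   c("<START-ac>", "M-ox", "A", "A", "K", "<END>"))
  # long-form MaxQuant modification names map to the same tokens
  expect_identical(tokenize("_(Acetyl (Protein N-term))M(Oxidation (M))AAK_",
                            "maxquant"),
                   c("<START-ac>", "M-ox", "A", "A", "K", "<END>"))
  # PEAKS mass deltas are matched to known modifications
  expect_identical(tokenize("AAS(+79.97)K", "peaks"),
                   c("<START>", "A", "A", "S-ph", "K", "<END>"))
  expect_identical(tokenize("M(+42.01)C(+57.02)K", "peaks"),
                   c("<START-ac>", "M", "C-cam", "K", "<END>"))
})

test_that("tokenizer rejects unknown residues and modifications, naming them", {
  expect_error(tokenize("AXZ"), "X", class = "pepccs_tokenization_error")
  expect_error(tokenize("PEPA(ph)K"), class = "pepccs_tokenization_error")
  expect_error(tokenize("_AM(Glyco)K_", "maxquant"), "Glyco",
               class = "pepccs_tokenization_error")
  expect_error(tokenize("AS(+123.45)K", "peaks"),
               class = "pepccs_tokenization_error")
  expect_error(tokenize(""), class = "pepccs_tokenization_error")
})

test_that("detokenize inverts tokenize on sequences covering every mod token", {
  set.seed(402)
  mods <- c("S(ph)", "T(ph)", "Y(ph)", "C(cam)", "C(cys)", "M(ox)")
  fixture <- vapply(1:50, function(i) {
    body <- paste(sample(pepccs:::AMINO_ACIDS, 8, replace = TRUE),
                  collapse = "")
    mod <- mods[1 + (i %% length(mods))]
    prefix <- if (i %% 5 == 0) "(ac)" else ""
    paste0(prefix, substr(body, 1, 4), mod, substr(body, 5, 8))
  }, character(1))
  for (s in fixture) expect_identical(detokenize(tokenize(s)), s)
})

test_that("monoisotopic masses match an independent calculator", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("PEPTIDE"), 799.35996, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("ACDEFGHIKL"), 1131.53828, tolerance = 1e-7)
  # modification deltas
  expect_equal(monoisotopic_mass("PES(ph)K") - monoisotopic_mass("PESK"),
               79.96633)
  expect_equal(monoisotopic_mass("(ac)PESK") - monoisotopic_mass("PESK"),
               42.01057)
  # additivity under concatenation (a peptide bond releases one water)
  expect_equal(monoisotopic_mass("PEPT") + monoisotopic_mass("IDE") -
                 pepccs:::WATER_MONO,
               monoisotopic_mass("PEPTIDE"))
})

test_that("m/z follows the proton-counting formula and decreases with charge", {
  expect_equal(peptide_mz(1000, 1), 1001.007276)
  expect_equal(peptide_mz(1000, 2), 501.007276)
  mzs <- peptide_mz(1500, 1:6)
  expect_true(all(diff(mzs) < 0))
  expect_error(peptide_mz(1000, 0), class = "pepccs_domain_error")
})

test_that("scalar descriptors are length-normalized sums over residues", {
  tab <- descriptor_table()
  expect_length(tab, 9L)
  # homopolymer: every descriptor equals the per-residue value
  kk <- scalar_descriptors("KKKK")
  for (nm in names(tab)) expect_equal(kk[[nm]], tab[[nm]][["K"]])
  # two-residue average
  ak <- scalar_descriptors("AK")
  expect_equal(ak[["hydropathy"]],
               (tab$hydropathy[["A"]] + tab$hydropathy[["K"]]) / 2)
  # hand-summed length-10 fixture
  seq10 <- "ACDEFGHIKL"
  expected <- vapply(tab, function(scale)
    sum(scale[strsplit(seq10, "")[[1]]]) / 10, numeric(1))
  expect_equal(scalar_descriptors(seq10), expected)
  # composition-only: invariant under residue permutation
  expect_equal(scalar_descriptors("GIKLMAAR"), scalar_descriptors("RAMLKIGA"))
  # modified residues fall back to the base amino acid
  expect_equal(scalar_descriptors("PES(ph)K"), scalar_descriptors("PESK"))
})
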