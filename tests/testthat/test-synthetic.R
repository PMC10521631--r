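test_that("generator is seed-deterministic and honors the square-root law", {
  truth0 <- synthetic_truth(effects = NULL, noise_sd = 0, seed = 81L)
  g1 <- generate_ions(truth0, 150L)
  g2 <- generate_ions(truth0, 150L)
  expect_identical(g1, g2)
  # sigma = 0 and no token effects: every ion lies exactly on its charge curve
  ds <- g1$dataset
  expect_equal(ds$ccs,
               truth0$w[ds$charge] * sqrt(ds$mz) + truth0$b[ds$charge])
  # occurrences support the aggregation rule (secondary mode can be smaller)
  expect_true(all(ds$occurrence >= 2L))
})

test_that("generated CCS decomposes into baseline + effects + centered noise", {
  truth <- synthetic_truth(seed = 82L)
  gen <- generate_ions(truth, 10000L)
  resid <- gen$truth$ccs - gen$truth$baseline - gen$truth$residual
  expect_equal(resid, gen$truth$noise)
  # CLT check on the noise mean
  expect_lt(abs(mean(resid)), 3 * truth$noise_sd / sqrt(10000))
  # m/z is consistent with the sequence mass and charge
  i <- 1:50
  expect_equal(gen$dataset$mz[i],
               unname(peptide_mz(vapply(gen$dataset$sequence[i],
                                        monoisotopic_mass, numeric(1)),
                                 gen$dataset$charge[i])))
})

test_that("injected bimodality is recovered by deduplication", {
  truth <- synthetic_truth(seed = 83L)
  gen <- generate_ions(truth, 2000L)
  inj <- inject_multimodality(gen$dataset, 0.05, 30, seed = 83L)
  # secondary occurrence strictly below the main mode by construction
  n <- nrow(gen$dataset)
  extra <- inj$dataset[(n + 1):nrow(inj$dataset), ]
  main_occ <- gen$dataset$occurrence[match(paste(extra$sequence, extra$charge),
                                           paste(gen$dataset$sequence,
                                                 gen$dataset$charge))]
  expect_true(all(extra$occurrence < main_occ))

  dd <- deduplicate(inj$dataset)
  key_dd <- paste(dd$sequence, dd$charge)
  key_inj <- paste(inj$injected$sequence, inj$injected$charge)
  flagged <- key_dd[dd$modality == "multimodal"]
  recovery <- mean(key_inj %in% flagged)
  false_pos <- length(setdiff(flagged, key_inj)) /
    max(1, length(key_dd) - length(key_inj))
  expect_gte(recovery, 0.9)
  expect_lte(false_pos, 0.01)

  # fraction 0 leaves the dataset unchanged
  none <- inject_multimodality(gen$dataset, 0, 30, seed = 83L)
  expect_identical(as.data.frame(none$dataset), as.data.frame(gen$dataset))
  expect_equal(nrow(none$injected), 0L)
})

test_that("emitted search tables round-trip through the readers", {
  gen <- generate_ions(synthetic_truth(seed = 84L), 100L)
  for (dialect in c("maxquant", "peaks")) {
    path <- withr::local_tempfile(fileext = ".txt")
    emit_search_table(gen$dataset, path, dialect)
    back <- read_search_results(path, dialect)
    expect_equal(attr(back, "read_report")$n_skipped, 0L)
    expect_identical(back$sequence, gen$dataset$sequence)
    expect_identical(back$charge, gen$dataset$charge)
    expect_equal(back$ccs, gen$dataset$ccs, tolerance = 1e-6)
  }
  # phospho is rendered with the short modification code in maxquant dialect
  one <- ion_dataset(data.frame(sequence = "PES(ph)K", charge = 2L,
                                mz = 290.1, ccs = 350))
  p <- withr::local_tempfile(fileext = ".txt")
  emit_search_table(one, p, "maxquant")
  expect_match(readLines(p)[2], "_PES(ph)K_", fixed = TRUE)
  # empty dataset: header-only file
  p2 <- withr::local_tempfile(fileext = ".txt")
  emit_search_table(ion_dataset(data.frame()), p2, "peaks")
  expect_length(readLines(p2), 1L)
})

test_that("full pipeline recovers the generating square-root parameters", {
  truth <- synthetic_truth(effects = NULL, noise_sd = 5, seed = 85L)
  gen <- generate_ions(truth, 5000L)
  path <- withr::local_tempfile(fileext = ".txt")
  emit_search_table(gen$dataset, path, "maxquant")
  ds <- read_search_results(path, "maxquant")
  fit <- fit_sqrt(deduplicate(ds))
  for (c_ in 1:4) {
    p <- fit$params[[as.character(c_)]]
    expect_lt(abs(p$w - truth$w[c_]) / truth$w[c_], 0.02)
    expect_lt(abs(p$b - truth$b[c_]), 5)
  }
})
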