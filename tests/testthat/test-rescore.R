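test_that("ccs_features computes the five rescoring features", {
  f <- ccs_features(600, 600)
  expect_equal(unlist(f), c(ccs_observed = 600, ccs_predicted = 600,
                            ccs_error = 0, ccs_abs_error = 0,
                            ccs_perc_error = 0))
  f2 <- ccs_features(600, 570)
  expect_equal(f2$ccs_error, 30)
  expect_equal(f2$ccs_abs_error, 30)
  expect_equal(f2$ccs_perc_error, 5.0)
  # sign convention: observed below predicted gives a negative signed error
  f3 <- ccs_features(570, 600)
  expect_equal(f3$ccs_error, -30)
  expect_equal(f3$ccs_abs_error, 30)
  expect_equal(f3$ccs_perc_error, 100 * (-30) / 570, tolerance = 1e-12)
  expect_equal(round(f3$ccs_perc_error, 3), -5.263)
  expect_error(ccs_features(0, 500), class = "pepccs_domain_error")
})

test_that("augment_pin inserts hand-computed feature columns before Peptide", {
  fix <- make_pin_fixture(withr::local_tempfile(fileext = ".pin"))
  pin <- read_pin(fix$path)
  res <- augment_pin(pin, fix$ccs_table)

  # one charge-5 row removed, nothing unmatched
  expect_equal(res$report$charge_filtered, 1L)
  expect_equal(res$report$unmatched, 0L)
  expect_equal(res$report$rows_out, 9L)
  expect_equal(nrow(res$pin$rows), 9L)

  # exactly five new columns, placed right before the peptide column
  expect_length(res$pin$header, length(pin$header) + 5L)
  pep_col <- which(res$pin$header == "Peptide")
  expect_identical(res$pin$header[(pep_col - 5):(pep_col - 1)],
                   c("ccs_observed", "ccs_predicted", "ccs_error",
                     "ccs_abs_error", "ccs_perc_error"))

  # feature values equal a spreadsheet-style recomputation
  kept <- fix$charges <= 4
  obs <- fix$ccs_table$ccs_observed[kept]
  pred <- fix$ccs_table$ccs_predicted[kept]
  expect_equal(as.numeric(res$pin$rows[, pep_col - 5]), obs)
  expect_equal(as.numeric(res$pin$rows[, pep_col - 4]), pred)
  expect_equal(as.numeric(res$pin$rows[, pep_col - 3]), obs - pred)
  expect_equal(as.numeric(res$pin$rows[, pep_col - 2]), abs(obs - pred))
  expect_equal(as.numeric(res$pin$rows[, pep_col - 1]),
               100 * (obs - pred) / obs, tolerance = 1e-6)

  # untouched columns are byte-stable
  orig_kept <- pin$rows[fix$charges <= 4, , drop = FALSE]
  expect_identical(res$pin$rows[, 1:(pep_col - 6)],
                   orig_kept[, 1:(pep_col - 6)])
  expect_identical(res$pin$rows[, (pep_col):(pep_col + 1)],
                   orig_kept[, (ncol(orig_kept) - 1):ncol(orig_kept)])

  # the result is still a valid PIN file
  out <- withr::local_tempfile(fileext = ".pin")
  write_pin(res$pin, out)
  back <- read_pin(out)
  expect_identical(back$rows, res$pin$rows)
})

test_that("augment_pin refuses double augmentation and counts unmatched rows", {
  fix <- make_pin_fixture(withr::local_tempfile(fileext = ".pin"))
  pin <- read_pin(fix$path)
  res <- augment_pin(pin, fix$ccs_table)
  expect_error(augment_pin(res$pin, fix$ccs_table), "refusing",
               class = "pepccs_format_error")

  # removing two peptides from the join table drops and counts those rows
  short <- fix$ccs_table[-c(1, 3), ]
  res2 <- augment_pin(pin, short)
  expect_equal(res2$report$unmatched, 2L)
  expect_equal(res2$report$rows_out, 7L)
})
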