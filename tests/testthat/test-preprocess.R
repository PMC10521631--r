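test_that("Mason-Schamp conversion is linear, invertible and monotone", {
  # linearity in 1/K0 at fixed charge and mass
  expect_equal(k0_to_ccs(2.2, 2, 1500), 2 * k0_to_ccs(1.1, 2, 1500))
  # inverse round-trip to 1e-9 relative
  x <- ccs_to_k0(400, 2, 1500)
  expect_equal(k0_to_ccs(x, 2, 1500), 400, tolerance = 1e-9)
  # frozen regression fixture computed with an independent constant-by-
  # constant evaluation of the Mason-Schamp formula (N2, 305 K)
  expect_equal(k0_to_ccs(1.10, 2, 1500), 444.645571, tolerance = 1e-6)
  # monotone in 1/K0 and in charge
  grid <- seq(0.6, 1.8, by = 0.1)
  expect_true(all(diff(k0_to_ccs(grid, 2, 1200)) > 0))
  expect_true(all(diff(k0_to_ccs(1.0, 1:4, 1200)) > 0))
  expect_error(k0_to_ccs(-1, 2, 1500), class = "pepccs_domain_error")
  expect_error(ccs_to_k0(400, 0, 1500), class = "pepccs_domain_error")
})

test_that("aggregate_group reproduces the worked two-sigma examples", {
  g <- aggregate_group(c(500, 501, 530), c(4, 4, 2))
  expect_equal(g$ccs, 500.5)
  expect_equal(g$occurrence, 8L)
  expect_identical(g$modality, "multimodal")
  expect_equal(g$n_modes, 2L)
  expect_equal(g$dropped_occurrence, 2L)

  s <- aggregate_group(400, 7)
  expect_equal(s$ccs, 400)
  expect_equal(s$occurrence, 7L)
  expect_identical(s$modality, "unimodal")
  expect_equal(s$n_modes, 1L)

  near <- aggregate_group(c(600, 600.5), c(1, 1))
  expect_equal(near$ccs, 600.25)
  expect_equal(near$occurrence, 2L)
  expect_identical(near$modality, "unimodal")

  expect_error(aggregate_group(numeric(0)), class = "pepccs_domain_error")
})

test_that("aggregate_group agrees with the brute-force expansion oracle", {
  set.seed(300)
  for (i in 1:300) {
    grp <- random_group()
    got <- aggregate_group(grp$ccs, grp$occ)
    want <- oracle_aggregate(grp$ccs, grp$occ)
    expect_equal(got$ccs, want$ccs)
    expect_equal(got$occurrence, want$occurrence)
    expect_equal(got$n_modes, want$n_modes)
    expect_identical(got$modality, want$modality)
  }
})

test_that("deduplicate conserves keys and occurrence mass", {
  gen <- generate_ions(synthetic_truth(seed = 31L), 400L)
  inj <- inject_multimodality(gen$dataset, 0.05, 30, seed = 31L)
  dd <- deduplicate(inj$dataset)
  rep_ <- attr(dd, "dedup_report")
  # key multiset preserved
  expect_setequal(paste(dd$sequence, dd$charge),
                  unique(paste(inj$dataset$sequence, inj$dataset$charge)))
  # occurrence conservation: fused + dropped = input
  expect_equal(rep_$fused_occurrence + rep_$dropped_occurrence,
               sum(inj$dataset$occurrence))
  expect_identical(unique(dd$modality[dd$n_modes >= 2]), "multimodal")

  # exact duplicates fuse to a single record
  two <- ion_dataset(data.frame(sequence = c("AAK", "AAK"), charge = 2L,
                                mz = 109.1, ccs = 300, occurrence = 1L))
  d2 <- deduplicate(two)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$occurrence, 2L)
  expect_equal(d2$ccs, 300)
  expect_identical(d2$modality, "unimodal")

  # without repeated keys deduplication is the identity on (key, ccs)
  uni <- ion_dataset(data.frame(sequence = c("AAK", "ACK"), charge = 2L,
                                mz = c(109.1, 125.4), ccs = c(300, 310)))
  du <- deduplicate(uni)
  expect_equal(nrow(du), 2L)
  expect_equal(sort(du$ccs), c(300, 310))
})

test_that("alignment recovers constructed offsets and is idempotent", {
  gen <- generate_ions(synthetic_truth(seed = 41L), 200L)
  ref <- gen$dataset
  target <- ref
  target$ccs <- target$ccs - 5
  attr(target, "meta")$source_id <- "shifted"

  res <- align_datasets(target, ref)
  expect_equal(res$shift$shift, 5.0)
  expect_equal(res$shift$n_matched,
               length(unique(paste(ref$sequence, ref$charge))))
  expect_equal(res$dataset$ccs, ref$ccs)
  # matched-pair mean difference after shifting is zero
  expect_lt(abs(mean(ref$ccs - res$dataset$ccs)), 1e-9)
  expect_equal(attr(res$dataset, "meta")$shift_applied, 5.0)

  # identity alignment and idempotence
  expect_equal(align_datasets(ref, ref)$shift$shift, 0.0)
  again <- align_datasets(res$dataset, ref)
  expect_lt(abs(again$shift$shift), 1e-9)

  disjoint <- ion_dataset(data.frame(sequence = "WWWW", charge = 2L,
                                     mz = 380, ccs = 500))
  expect_error(align_datasets(disjoint, ref),
               class = "pepccs_alignment_error")
})
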