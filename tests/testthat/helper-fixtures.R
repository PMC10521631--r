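# Shared fixtures: an independent brute-force aggregation oracle, a PIN
# fixture builder, and a lazily trained reduced model reused by the tests
# that need a trained network.

# Brute-force oracle for the two-sigma aggregation rule: merges identical
# CCS instances, expands every instance into `occurrence` copies, and
# applies the rule literally on the expanded values. Deliberately written
# in a different style from the package implementation.
oracle_aggregate <- function(ccs, occ) {
  merged <- tapply(occ, ccs, sum)
  vals <- as.numeric(names(merged))
  counts <- as.numeric(merged)
  expanded <- rep(vals, counts)
  sigma <- sqrt(mean((expanded - mean(expanded))^2))
  top <- max(counts)
  main_val <- min(vals[counts == top])
  in_main <- abs(expanded - main_val) <= 2 * sigma
  inst_in <- abs(vals - main_val) <= 2 * sigma
  list(ccs = mean(expanded[in_main]),
       occurrence = sum(in_main),
       n_modes = 1L + sum(!inst_in),
       modality = if (any(!inst_in)) "multimodal" else "unimodal",
       dropped_occurrence = sum(!in_main))
}

random_group <- function() {
  k <- sample(1:6, 1)
  list(ccs = round(runif(k, 350, 700), 1),
       occ = sample(1:8, k, replace = TRUE))
}

# A 10-row percolator PIN fixture: 9 matched rows over charges 1-4 plus one
# charge-5 row. Returns the path plus the CCS join table.
make_pin_fixture <- function(path) {
  header <- c("SpecId", "Label", "ScanNr", "lnrSp", "Charge1", "Charge2",
              "Charge3", "Charge4", "Charge5", "Peptide", "Proteins")
  peptides <- sprintf("K.PEP%02dTIDE.A", 1:10)
  charges <- c(1, 2, 2, 3, 3, 4, 2, 1, 4, 5)
  rows <- t(vapply(1:10, function(i) {
    onehot <- as.character(as.integer(charges[i] == 1:5))
    c(sprintf("psm_%02d", i), ifelse(i %% 2 == 0, "-1", "1"),
      as.character(100 + i), sprintf("%.4f", i / 7),
      onehot, peptides[i], sprintf("PROT_%d", i))
  }, character(11)))
  writeLines(c(paste(header, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")), path)
  obs <- 400 + 10 * (1:10)
  pred <- obs + c(0, -30, 15, -7.5, 3, 0.4, -12, 22, -5, 60)
  list(path = path,
       peptides = peptides, charges = charges,
       ccs_table = data.frame(peptide = peptides, charge = charges,
                              ccs_observed = obs, ccs_predicted = pred,
                              stringsAsFactors = FALSE))
}

# Reduced-architecture model trained once per test run on synthetic data
# with token-effect residuals (the shared study conditions), cached so the
# training and phospho-direction checks reuse one 5,000-ion training run.
fixture_cache <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(fixture_cache$trained)) return(fixture_cache$trained)
  truth <- synthetic_truth(seed = 11L)
  gen <- generate_ions(truth, 6250L)
  train_idx <- 1:5000
  val_idx <- 5001:6250
  fit <- fit_sqrt(gen$dataset[train_idx, ])
  model <- build_ccs_model(
    token_vocab(), fit,
    model_config(embedding_dim = 32L, gru_units = c(32L, 32L)),
    seed = 5L)
  res <- train_ccs_model(model, gen$dataset[train_idx, ],
                         gen$dataset[val_idx, ],
                         train_config(max_epochs = 20L, seed = 5L))
  fixture_cache$trained <- list(truth = truth, gen = gen, fit = fit,
                                untrained = model, res = res)
  fixture_cache$trained
}

# Recompute the learning-rate sequence implied by the plateau schedule from
# a validation-MAE history; used to check the recorded schedule.
expected_lr_schedule <- function(val_mae, lr0, patience = 3L, factor = 0.1) {
  lr <- lr0
  best <- Inf
  wait <- 0L
  phase <- 0L
  out <- numeric(0)
  stopped_at <- length(val_mae)
  for (i in seq_along(val_mae)) {
    out <- c(out, lr)
    if (val_mae[i] < best - 1e-12) {
      best <- val_mae[i]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        if (phase == 0L) {
          lr <- lr * factor
          phase <- 1L
          wait <- 0L
        } else {
          stopped_at <- i
          break
        }
      }
    }
  }
  list(lr = out, stopped_at = stopped_at)
}
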