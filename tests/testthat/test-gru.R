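tiny_fit <- function() {
  structure(list(params = list("1" = list(w = 15, b = 120, n = 10, mae = 1),
                               "2" = list(w = 18, b = 60, n = 10, mae = 1),
                               "3" = list(w = 21, b = 40, n = 10, mae = 1),
                               "4" = list(w = 24, b = 30, n = 10, mae = 1)),
                 max_charge = 4L),
            class = "sqrt_fit")
}

tiny_model <- function(seed = 7L) {
  build_ccs_model(token_vocab(), tiny_fit(),
                  model_config(embedding_dim = 8L, gru_units = c(6L, 6L),
                               dense_units = c(10L, 5L), dropout = 0.2),
                  seed = seed)
}

# Closed-form parameter accounting: embedding V*E; each GRU direction
# 3*(in*u + u^2 + 2u); dense layers in*out + out.
hand_count <- function(V, E, u1, u2, h1, h2, C) {
  gru <- function(inp, u) 3 * (inp * u + u^2 + 2 * u)
  V * E + 2 * gru(E, u1) + 2 * gru(2 * u1, u2) +
    (2 * u2 + C) * h1 + h1 + h1 * h2 + h2 + h2 + 1
}

test_that("default architecture lands at the published ~550k weight scale", {
  model <- build_ccs_model(token_vocab(), tiny_fit(), model_config())
  expect_lt(abs(model$param_count - 550000) / 550000, 0.05)
  V <- length(token_vocab()$tokens)
  expect_identical(model$param_count,
                   as.integer(hand_count(V, 128, 128, 128, 128, 64, 4)))
})

test_that("parameter count matches the per-layer hand count for odd shapes", {
  cfg <- model_config(embedding_dim = 12L, gru_units = c(9L, 7L),
                      dense_units = c(11L, 5L), max_charge = 3L)
  model <- build_ccs_model(token_vocab(), tiny_fit(), cfg)
  V <- length(token_vocab()$tokens)
  expect_identical(model$param_count,
                   as.integer(hand_count(V, 12, 9, 7, 11, 5, 3)))
})

test_that("untrained model predicts exactly the baseline (zero residual head)", {
  model <- tiny_model()
  gen <- generate_ions(synthetic_truth(seed = 61L), 40L)
  pred <- predict(model, gen$dataset)
  expect_equal(pred$residual, rep(0, 40))
  expect_equal(pred$ccs_predicted,
               predict_init(gen$dataset$mz, gen$dataset$charge, tiny_fit()))
})

test_that("additive decomposition and batch invariance hold exactly", {
  model <- tiny_model()
  # make the head non-trivial without training
  model$weights$out_W[] <- seq(-0.2, 0.2, length.out = length(model$weights$out_W))
  model$weights$out_b <- 0.3
  gen <- generate_ions(synthetic_truth(seed = 62L), 30L)
  pred <- predict(model, gen$dataset)
  expect_equal(pred$ccs_predicted - pred$residual, pred$ccs_baseline)
  expect_equal(pred$ccs_baseline,
               predict_init(gen$dataset$mz, gen$dataset$charge, model$baseline))
  # batch prediction equals per-ion prediction elementwise
  single <- vapply(seq_len(nrow(gen$dataset)), function(i)
    predict(model, gen$dataset[i, ])$ccs_predicted, numeric(1))
  expect_equal(pred$ccs_predicted, single)
})

test_that("training is deterministic, freezes the baseline and validates input", {
  gen <- generate_ions(synthetic_truth(seed = 63L), 250L)
  tr <- gen$dataset[1:200, ]
  va <- gen$dataset[201:250, ]
  model <- tiny_model()
  cfg <- train_config(max_epochs = 3L, batch_size = 32L, seed = 9L)
  run1 <- train_ccs_model(model, tr, va, cfg)
  run2 <- train_ccs_model(model, tr, va, cfg)
  expect_identical(run1$history, run2$history)
  expect_identical(run1$model$weights, run2$model$weights)
  # frozen baseline: bit-identical before and after training
  expect_identical(run1$model$baseline, model$baseline)
  # history bookkeeping
  expect_identical(names(run1$history),
                   c("epoch", "train_mae", "val_mae", "lr"))
  expect_equal(run1$history$lr[1], 1e-3)

  expect_error(train_ccs_model(model, tr[0, ], va, cfg),
               class = "pepccs_training_error")
  bad <- tr
  bad$charge[1] <- 5L
  expect_error(train_ccs_model(model, bad, va, cfg),
               class = "pepccs_training_error")
})

test_that("prediction rejects charges outside the modeled range, listing rows", {
  model <- tiny_model()
  df <- data.frame(sequence = c("AAK", "ACK"), charge = c(2L, 5L),
                   mz = c(109.6, 125.1))
  expect_error(predict(model, df), "2", class = "pepccs_prediction_error")
})

test_that("embeddings have one vector per token with the configured width", {
  model <- tiny_model()
  emb <- extract_embeddings(model)
  expect_identical(rownames(emb), token_vocab()$tokens)
  expect_identical(dim(emb), c(length(token_vocab()$tokens), 8L))
})

test_that("a model survives the JSON save/load round trip", {
  model <- tiny_model()
  model$weights$out_W[] <- rnorm(length(model$weights$out_W))
  dir <- withr::local_tempdir()
  save_ccs_model(model, dir)
  back <- load_ccs_model(dir)
  expect_equal(back$weights, model$weights)
  expect_equal(back$param_count, model$param_count)
  gen <- generate_ions(synthetic_truth(seed = 64L), 20L)
  expect_equal(predict(back, gen$dataset), predict(model, gen$dataset))
})
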