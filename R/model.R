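# The residual CCS predictor: token embedding -> two bidirectional GRU
# layers -> dense head fed with the charge one-hot -> scalar residual,
# added to the frozen per-charge square-root baseline:
#   CCS_final(mz, c, s) = CCS_init(mz, c) + M(s, c, theta).

#' Architecture configuration for the GRU residual model
#'
#' Defaults reproduce the published architecture scale: 128-dimensional
#' token embeddings, two bidirectional GRU layers with 128 units per
#' direction, dense layers of 128 and 64 units with dropout 0.2 between
#' them, charges modeled up to 4. With the packaged 30-token vocabulary the
#' model has 540,161 trainable weights.
#'
#' @param embedding_dim Token embedding dimension.
#' @param gru_units Units per direction for the two bidirectional layers.
#' @param dense_units Widths of the two dense layers.
#' @param dropout Dropout rate between the two dense layers.
#' @param max_charge Highest modeled charge state.
#' @return Object of class \code{model_config}.
#' @export
model_config <- function(embedding_dim = 128L, gru_units = c(128L, 128L),
                         dense_units = c(128L, 64L), dropout = 0.2,
                         max_charge = 4L) {
  if (any(c(embedding_dim, gru_units, dense_units, max_charge) < 1L))
    stop_config("all dimensions must be >= 1")
  if (dropout < 0 || dropout >= 1)
    stop_config("dropout must be in [0, 1)")
  if (length(gru_units) != 2L || length(dense_units) != 2L)
    stop_config("gru_units and dense_units must each have length 2")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 gru_units = as.integer(gru_units),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 max_charge = as.integer(max_charge)),
            class = "model_config")
}

cpp_config <- function(model) {
  cfg <- model$config
  list(vocab_size = length(model$vocab$tokens),
       embedding_dim = cfg$embedding_dim,
       units1 = cfg$gru_units[1L], units2 = cfg$gru_units[2L],
       dense1 = cfg$dense_units[1L], dense2 = cfg$dense_units[2L],
       max_charge = cfg$max_charge, dropout = cfg$dropout)
}

glorot <- function(nr, nc, fan_in = nc, fan_out = nr) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_gru <- function(units, input_dim, prefix) {
  w <- list(
    glorot(3L * units, input_dim, fan_in = input_dim, fan_out = units),
    glorot(3L * units, units, fan_in = units, fan_out = units),
    numeric(3L * units),
    numeric(3L * units))
  names(w) <- paste0(prefix, "_", c("Wx", "Wh", "bx", "bh"))
  w
}

init_weights <- function(vocab_size, cfg) {
  u1 <- cfg$gru_units[1L]; u2 <- cfg$gru_units[2L]
  h1 <- cfg$dense_units[1L]; h2 <- cfg$dense_units[2L]
  E <- cfg$embedding_dim
  c(list(emb = matrix(runif(vocab_size * E, -0.05, 0.05), vocab_size, E)),
    init_gru(u1, E, "g1f"), init_gru(u1, E, "g1b"),
    init_gru(u2, 2L * u1, "g2f"), init_gru(u2, 2L * u1, "g2b"),
    list(d1_W = glorot(h1, 2L * u2 + cfg$max_charge),
         d1_b = numeric(h1),
         d2_W = glorot(h2, h1),
         d2_b = numeric(h2),
         out_W = matrix(0, 1L, h2),   # zero head: untrained model = baseline
         out_b = 0))
}

#' Build the GRU residual CCS model
#'
#' Assembles the architecture around a frozen square-root baseline. The
#' final output layer is zero-initialised, so an untrained model predicts
#' exactly the baseline. The baseline parameters are not part of the
#' trainable weights and are bit-identical before and after training.
#'
#' @param vocab A [token_vocab()].
#' @param baseline A \code{sqrt_fit} from [fit_sqrt()].
#' @param config A [model_config()].
#' @param seed Seed for weight initialisation.
#' @return Object of class \code{ccs_model} with elements \code{config},
#'   \code{vocab}, \code{baseline}, \code{weights} and \code{param_count}.
#' @export
build_ccs_model <- function(vocab = token_vocab(), baseline,
                            config = model_config(), seed = 42L) {
  stopifnot(inherits(baseline, "sqrt_fit"))
  if (length(vocab$tokens) > 64L)
    stop_config("vocabulary (%d tokens) exceeds the embedding table limit of 64",
                length(vocab$tokens))
  weights <- with_seed(seed, init_weights(length(vocab$tokens), config))
  model <- structure(list(config = config, vocab = vocab,
                          baseline = baseline, weights = weights),
                     class = "ccs_model")
  model$param_count <- count_params(model)
  model
}

#' Trainable parameter count of a model
#'
#' Sum over all trainable weight arrays (the frozen baseline excluded).
#' Each GRU direction contributes \code{3 * (in * u + u^2 + 2u)} weights.
#'
#' @param model A \code{ccs_model}.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' @export
print.ccs_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<ccs_model: embedding %d, biGRU %d+%d/dir, ",
                     "dense %d-%d, dropout %.2f, max charge %d>\n"),
              cfg$embedding_dim, cfg$gru_units[1L], cfg$gru_units[2L],
              cfg$dense_units[1L], cfg$dense_units[2L], cfg$dropout,
              cfg$max_charge))
  cat(sprintf("  vocabulary: %d tokens; trainable weights: %s\n",
              length(x$vocab$tokens), format(x$param_count, big.mark = ",")))
  invisible(x)
}

seqs_to_ids <- function(sequences, vocab) {
  lapply(sequences, function(s) {
    tokens <- tokenize(s)
    ids <- unname(vocab$index[tokens])
    if (anyNA(ids))
      stop_token("sequence \"%s\" contains tokens outside the model vocabulary", s)
    as.integer(ids)
  })
}

#' Training configuration
#'
#' Adam with MAE objective and the plateau schedule: if the validation MAE
#' has not improved for \code{patience} epochs the learning rate is divided
#' by 10; if it then fails to improve for another \code{patience} epochs,
#' training stops. The weights of the best validation epoch are returned.
#'
#' @param learning_rate Initial learning rate (default 1e-3).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Plateau length in epochs (default 3).
#' @param lr_factor Multiplicative learning-rate reduction (default 0.1).
#' @param seed Seed controlling shuffling and dropout; a fixed seed makes
#'   training bit-reproducible.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 100L, patience = 3L, lr_factor = 0.1,
                         seed = 1L) {
  if (patience < 1L) stop_config("patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_factor = lr_factor, seed = as.integer(seed)),
            class = "train_config")
}

prepare_training_frame <- function(ds, model, what) {
  if (nrow(ds) == 0L) stop_train("%s set is empty", what)
  if (anyNA(ds$ccs)) stop_train("%s set has records without CCS", what)
  if (any(ds$charge > model$config$max_charge))
    stop_train("%s set contains charges above max_charge %d",
               what, model$config$max_charge)
  list(ids = seqs_to_ids(ds$sequence, model$vocab),
       charge = as.integer(ds$charge),
       target = ds$ccs - predict_init(ds$mz, ds$charge, model$baseline))
}

#' Train the GRU residual model
#'
#' Optimizes only the network weights theta (the square-root baseline is
#' frozen) by Adam on the mean absolute error of the predicted residual,
#' which equals the MAE of the final CCS prediction. Validation MAE is
#' computed after every epoch and drives the learning-rate schedule and
#' early stopping.
#'
#' @param model A \code{ccs_model}.
#' @param train,val Training and validation [ion_dataset()]s with CCS.
#' @param config A [train_config()].
#' @return List with \code{model} (best-validation weights),
#'   \code{history} (data frame: epoch, train_mae, val_mae, lr),
#'   \code{best_epoch}, \code{best_val_mae} and \code{baseline_val_mae}
#'   (validation MAE of the baseline alone).
#' @export
train_ccs_model <- function(model, train, val, config = train_config()) {
  stopifnot(inherits(model, "ccs_model"), inherits(config, "train_config"))
  tr <- prepare_training_frame(train, model, "training")
  va <- prepare_training_frame(val, model, "validation")

  res <- cpp_train_gru(model$weights, cpp_config(model),
                       tr$ids, tr$charge, tr$target,
                       va$ids, va$charge, va$target,
                       config$learning_rate, config$batch_size,
                       config$max_epochs, config$patience,
                       config$lr_factor, config$seed)

  trained <- model
  trained$weights <- restore_weight_shapes(res$weights, model$weights)
  history <- data.frame(epoch = seq_along(res$val_mae),
                        train_mae = res$train_mae,
                        val_mae = res$val_mae,
                        lr = res$lr)
  list(model = trained, history = history,
       best_epoch = res$best_epoch, best_val_mae = res$best_val_mae,
       baseline_val_mae = mean(abs(va$target)))
}

# C++ returns biases as 1-column matrices; restore the original vector
# shapes so weight lists stay interchangeable.
restore_weight_shapes <- function(new, template) {
  out <- template
  for (nm in names(template)) {
    w <- new[[nm]]
    if (is.matrix(template[[nm]])) out[[nm]] <- matrix(w, nrow(template[[nm]]),
                                                       ncol(template[[nm]]))
    else out[[nm]] <- as.numeric(w)
  }
  out
}

#' Predict CCS for a dataset
#'
#' Returns the additive decomposition per ion: the frozen square-root
#' baseline, the network residual, and their sum \code{ccs_predicted}.
#' When a record has no m/z it is recomputed from the sequence mass and
#' charge.
#'
#' @param object A \code{ccs_model}.
#' @param newdata An [ion_dataset()] or data frame with \code{sequence},
#'   \code{charge} and optionally \code{mz}.
#' @param ... Unused.
#' @return Data frame with \code{ccs_baseline}, \code{residual},
#'   \code{ccs_predicted}.
#' @export
predict.ccs_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  if (nrow(df) == 0L)
    return(data.frame(ccs_baseline = numeric(0), residual = numeric(0),
                      ccs_predicted = numeric(0)))
  over <- which(df$charge > object$config$max_charge | df$charge < 1L)
  if (length(over))
    stop_predict("charge outside 1..%d in row(s): %s",
                 object$config$max_charge,
                 paste(utils::head(over, 10L), collapse = ", "))
  mz <- if (is.null(df$mz)) rep(NA_real_, nrow(df)) else df$mz
  needs_mz <- is.na(mz)
  if (any(needs_mz))
    mz[needs_mz] <- peptide_mz(
      vapply(df$sequence[needs_mz], monoisotopic_mass, numeric(1)),
      df$charge[needs_mz])
  ids <- seqs_to_ids(df$sequence, object$vocab)
  residual <- cpp_predict_gru(object$weights, cpp_config(object), ids,
                              as.integer(df$charge))
  baseline <- predict_init(mz, df$charge, object$baseline)
  data.frame(ccs_baseline = baseline, residual = residual,
             ccs_predicted = baseline + residual)
}

#' Extract the token embedding vectors
#'
#' One row per vocabulary token, \code{embedding_dim} columns; lets the
#' learned grouping of unmodified and modified amino acids be inspected.
#'
#' @param model A \code{ccs_model}.
#' @return Numeric matrix with token row names.
#' @export
extract_embeddings <- function(model) {
  emb <- model$weights$emb
  rownames(emb) <- model$vocab$tokens
  emb
}

#' Save a model as plain-text JSON files
#'
#' Writes \code{config.json} (architecture, vocabulary, parameter count),
#' \code{baseline.json} (frozen square-root fit) and \code{weights.json}
#' (full-precision weight arrays keyed by layer name) into a directory.
#'
#' @param model A \code{ccs_model}.
#' @param dir Output directory (created if missing).
#' @export
save_ccs_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = unclass(model$config),
         vocab = model$vocab$tokens,
         param_count = model$param_count),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  write_sqrt_fit(model$baseline, file.path(dir, "baseline.json"))
  jsonlite::write_json(model$weights, file.path(dir, "weights.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Load a model saved by [save_ccs_model()]
#'
#' @param dir Directory containing config.json, baseline.json, weights.json.
#' @return A \code{ccs_model}.
#' @export
load_ccs_model <- function(dir) {
  conf <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- model_config(embedding_dim = conf$config$embedding_dim,
                      gru_units = conf$config$gru_units,
                      dense_units = conf$config$dense_units,
                      dropout = conf$config$dropout,
                      max_charge = conf$config$max_charge)
  vocab <- token_vocab()
  if (!identical(vocab$tokens, as.character(conf$vocab)))
    stop_config("saved vocabulary does not match the packaged vocabulary")
  baseline <- read_sqrt_fit(file.path(dir, "baseline.json"))
  weights <- jsonlite::read_json(file.path(dir, "weights.json"),
                                 simplifyVector = TRUE)
  model <- structure(list(config = cfg, vocab = vocab, baseline = baseline,
                          weights = weights),
                     class = "ccs_model")
  model$param_count <- count_params(model)
  stopifnot(model$param_count == conf$param_count)
  model
}
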