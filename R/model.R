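#' Configuration for the stacked LSTM recurrence model
#'
#' Defaults follow the reference architecture: 300-dim note-vector inputs,
#' a first LSTM layer of 50 units with batch normalisation and 20% dropout,
#' a second LSTM layer of 25 units with 20% dropout, and a per-timestep
#' 3-way softmax (no recurrence / recurrence / pad). Training uses weighted
#' categorical cross-entropy (pad class weight 0), Adam, batch size 32,
#' 20 epochs, and a learning rate of `initial_lr * lr_decay^(epoch-1)`.
#'
#' @param input_dim Note-vector dimension.
#' @param layer1_units,layer2_units Hidden units in LSTM layers 1 and 2.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param n_classes Output classes (3: no-recurrence, recurrence, pad).
#' @param batch_size,epochs Training batch size and epoch count.
#' @param initial_lr,lr_decay Initial learning rate and per-epoch decay.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return An `lstm_config` list.
#' @export
lstm_config <- function(input_dim = 300L, layer1_units = 50L,
                        layer2_units = 25L, dropout = 0.2, n_classes = 3L,
                        batch_size = 32L, epochs = 20L, initial_lr = 1e-3,
                        lr_decay = 0.9, seed = 1L) {
  cfg <- list(
    input_dim = as.integer(input_dim), layer1_units = as.integer(layer1_units),
    layer2_units = as.integer(layer2_units), dropout = dropout,
    n_classes = as.integer(n_classes), batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), initial_lr = initial_lr,
    lr_decay = lr_decay, seed = as.integer(seed)
  )
  with(cfg, stopifnot(
    input_dim > 0, layer1_units > 0, layer2_units > 0, n_classes > 1,
    batch_size > 0, epochs > 0, initial_lr > 0, lr_decay > 0,
    dropout >= 0, dropout < 1
  ))
  structure(cfg, class = "lstm_config")
}

#' Closed-form trainable parameter count
#'
#' Counts the trainable parameters of the architecture:
#' `4 * (input_dim + h1 + 1) * h1` for layer 1, `2 * h1` batch-norm scale
#' and shift parameters, `4 * (h1 + h2 + 1) * h2` for layer 2, and
#' `(h2 + 1) * n_classes` for the softmax output layer. The default
#' configuration gives 77,978 (about 78 K).
#'
#' @param config An `lstm_config`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "lstm_config"))
  d <- config$input_dim; h1 <- config$layer1_units
  h2 <- config$layer2_units; C <- config$n_classes
  as.integer(4L * (d + h1 + 1L) * h1 + 2L * h1 +
               4L * (h1 + h2 + 1L) * h2 + (h2 + 1L) * C)
}

#' Build an untrained stacked LSTM model
#'
#' Initialises all parameters (Glorot-uniform kernels, forget-gate bias 1,
#' unit batch-norm scale) deterministically from `config$seed`.
#'
#' @param config An `lstm_config`.
#' @return An `lstm_model`: list with `config`, `params`, `history`.
#' @export
build_lstm <- function(config = lstm_config()) {
  stopifnot(inherits(config, "lstm_config"))
  d <- config$input_dim; h1 <- config$layer1_units
  h2 <- config$layer2_units; C <- config$n_classes
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  lstm_bias <- function(h) c(numeric(h), rep(1, h), numeric(2L * h))
  params <- with_seed(config$seed, list(
    W1 = glorot(4L * h1, d + h1), b1 = lstm_bias(h1),
    gamma = rep(1, h1), beta = numeric(h1),
    run_mean = numeric(h1), run_var = rep(1, h1),
    W2 = glorot(4L * h2, h1 + h2), b2 = lstm_bias(h2),
    Wout = glorot(C, h2), bout = numeric(C)
  ))
  structure(list(config = config, params = params, history = NULL),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cfg <- x$config
  cat("Stacked LSTM: ", cfg$input_dim, " -> LSTM(", cfg$layer1_units,
      ") + BN + dropout -> LSTM(", cfg$layer2_units, ") + dropout -> ",
      cfg$n_classes, "-class softmax (", count_parameters(cfg),
      " trainable parameters)\n", sep = "")
  if (!is.null(x$history))
    cat("Trained ", length(x$history), " epochs; final loss ",
        signif(tail(x$history, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Trainable parameter count of a built model
#'
#' Enumerates the model's actual parameter arrays (excluding the
#' non-trainable batch-norm running moments); serves as an independent
#' check of [count_parameters()].
#'
#' @param model An `lstm_model`.
#' @return Integer count.
#' @export
model_parameter_count <- function(model) {
  stopifnot(inherits(model, "lstm_model"))
  p <- model$params[c("W1", "b1", "gamma", "beta", "W2", "b2", "Wout", "bout")]
  sum(vapply(p, length, integer(1)))
}

#' Inverse-frequency class weights over real positions
#'
#' @param y Integer matrix of sequence labels (0/1/2 with 2 = pad).
#' @return Length-2 numeric weights for classes 0 and 1, scaled so their
#'   weighted mean over real positions is 1. The pad class always gets 0.
#' @export
inverse_class_weights <- function(y) {
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("both real classes must be present to compute class weights")
  n <- n0 + n1
  c(n / (2 * n0), n / (2 * n1))
}

#' Train the stacked LSTM on a sequence batch
#'
#' Optimises weighted categorical cross-entropy with Adam; padded positions
#' carry zero weight and thus contribute nothing to the loss or gradients.
#' Training is deterministic given `config$seed` (single-threaded).
#'
#' @param model An `lstm_model` from [build_lstm()].
#' @param batch A `sequence_batch` from [build_sequence_batch()]. Its `w`
#'   matrix is used as the per-position sample weight (build it with the
#'   desired class weights, e.g. [inverse_class_weights()]).
#' @param epochs,batch_size Optional overrides of the config values.
#' @return The trained `lstm_model` with a per-epoch loss `history`.
#' @export
train_lstm <- function(model, batch, epochs = NULL, batch_size = NULL) {
  stopifnot(inherits(model, "lstm_model"), inherits(batch, "sequence_batch"))
  cfg <- model$config
  if (dim(batch$X)[1] != cfg$input_dim)
    stop("batch input dimension does not match the model")
  if (all(batch$w == 0)) stop("all positions carry zero weight (all-pad batch)")
  res <- cpp_lstm_train(
    model$params, batch$X, batch$y, batch$w,
    as.integer(epochs %||% cfg$epochs),
    as.integer(batch_size %||% cfg$batch_size),
    cfg$initial_lr, cfg$lr_decay, cfg$dropout, cfg$n_classes, cfg$seed
  )
  model$params <- res$params
  model$history <- c(model$history, as.numeric(res$loss))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-timestep class probabilities for padded sequences
#'
#' Runs the model in inference mode (running batch-norm statistics, no
#' dropout). Inference is strictly causal: the output at timestep t
#' depends only on inputs at timesteps <= t.
#'
#' @param model A trained `lstm_model`.
#' @param X A dim x max_len x n array (or a `sequence_batch`).
#' @return A `n_classes` x max_len x n array of probabilities.
#' @export
predict_lstm <- function(model, X) {
  stopifnot(inherits(model, "lstm_model"))
  if (inherits(X, "sequence_batch")) X <- X$X
  if (dim(X)[1] != model$config$input_dim)
    stop("input dimension does not match the model")
  cpp_lstm_predict(model$params, X, model$config$n_classes)
}

#' Recurrence probability trajectory for one padded sequence
#'
#' Returns the class-1 (recurrence) softmax probability at each real
#' (unpadded) position, in chronological order.
#'
#' @param model A trained `lstm_model`.
#' @param X A dim x max_len matrix (one sequence) or dim x max_len x 1 array.
#' @param n_real Number of real positions at the start of the sequence.
#' @return Numeric vector of length `n_real`.
#' @export
predict_sequence <- function(model, X, n_real) {
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1L))
  P <- predict_lstm(model, X)
  stopifnot(n_real <= dim(P)[2])
  as.numeric(P[2L, seq_len(n_real), 1L])
}

#' Gradient-boosted single-note baseline
#'
#' Trains an XGBoost binary classifier on individual note vectors (pad
#' positions excluded), ignoring all temporal context; this is the
#' reference point against which the sequence model's use of history is
#' measured.
#'
#' @param vectors Numeric matrix of note vectors (rows = notes).
#' @param labels Integer 0/1 per-note labels.
#' @param nrounds Boosting rounds (default 100).
#' @param seed RNG seed.
#' @param params Named list of extra xgboost parameters (defaults
#'   otherwise).
#' @return A `gbt_model` wrapping the fitted booster.
#' @export
train_gbt_baseline <- function(vectors, labels, nrounds = 100L, seed = 1L,
                               params = list()) {
  vectors <- as.matrix(vectors)
  labels <- as.integer(labels)
  stopifnot(nrow(vectors) == length(labels), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("baseline training requires both classes")
  p <- utils::modifyList(
    list(objective = "binary:logistic", nthread = 1L,
         eval_metric = "logloss", seed = as.integer(seed)),
    params
  )
  dtrain <- xgboost::xgb.DMatrix(vectors, label = labels, nthread = 1L)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = p, data = dtrain, nrounds = as.integer(nrounds), verbose = 0
  ))
  structure(list(booster = booster), class = "gbt_model")
}

#' @rdname train_gbt_baseline
#' @param model A `gbt_model`.
#' @export
predict_gbt <- function(model, vectors) {
  stopifnot(inherits(model, "gbt_model"))
  dm <- xgboost::xgb.DMatrix(as.matrix(vectors), nthread = 1L)
  stats::predict(model$booster, dm)
}
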