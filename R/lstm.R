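#' LSTM model configuration
#'
#' Hyperparameters of the stacked LSTM classifier. The defaults are the
#' full-scale configuration used for real EHR cohorts: four layers of 100
#' LSTM units, dropout probability 0.4 on the non-recurrent (inter-layer)
#' connections, 1,000 training epochs of 40 mini-batches with 50 sequences
#' each, and positive sequences weighted three times higher than negative
#' ones in the cross-entropy loss (the class imbalance adjustment for
#' cohorts where negative admissions dominate).
#'
#' Optimizer settings (Adam with gradient-norm clipping) are the package's
#' own documented defaults; they are recorded in the training log.
#'
#' @param n_layers Number of stacked LSTM layers.
#' @param units LSTM units per layer.
#' @param dropout_p Dropout probability on layer inputs during training.
#' @param epochs Training epochs.
#' @param batches_per_epoch Mini-batches processed per epoch.
#' @param batch_size Sequences per mini-batch.
#' @param positive_weight Loss weight multiplier for positive hours.
#' @param learning_rate Adam step size.
#' @param clip_norm Global L2 gradient-norm clip.
#' @param validation_interval Epoch interval at which train/validation
#'   AUROC is recorded in the training log.
#' @param seed Integer seed for weight initialization, batch sampling and
#'   dropout.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(n_layers = 4, units = 100, dropout_p = 0.4,
                        epochs = 1000, batches_per_epoch = 40,
                        batch_size = 50, positive_weight = 3,
                        learning_rate = 0.005, clip_norm = 5,
                        validation_interval = 10, seed = 1L) {
  stopifnot(n_layers >= 1, units >= 1, dropout_p >= 0, dropout_p < 1,
            positive_weight > 0, epochs >= 1, batch_size >= 1,
            batches_per_epoch >= 1, learning_rate > 0)
  structure(list(n_layers = as.integer(n_layers), units = as.integer(units),
                 dropout_p = dropout_p, epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 batch_size = as.integer(batch_size),
                 positive_weight = positive_weight,
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 validation_interval = as.integer(validation_interval),
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' @rdname lstm_config
#' @details `desk_scale_preset()` is a small configuration (2 layers of 16
#'   units, 30 epochs, light dropout) sized so that the full
#'   cross-validation harness runs in minutes on one CPU core against
#'   synthetic cohorts of a few hundred admissions; it is the configuration
#'   used throughout the test suite and worked examples.
#' @export
desk_scale_preset <- function(seed = 1L) {
  lstm_config(n_layers = 2, units = 16, dropout_p = 0.2, epochs = 30,
              batches_per_epoch = 8, batch_size = 32, positive_weight = 3,
              learning_rate = 0.01, clip_norm = 5,
              validation_interval = 5, seed = seed)
}

lstm_dims <- function(n_features, config) {
  list(n_features = as.integer(n_features), n_layers = config$n_layers,
       units = config$units)
}

lstm_n_params <- function(dims) {
  u <- dims$units
  tot <- 0L
  for (l in seq_len(dims$n_layers)) {
    fin <- if (l == 1) dims$n_features else u
    tot <- tot + fin * 4 * u + u * 4 * u + 4 * u
  }
  tot + u + 1L
}

#' Initialize LSTM parameters
#'
#' Glorot-uniform initialization for input and recurrent weights, zero
#' biases except the forget-gate bias which starts at 1 (the usual device
#' to keep early memory open). Deterministic given the RNG state.
#'
#' @param n_features Input feature dimension.
#' @param config An [lstm_config()].
#' @return Numeric parameter vector in the packed layout used by the
#'   C++ backend (per layer `W`, `U`, `b` with gate blocks
#'   `i | f | o | g`, then the output head).
#' @export
lstm_init <- function(n_features, config) {
  dims <- lstm_dims(n_features, config)
  u <- dims$units
  parts <- list()
  for (l in seq_len(dims$n_layers)) {
    fin <- if (l == 1) dims$n_features else u
    rW <- sqrt(6 / (fin + 4 * u))
    rU <- sqrt(6 / (u + 4 * u))
    b <- rep(0, 4 * u)
    b[(u + 1):(2 * u)] <- 1  # forget gate bias
    parts[[length(parts) + 1]] <- stats::runif(fin * 4 * u, -rW, rW)
    parts[[length(parts) + 1]] <- stats::runif(u * 4 * u, -rU, rU)
    parts[[length(parts) + 1]] <- b
  }
  rO <- sqrt(6 / (u + 1))
  parts[[length(parts) + 1]] <- stats::runif(u, -rO, rO)
  parts[[length(parts) + 1]] <- 0
  unlist(parts, use.names = FALSE)
}

#' Unpack a flat parameter vector into named gate matrices
#'
#' Returns, per layer, the input weight matrices `W_i`, `W_f`, `W_o`, `W_c`
#' (input_dim x units), recurrent matrices `U_i`, `U_f`, `U_o`, `U_c`
#' (units x units) and bias vectors `b_i`, `b_f`, `b_o`, `b_c`, plus the
#' output head (`w_out`, `b_out`). The naive reference implementation
#' ([lstm_cell_step()]) consumes this form.
#'
#' @param params Flat parameter vector from [lstm_init()] or a trained
#'   model.
#' @param n_features Input feature dimension.
#' @param config The [lstm_config()] the vector was built for.
#' @return List with `layers` (list of per-layer weight lists), `w_out`,
#'   `b_out`.
#' @export
lstm_unpack <- function(params, n_features, config) {
  dims <- lstm_dims(n_features, config)
  u <- dims$units
  stopifnot(length(params) == lstm_n_params(dims))
  off <- 0L
  take <- function(n) {
    out <- params[(off + 1):(off + n)]
    off <<- off + n
    out
  }
  gates <- c("i", "f", "o", "c")  # candidate block is "c" here, "g" in C++
  layers <- vector("list", dims$n_layers)
  for (l in seq_len(dims$n_layers)) {
    fin <- if (l == 1) dims$n_features else u
    W <- matrix(take(fin * 4 * u), nrow = fin)
    U <- matrix(take(u * 4 * u), nrow = u)
    b <- take(4 * u)
    lw <- list()
    for (q in seq_along(gates)) {
      cols <- ((q - 1) * u + 1):(q * u)
      lw[[paste0("W_", gates[q])]] <- W[, cols, drop = FALSE]
      lw[[paste0("U_", gates[q])]] <- U[, cols, drop = FALSE]
      lw[[paste0("b_", gates[q])]] <- b[cols]
    }
    layers[[l]] <- lw
  }
  list(layers = layers, w_out = take(u), b_out = take(1))
}

#' One LSTM cell update (reference implementation)
#'
#' A direct, naive transcription of the LSTM recurrence, kept deliberately
#' independent of the compiled training backend so the two can be checked
#' against each other:
#' \deqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)}
#' \deqn{i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i)}
#' \deqn{o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)}
#' \deqn{c_t = f_t \circ c_{t-1} + i_t \circ \tanh(W_c x_t + U_c h_{t-1} + b_c)}
#' \deqn{h_t = o_t \circ \tanh(c_t)}
#' with \eqn{\sigma} the logistic sigmoid and \eqn{\circ} the elementwise
#' product.
#'
#' @param x Input vector (length input_dim).
#' @param state List with cell state `c` and hidden state `h` (length
#'   units); use zeros at the first hour.
#' @param w Per-layer weight list as produced by [lstm_unpack()]: matrices
#'   `W_q` (input_dim x units), `U_q` (units x units), biases `b_q` for
#'   q in i, f, o, c.
#' @return List with updated `c` and `h`.
#' @export
lstm_cell_step <- function(x, state, w) {
  stopifnot(length(x) == nrow(w$W_f), length(state$h) == nrow(w$U_f))
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(drop(x %*% w$W_f) + drop(state$h %*% w$U_f) + w$b_f)
  i <- sig(drop(x %*% w$W_i) + drop(state$h %*% w$U_i) + w$b_i)
  o <- sig(drop(x %*% w$W_o) + drop(state$h %*% w$U_o) + w$b_o)
  cc <- tanh(drop(x %*% w$W_c) + drop(state$h %*% w$U_c) + w$b_c)
  c_new <- f * state$c + i * cc
  h_new <- o * tanh(c_new)
  list(c = c_new, h = h_new)
}

#' Naive full forward pass (reference implementation)
#'
#' Runs the stacked recurrence hour by hour with [lstm_cell_step()], layer
#' `l`'s hidden state feeding layer `l+1`'s input, states initialized to
#' zero at hour 0, then maps the top layer's hidden state through the
#' affine + sigmoid output head. Used as the independent oracle for the
#' compiled backend; quadratic bookkeeping, so keep instances small.
#'
#' @inheritParams lstm_unpack
#' @param x Sequence matrix (hours x features), standardized and dense.
#' @return Numeric vector of per-hour probabilities.
#' @export
lstm_forward_naive <- function(x, params, config) {
  uw <- lstm_unpack(params, ncol(x), config)
  u <- config$units
  probs <- numeric(nrow(x))
  states <- lapply(seq_len(config$n_layers),
                   function(l) list(c = rep(0, u), h = rep(0, u)))
  for (t in seq_len(nrow(x))) {
    inp <- x[t, ]
    for (l in seq_len(config$n_layers)) {
      states[[l]] <- lstm_cell_step(inp, states[[l]], uw$layers[[l]])
      inp <- states[[l]]$h
    }
    logit <- sum(uw$w_out * inp) + uw$b_out
    probs[t] <- 1 / (1 + exp(-logit))
  }
  probs
}

#' Forward pass of a (trained or raw) model
#'
#' Dropout is inactive; output is the per-hour probability of developing
#' septic shock. Inputs must be dense (no `NA`) and standardized with the
#' statistics the model was trained with.
#'
#' @param model A `sepsis_lstm` object (see [lstm_train()]), or a list with
#'   `params`, `n_features`, `config`.
#' @param x A single hours-x-features matrix or a list of them.
#' @return A probability vector, or a list of them when `x` is a list.
#' @export
lstm_forward <- function(model, x) {
  single <- is.matrix(x)
  xs <- if (single) list(x) else x
  for (m in xs) {
    if (!is.matrix(m) || ncol(m) != model$n_features) {
      stop("input has ", if (is.matrix(m)) ncol(m) else NA,
           " features; model expects ", model$n_features)
    }
    if (anyNA(m)) stop("input sequences must be dense (impute first)")
  }
  out <- cpp_lstm_forward(xs, model$params, model$n_features,
                          model$config$n_layers, model$config$units)
  out <- lapply(out, as.numeric)
  if (single) out[[1]] else out
}

#' @export
predict.sepsis_lstm <- function(object, newdata, ...) {
  lstm_forward(object, newdata)
}

#' @export
print.sepsis_lstm <- function(x, ...) {
  cat(sprintf("<sepsis_lstm> %d-layer x %d-unit LSTM, %d input features, %d parameters\n",
              x$config$n_layers, x$config$units, x$n_features,
              length(x$params)))
  if (!is.null(x$log) && nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epochs; final loss %.4f", last$epoch, last$loss))
    if (!is.na(last$val_auroc)) cat(sprintf(", val AUROC %.3f", last$val_auroc))
    cat("\n")
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned JSON container holding the flat parameter
#' vector, the configuration, the feature list and the population
#' statistics (with scope provenance) used for standardization, so a saved
#' model can score new admissions end to end.
#'
#' @param model A `sepsis_lstm`.
#' @param path File path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   `sepsis_lstm`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    container = "shockcast-lstm-checkpoint",
    version = 1L,
    n_features = model$n_features,
    features = model$features,
    config = unclass(model$config),
    params = model$params,
    stats = if (!is.null(model$stats)) {
      list(feature = model$stats$feature, mean = model$stats$mean,
           sd = model$stats$sd, n_obs = model$stats$n_obs,
           scope = attr(model$stats, "scope"))
    },
    log = model$log
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (!identical(payload$container, "shockcast-lstm-checkpoint")) {
    stop("not a shockcast model checkpoint: ", path)
  }
  config <- do.call(lstm_config, payload$config[names(formals(lstm_config))])
  stats <- NULL
  if (!is.null(payload$stats)) {
    stats <- data.frame(feature = payload$stats$feature,
                        mean = payload$stats$mean, sd = payload$stats$sd,
                        n_obs = payload$stats$n_obs, stringsAsFactors = FALSE)
    class(stats) <- c("population_stats", "data.frame")
    attr(stats, "scope") <- payload$stats$scope
  }
  structure(list(params = as.numeric(payload$params),
                 n_features = as.integer(payload$n_features),
                 features = payload$features, config = config,
                 stats = stats, log = as.data.frame(payload$log)),
            class = "sepsis_lstm")
}
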