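#' Train the stacked LSTM classifier
#'
#' Minimizes class-weighted binary cross-entropy over per-hour targets:
#' every hour of a sequence carries its admission's outcome label (1 if the
#' admission develops septic shock, 0 otherwise), with positive hours
#' weighted `positive_weight` times higher. Callers are expected to
#' truncate positive admissions' inputs at septic-shock onset before
#' training (post-onset hours would leak the outcome); see
#' [prepare_sequences()]. Optimization is Adam with global gradient-norm
#' clipping over mini-batches drawn by shuffling and cycling the training
#' set. Dropout (inverted, per-sequence masks on each layer's input) is
#' active during training only. Deterministic given `config$seed`.
#'
#' @param train_x List of standardized, dense hours-x-features matrices.
#' @param train_y Logical/0-1 vector: outcome per training sequence.
#' @param val_x,val_y Optional validation sequences and outcomes; when
#'   given, validation AUROC (admission score = max per-hour probability)
#'   is logged every `config$validation_interval` epochs.
#' @param config An [lstm_config()].
#' @param features Optional feature-name vector stored in the model.
#' @param stats Optional `population_stats` stored for provenance.
#' @return A `sepsis_lstm`: list with `params`, `n_features`, `config`,
#'   `features`, `stats` and a training `log` (data.frame with columns
#'   `epoch`, `loss`, `train_auroc`, `val_auroc`; AUROCs are `NA` between
#'   validation intervals).
#' @export
lstm_train <- function(train_x, train_y, val_x = NULL, val_y = NULL,
                       config = desk_scale_preset(), features = NULL,
                       stats = NULL) {
  train_y <- as.logical(train_y)
  stopifnot(length(train_x) == length(train_y))
  if (!any(train_y) || all(train_y)) {
    stop("training set needs both positive and negative admissions")
  }
  for (m in train_x) {
    if (anyNA(m)) stop("training sequences must be dense (impute first)")
  }
  n_features <- ncol(train_x[[1]])

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)

  params <- lstm_init(n_features, config)
  np <- length(params)
  m_adam <- v_adam <- numeric(np)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  targets <- lapply(seq_along(train_x),
                    function(i) rep(as.numeric(train_y[i]), nrow(train_x[[i]])))
  weights <- lapply(seq_along(train_x), function(i) {
    rep(if (train_y[i]) config$positive_weight else 1, nrow(train_x[[i]]))
  })

  n <- length(train_x)
  pool <- sample.int(n)
  pool_pos <- 0L
  next_batch <- function() {
    idx <- integer(0)
    while (length(idx) < config$batch_size) {
      if (pool_pos >= n) {
        pool <<- sample.int(n)
        pool_pos <<- 0L
      }
      take <- min(config$batch_size - length(idx), n - pool_pos)
      idx <- c(idx, pool[(pool_pos + 1):(pool_pos + take)])
      pool_pos <<- pool_pos + take
    }
    idx
  }

  score_set <- function(xs) {
    vapply(lstm_forward(list(params = params, n_features = n_features,
                             config = config), xs),
           max, 0)
  }

  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- 0
    for (b in seq_len(config$batches_per_epoch)) {
      idx <- next_batch()
      lg <- cpp_lstm_loss_grad(train_x[idx], targets[idx], weights[idx],
                               params, n_features, config$n_layers,
                               config$units, config$dropout_p)
      g <- as.numeric(lg$grad)
      gn <- sqrt(sum(g^2))
      if (is.finite(config$clip_norm) && gn > config$clip_norm) {
        g <- g * (config$clip_norm / gn)
      }
      step <- step + 1L
      m_adam <- beta1 * m_adam + (1 - beta1) * g
      v_adam <- beta2 * v_adam + (1 - beta2) * g^2
      mhat <- m_adam / (1 - beta1^step)
      vhat <- v_adam / (1 - beta2^step)
      params <- params - config$learning_rate * mhat / (sqrt(vhat) + eps)
      epoch_loss <- epoch_loss + lg$loss
    }
    tr_auc <- va_auc <- NA_real_
    if (epoch %% config$validation_interval == 0 || epoch == config$epochs) {
      tr_auc <- auroc(score_set(train_x), train_y)
      if (!is.null(val_x) && length(val_x) && length(unique(val_y)) == 2) {
        va_auc <- auroc(score_set(val_x), as.logical(val_y))
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = epoch_loss / config$batches_per_epoch,
      train_auroc = tr_auc, val_auroc = va_auc
    )
  }

  structure(list(params = params, n_features = n_features, config = config,
                 features = features, stats = stats,
                 log = do.call(rbind, log_rows)),
            class = "sepsis_lstm")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Prepare model-ready sequences from grids and labels
#'
#' Applies the fold-scoped half of the feature pipeline and the
#' onset-truncation rule: each admission's grid is population-mean imputed
#' and standardized with the supplied statistics, and positive admissions
#' are truncated at septic-shock onset (hours `0..onset` inclusive; the
#' onset hour itself is the diagnosis hour, later hours would leak the
#' outcome).
#'
#' @param grids Named list of [hourly_grid()] (from [build_grids()]).
#' @param onsets Onset table from [label_cohort()] (`admission_id`,
#'   `onset_hour`, `shock`).
#' @param stats `population_stats` computed on the training scope.
#' @param ranges Feature table.
#' @return List with `x` (named list of dense standardized matrices), `y`
#'   (named logical outcome vector), `onset` (named integer vector, NA for
#'   negatives).
#' @export
prepare_sequences <- function(grids, onsets, stats,
                              ranges = default_feature_table()) {
  ids <- names(grids)
  row <- match(ids, onsets$admission_id)
  if (anyNA(row)) stop("onset table missing admission(s): ",
                       paste(ids[is.na(row)], collapse = ", "))
  y <- onsets$shock[row]
  onset <- onsets$onset_hour[row]
  x <- vector("list", length(ids))
  names(x) <- ids
  for (i in seq_along(ids)) {
    g <- standardize(impute_population_mean(grids[[i]], stats), stats, ranges)
    v <- g$values
    if (y[i] && !is.na(onset[i])) {
      v <- v[seq_len(onset[i] + 1L), , drop = FALSE]
    }
    x[[i]] <- v
  }
  names(y) <- names(onset) <- ids
  list(x = x, y = y, onset = onset)
}
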