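# Adam optimizer over a named list of parameter arrays.

adam_state <- function(params) {
  numeric_par <- Filter(is.numeric, params)
  list(m = lapply(numeric_par, function(p) p * 0),
       v = lapply(numeric_par, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay_on = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(dim(params[[nm]]))) g <- as.numeric(g)
    if (weight_decay > 0 && nm %in% decay_on) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration for gradient-fit readouts
#'
#' Hyperparameters of the Adam / mean-squared-error training loop shared by
#' the transformer and factorized readouts. Early stopping monitors the mean
#' validation Pearson correlation across vertices.
#'
#' @param learning_rate Adam step size.
#' @param batch_size stimuli per gradient step.
#' @param max_epochs upper bound on training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (the best-validation parameters are kept).
#' @param seed integer seed controlling initialization and batch order.
#' @param weight_decay L2 penalty on weight matrices (not biases/gains).
#' @param lr_schedule `"constant"`, or `"cosine"` for a cosine decay of the
#'   learning rate to zero over `max_epochs`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                         max_epochs = 30L, early_stop_patience = 5L,
                         seed = 1L, weight_decay = 0,
                         lr_schedule = c("constant", "cosine")) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, weight_decay >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), weight_decay = weight_decay,
                 lr_schedule = match.arg(lr_schedule)),
            class = "train_config")
}

# Shared minibatch Adam driver. grad_fn(params, idx) -> list(loss, grads);
# val_fn(params) -> scalar validation score (higher better) or NULL.
run_adam <- function(params, grad_fn, val_fn, config, decay_on = character()) {
  state <- adam_state(params)
  best <- list(params = params, score = -Inf, epoch = 0L)
  since_best <- 0L
  n <- attr(grad_fn, "n_train")
  history <- numeric(0)
  schedule <- config$lr_schedule %||% "constant"
  for (epoch in seq_len(config$max_epochs)) {
    lr <- if (schedule == "cosine")
      config$learning_rate * 0.5 *
        (1 + cos(pi * (epoch - 1) / config$max_epochs))
    else config$learning_rate
    old <- .Random.seed_exists()
    set.seed(config$seed + 1000L * epoch)
    ord <- sample.int(n)
    .restore_seed(old)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      gl <- grad_fn(params, idx)
      if (!is.finite(gl$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      upd <- adam_step(params, gl$grads, state, lr,
                       weight_decay = config$weight_decay, decay_on = decay_on)
      params <- upd$params
      state <- upd$state
    }
    if (!is.null(val_fn)) {
      score <- val_fn(params)
      history <- c(history, score)
      if (score > best$score + 1e-6) {
        best <- list(params = params, score = score, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$early_stop_patience) break
      }
    } else {
      best <- list(params = params, score = NA_real_, epoch = epoch)
    }
  }
  list(params = best$params, val_score = best$score, best_epoch = best$epoch,
       history = history)
}
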