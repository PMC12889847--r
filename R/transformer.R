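#' Transformer-decoder readout ("attention routing" encoder)
#'
#' The core encoding model: a learned query per readout unit (one per
#' (hemisphere, ROI) mask at `"roi"` granularity, one per vertex at
#' `"vertex"` granularity) cross-attends over the image tokens. Keys are the
#' (optionally projected) tokens plus fixed sinusoidal positional encodings,
#' values are the tokens without positions, so each query can select input by
#' grid location, by content, or both. The decoder is a single layer — one
#' cross-attention and one feedforward block with residual connections and
#' pre-normalization — followed by a per-query linear readout that is
#' multiplied by the query's binary vertex mask; masked readouts are summed
#' into the full prediction, so every vertex is predicted by exactly one
#' query and readout gradients never cross ROI boundaries. Training is Adam
#' on mean-squared error ([fit_attn_readout()]); predictions and head-averaged
#' attention maps come from [predict.attn_readout()] / [attn_forward()].
#'
#' @name attention_readout
NULL

# Parameter initialization. d_model defaults to the token dimension when it
# is at most 1024, otherwise a learned input projection maps to 768.
attn_init <- function(d, masks, n_heads = 1L, d_model = NULL, seed = 1L) {
  if (is.null(d_model)) d_model <- if (d <= 1024L) d else 768L
  use_proj <- d_model != d
  if (d_model %% n_heads != 0L)
    stop("attn_init: d_model must be divisible by n_heads")
  m <- length(masks)
  V <- length(masks[[1]])
  dh <- 4L * d_model
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  params <- list(
    Q = matrix(stats::rnorm(m * d_model), m, d_model),
    g1 = rep(1, d_model), b1 = rep(0, d_model),
    g2 = rep(1, d_model), b2 = rep(0, d_model),
    g3 = rep(1, d_model), b3 = rep(0, d_model),
    # attention projections start at identity: the initial attention is the
    # plain query-key dot product, and training can rotate content and
    # position into separate key subspaces
    Wq = diag(d_model), bq = rep(0, d_model),
    Wk = diag(d_model), bk = rep(0, d_model),
    Wv = diag(d_model), bv = rep(0, d_model),
    Wo = diag(d_model), bo = rep(0, d_model),
    W1 = matrix(stats::rnorm(d_model * dh, sd = sqrt(2 / (d_model + dh))),
                d_model, dh),
    bh = rep(0, dh),
    W2 = matrix(stats::rnorm(dh * d_model, sd = sqrt(2 / (d_model + dh))),
                dh, d_model),
    b2f = rep(0, d_model),
    Wout = matrix(stats::rnorm(d_model * V, sd = 0.01), d_model, V),
    bout = rep(0, V))
  if (use_proj) {
    params$Win <- matrix(stats::rnorm(d * d_model, sd = sqrt(2 / (d + d_model))),
                         d, d_model)
    params$bin <- rep(0, d_model)
  }
  params$use_proj <- use_proj
  params$n_heads <- as.integer(n_heads)
  params
}

# S x n x d array -> n x d x B cube expected by the C++ kernels.
tokens_to_cube <- function(tokens, idx = NULL) {
  if (!is.null(idx)) tokens <- tokens[idx, , , drop = FALSE]
  aperm(tokens, c(2, 3, 1))
}

#' Fit the transformer readout
#'
#' @param tokens `n_stimuli x n_tokens x d` training token array.
#' @param targets `n_stimuli x n_vertices` training responses.
#' @param masks named list of binary vertex masks (from [build_masks()]);
#'   must partition the vertex set.
#' @param positions a `positional_encoding` whose dimension equals the model
#'   width (token dimension unless an input projection is used).
#' @param config a [train_config()].
#' @param val_tokens,val_targets held-out data for early stopping; when
#'   `NULL`, training runs for `max_epochs`.
#' @param n_heads attention heads (default 1; attention maps are
#'   head-averaged when more are used).
#' @param d_model decoder width; defaults to the token dimension (a learned
#'   projection is inserted when they differ).
#' @return A `attn_readout`: fitted parameters, masks and query names, target
#'   standardization statistics, and the validation trace.
#' @export
fit_attn_readout <- function(tokens, targets, masks, positions, config = train_config(),
                     val_tokens = NULL, val_targets = NULL, n_heads = 1L,
                     d_model = NULL) {
  d <- dim(tokens)[3]
  owner <- mask_owner(masks)
  params <- attn_init(d, masks, n_heads = n_heads, d_model = d_model,
                      seed = config$seed)
  if (nrow(positions$table) != dim(tokens)[2] ||
      ncol(positions$table) != ncol(params$Q))
    stop("fit_attn_readout: positional encoding does not match tokens/model width")
  y_mean <- colMeans(targets)
  y_sd <- pmax(apply(targets, 2, stats::sd), 1e-8)
  Ys <- sweep(sweep(targets, 2, y_mean), 2, y_sd, "/")
  cube <- tokens_to_cube(tokens)
  grad_fn <- function(par, idx)
    .attn_grad_cpp(cube[, , idx, drop = FALSE], Ys[idx, , drop = FALSE],
                   par, positions$table, owner)
  attr(grad_fn, "n_train") <- dim(tokens)[1]
  val_fn <- NULL
  if (!is.null(val_tokens)) {
    vcube <- tokens_to_cube(val_tokens)
    Yv <- sweep(sweep(val_targets, 2, y_mean), 2, y_sd, "/")
    val_fn <- function(par) {
      pred <- .attn_forward_cpp(vcube, par, positions$table, owner, FALSE)$pred
      mean(colwise_pearson(pred, Yv), na.rm = TRUE)
    }
  }
  fit <- run_adam(params, grad_fn, val_fn, config,
                  decay_on = c("Q", "W1", "W2", "Wout", "Win",
                               "Wq", "Wk", "Wv", "Wo"))
  structure(list(params = fit$params, masks = masks, owner = owner,
                 query_names = names(masks), positions = positions,
                 y_mean = y_mean, y_sd = y_sd, n_heads = as.integer(n_heads),
                 config = config, val_score = fit$val_score,
                 best_epoch = fit$best_epoch, history = fit$history),
            class = "attn_readout")
}

#' @export
print.attn_readout <- function(x, ...) {
  cat(sprintf(
    "<attn_readout: %d queries, d_model = %d, %d head(s), %d vertices%s>\n",
    nrow(x$params$Q), ncol(x$params$Q), x$n_heads, length(x$owner),
    if (is.na(x$val_score)) "" else
      sprintf(", val r = %.3f @ epoch %d", x$val_score, x$best_epoch)))
  invisible(x)
}

#' Predict vertex responses (and attention) for a token array
#'
#' @param object a fitted `attn_readout`.
#' @param tokens `n_stimuli x n_tokens x d` array.
#' @param attention if `TRUE`, also return the head-averaged attention cube
#'   (`n_queries x n_tokens x n_stimuli`).
#' @param ... unused.
#' @return Prediction matrix `n_stimuli x n_vertices`, or
#'   `list(pred, attention)` when `attention = TRUE`.
#' @export
predict.attn_readout <- function(object, tokens, attention = FALSE, ...) {
  out <- .attn_forward_cpp(tokens_to_cube(tokens), object$params,
                           object$positions$table, object$owner, attention)
  pred <- sweep(sweep(out$pred, 2, object$y_sd, "*"), 2, object$y_mean, "+")
  if (!attention) return(pred)
  list(pred = pred, attention = out$attention)
}

#' Single-stimulus forward pass with attention
#'
#' Runs one [token_grid] through a fitted (or freshly initialized)
#' transformer readout and returns both the vertex prediction and the
#' head-averaged attention distribution of every query over the tokens.
#'
#' @param model a `attn_readout`.
#' @param grid a [token_grid].
#' @param positions optional `positional_encoding` overriding the model's
#'   (must match the grid).
#' @return `list(prediction, attention)`: `prediction` is a vertex vector,
#'   `attention` an `n_queries x n_tokens` matrix (rows sum to 1, rownames =
#'   query names).
#' @export
attn_forward <- function(model, grid, positions = NULL) {
  pos <- positions %||% model$positions
  arr <- array(grid$tokens, c(1, nrow(grid$tokens), ncol(grid$tokens)))
  out <- .attn_forward_cpp(tokens_to_cube(arr), model$params, pos$table,
                           model$owner, TRUE)
  attn <- out$attention[, , 1]
  rownames(attn) <- model$query_names
  pred <- as.numeric(out$pred[1, ] * model$y_sd + model$y_mean)
  list(prediction = pred, attention = attn)
}

#' Combine per-query masked outputs into one prediction
#'
#' Exact scatter-reconstruction: the value at vertex `v` is the output of the
#' unique query whose mask contains `v`. Masks must be pairwise disjoint and
#' cover every vertex.
#'
#' @param outputs list (one per query) of full-length vertex vectors, or a
#'   `n_queries x n_vertices` matrix.
#' @param masks named list of binary masks partitioning the vertices.
#' @return numeric vector over vertices.
#' @export
mask_combine <- function(outputs, masks) {
  if (is.matrix(outputs))
    outputs <- lapply(seq_len(nrow(outputs)), function(q) outputs[q, ])
  if (length(outputs) != length(masks))
    stop("mask_combine: one output per mask required")
  owner <- mask_owner(masks)   # errors on overlap / gaps
  out <- numeric(length(owner))
  for (q in seq_along(masks)) {
    idx <- which(masks[[q]])
    out[idx] <- outputs[[q]][idx]
  }
  out
}
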