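#' Spatial-feature factorized readout
#'
#' The fixed-receptive-field comparison model: each query (ROI or vertex)
#' owns a stimulus-independent spatial map over the token grid — a softmax
#' over learned logits, so the weights are nonnegative and sum to one — which
#' pools the tokens into a single feature vector; a linear feature map then
#' predicts the query's masked vertices. Spatial and feature weights are
#' trained jointly by Adam on mean-squared error with the same masking rule
#' as the transformer readout. Because the map cannot depend on image
#' content, this family is the static-routing limit the transformer is
#' compared against.
#'
#' @param tokens `n_stimuli x n_tokens x d` training token array.
#' @param targets `n_stimuli x n_vertices` training responses.
#' @param masks named list of binary masks partitioning the vertices.
#' @param config a [train_config()].
#' @param val_tokens,val_targets held-out data for early stopping.
#' @return A `factorized_model` with `spatial_logits` (`n_queries x
#'   n_tokens`), packed feature weights, and target standardization
#'   statistics. `spatial_weights()` returns the softmaxed maps.
#' @export
fit_factorized <- function(tokens, targets, masks, config = train_config(),
                           val_tokens = NULL, val_targets = NULL) {
  owner <- mask_owner(masks)
  m <- length(masks)
  n_tok <- dim(tokens)[2]; d <- dim(tokens)[3]
  V <- ncol(targets)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  params <- list(S = matrix(stats::rnorm(m * n_tok, sd = 0.01), m, n_tok),
                 Wf = matrix(stats::rnorm(d * V, sd = 0.01), d, V),
                 bout = rep(0, V))
  .restore_seed(old)
  y_mean <- colMeans(targets)
  y_sd <- pmax(apply(targets, 2, stats::sd), 1e-8)
  Ys <- sweep(sweep(targets, 2, y_mean), 2, y_sd, "/")
  cube <- tokens_to_cube(tokens)
  grad_fn <- function(par, idx)
    .factorized_grad_cpp(cube[, , idx, drop = FALSE], Ys[idx, , drop = FALSE],
                         par$S, par$Wf, par$bout, owner)
  attr(grad_fn, "n_train") <- dim(tokens)[1]
  val_fn <- NULL
  if (!is.null(val_tokens)) {
    vcube <- tokens_to_cube(val_tokens)
    Yv <- sweep(sweep(val_targets, 2, y_mean), 2, y_sd, "/")
    val_fn <- function(par) {
      pred <- .factorized_forward_cpp(vcube, par$S, par$Wf, par$bout, owner)
      mean(colwise_pearson(pred, Yv), na.rm = TRUE)
    }
  }
  fit <- run_adam(params, grad_fn, val_fn, config, decay_on = c("S", "Wf"))
  structure(list(params = fit$params, masks = masks, owner = owner,
                 query_names = names(masks), y_mean = y_mean, y_sd = y_sd,
                 config = config, val_score = fit$val_score,
                 best_epoch = fit$best_epoch),
            class = "factorized_model")
}

#' @export
print.factorized_model <- function(x, ...) {
  cat(sprintf("<factorized_model: %d spatial maps over %d tokens, %d vertices>\n",
              nrow(x$params$S), ncol(x$params$S), length(x$owner)))
  invisible(x)
}

#' @export
predict.factorized_model <- function(object, tokens, ...) {
  pred <- .factorized_forward_cpp(tokens_to_cube(tokens), object$params$S,
                                  object$params$Wf, object$params$bout,
                                  object$owner)
  sweep(sweep(pred, 2, object$y_sd, "*"), 2, object$y_mean, "+")
}

#' Softmax-normalized spatial maps of a factorized model
#'
#' @param model a `factorized_model`.
#' @return `n_queries x n_tokens` matrix; rows are nonnegative and sum to 1.
#' @export
spatial_weights <- function(model) {
  S <- model$params$S
  out <- exp(S - apply(S, 1, max))
  out <- out / rowSums(out)
  rownames(out) <- model$query_names
  out
}
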