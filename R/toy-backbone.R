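#' Deterministic toy feature backbone
#'
#' A frozen random projection standing in for a pretrained feature extractor
#' in tests and examples: input values (an image-like array, or a latent
#' vector when `input` is a single seed-specified vector) are mapped through a
#' fixed seeded linear map plus a tanh nonlinearity into unit-scale tokens on
#' a grid. The map (weights and bias) depends only on `(input dim, grid_shape,
#' d, seed)`, so identical inputs with identical seeds give identical tokens.
#' The CLS vector is the token mean.
#'
#' @param input numeric vector/array; flattened to the backbone input.
#' @param grid_shape integer `c(rows, cols)` of the output token grid.
#' @param d output feature dimension.
#' @param seed integer seed fixing the frozen weights.
#' @param stimulus_id character scalar.
#' @return A [token_grid].
#' @export
toy_backbone <- function(input, grid_shape, d, seed = 1L, stimulus_id = "") {
  x <- as.numeric(input)
  n_tokens <- prod(grid_shape)
  map <- .toy_backbone_map(length(x), n_tokens, d, seed)
  tok <- tanh(as.numeric(x %*% map$W) + map$b)
  tokens <- matrix(tok, n_tokens, d)
  token_grid(tokens, grid_shape = grid_shape, cls = colMeans(tokens),
             stimulus_id = stimulus_id)
}

# Frozen-map cache: the weights are a deterministic function of the key, so
# caching only avoids regenerating them per stimulus.
.toy_cache <- new.env(parent = emptyenv())
.toy_backbone_map <- function(n_in, n_tokens, d, seed) {
  key <- sprintf("%d_%d_%d_%d", n_in, n_tokens, d, seed)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  map <- list(
    W = matrix(stats::rnorm(n_in * n_tokens * d, sd = 1 / sqrt(n_in)),
               n_in, n_tokens * d),
    b = stats::rnorm(n_tokens * d, sd = 0.5))
  .toy_cache[[key]] <- map
  map
}
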