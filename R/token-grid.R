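#' Per-stimulus token grid
#'
#' A `token_grid` holds the frozen-backbone representation of one stimulus: a
#' matrix of token feature vectors, optionally arranged on a 2-D spatial grid
#' (row-major, row 1 = top of image, column 1 = left), plus an optional CLS
#' summary vector. Token sequences without a spatial layout (e.g. text
#' captions) carry `grid_shape = NULL` and are positioned by token index.
#'
#' @param tokens numeric matrix, `n_tokens x d`; all entries finite.
#' @param grid_shape integer vector `c(rows, cols)` with
#'   `rows * cols == nrow(tokens)`, or `NULL` for non-spatial sequences.
#' @param cls optional numeric vector of length `d`: the backbone's global
#'   summary token.
#' @param stimulus_id character scalar identifying the stimulus.
#' @return An object of class `token_grid`.
#' @examples
#' tg <- token_grid(matrix(rnorm(16 * 8), 16, 8), grid_shape = c(4, 4),
#'                  stimulus_id = "s1")
#' tg$grid_shape
#' @export
token_grid <- function(tokens, grid_shape = NULL, cls = NULL, stimulus_id = "") {
  tokens <- as.matrix(tokens)
  storage.mode(tokens) <- "double"
  if (nrow(tokens) < 1L) stop("token_grid: need at least one token")
  if (!all(is.finite(tokens))) stop("token_grid: non-finite token entries")
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 2L || any(grid_shape < 1L))
      stop("token_grid: grid_shape must be two positive integers")
    if (prod(grid_shape) != nrow(tokens))
      stop(sprintf("token_grid: grid_shape %dx%d does not match %d tokens",
                   grid_shape[1], grid_shape[2], nrow(tokens)))
  }
  if (!is.null(cls)) {
    cls <- as.numeric(cls)
    if (length(cls) != ncol(tokens))
      stop("token_grid: cls length must equal feature dim")
    if (!all(is.finite(cls))) stop("token_grid: non-finite cls entries")
  }
  structure(list(tokens = tokens, grid_shape = grid_shape, cls = cls,
                 stimulus_id = as.character(stimulus_id)),
            class = "token_grid")
}

#' @export
print.token_grid <- function(x, ...) {
  shape <- if (is.null(x$grid_shape)) "sequence"
           else sprintf("%dx%d grid", x$grid_shape[1], x$grid_shape[2])
  cat(sprintf("<token_grid '%s': %d tokens (%s), d = %d%s>\n",
              x$stimulus_id, nrow(x$tokens), shape, ncol(x$tokens),
              if (is.null(x$cls)) "" else ", CLS"))
  invisible(x)
}

#' Unroll a convolutional feature map into a token grid
#'
#' Reshapes a `channels x rows x cols` feature map (e.g. the last layer of a
#' convolutional backbone) into tokens by row-major spatial unrolling: token 1
#' is cell (1,1), token 2 is cell (1,2), and so on. The feature dimension is
#' the channel axis. No CLS vector is produced.
#'
#' @param feature_map numeric array `channels x rows x cols`.
#' @param stimulus_id character scalar.
#' @return A [token_grid] with `rows * cols` tokens of dimension `channels`.
#' @export
reshape_feature_map <- function(feature_map, stimulus_id = "") {
  if (length(dim(feature_map)) != 3L)
    stop("reshape_feature_map: expected a channels x rows x cols array")
  d <- dim(feature_map)
  tokens <- matrix(0, d[2] * d[3], d[1])
  k <- 0L
  for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    k <- k + 1L
    tokens[k, ] <- feature_map[, r, cc]
  }
  token_grid(tokens, grid_shape = c(d[2], d[3]), stimulus_id = stimulus_id)
}

#' Stack a list of token grids into an array
#'
#' Converts a list of [token_grid] objects sharing `n_tokens` and feature
#' dimension into an `n_stimuli x n_tokens x d` array, the layout consumed by
#' the fitting routines. Stimulus order is the list order.
#'
#' @param grids list of [token_grid] objects.
#' @return numeric array with `dimnames[[1]]` set to the stimulus ids.
#' @export
grids_to_array <- function(grids) {
  stopifnot(length(grids) >= 1L)
  n <- nrow(grids[[1]]$tokens); d <- ncol(grids[[1]]$tokens)
  for (g in grids)
    if (nrow(g$tokens) != n || ncol(g$tokens) != d)
      stop("grids_to_array: inconsistent token dimensions across stimuli")
  arr <- array(0, c(length(grids), n, d))
  for (i in seq_along(grids)) arr[i, , ] <- grids[[i]]$tokens
  dimnames(arr) <- list(vapply(grids, function(g) g$stimulus_id, ""), NULL, NULL)
  arr
}

#' Extract the CLS vectors of a list of token grids
#'
#' @param grids list of [token_grid] objects, each carrying a CLS vector.
#' @return numeric matrix `n_stimuli x d`, rownames = stimulus ids.
#' @export
grids_to_cls <- function(grids) {
  if (any(vapply(grids, function(g) is.null(g$cls), TRUE)))
    stop("grids_to_cls: some grids have no CLS vector")
  out <- t(vapply(grids, function(g) g$cls, numeric(ncol(grids[[1]]$tokens))))
  rownames(out) <- vapply(grids, function(g) g$stimulus_id, "")
  out
}
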