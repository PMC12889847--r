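#' Fixed sinusoidal positional encodings
#'
#' Deterministic 2-D positional codes added to the token features to form the
#' attention keys, so a query can select tokens by grid location as well as by
#' content. Half of the channels encode the row index and half the column
#' index, each with a sine/cosine geometric frequency ladder whose
#' wavelengths run from 2 grid cells (the Nyquist wavelength, so queries can
#' synthesize receptive fields down to single-cell width) up to twice the
#' axis extent, sin/cos interleaved. Every entry lies in `[-1, 1]` and
#' distinct grid cells receive distinct code rows.
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param d encoding dimension; must be divisible by 4.
#' @return An object of class `positional_encoding`: `table` is an
#'   `n_tokens x d` matrix in row-major grid order, plus `grid_shape`.
#' @examples
#' pe <- sinusoidal_positions(c(4, 4), 16)
#' range(pe$table)
#' @export
sinusoidal_positions <- function(grid_shape, d) {
  grid_shape <- as.integer(grid_shape)
  if (d %% 4L != 0L)
    stop("sinusoidal_positions: d must be divisible by 4")
  rows <- grid_shape[1]; cols <- grid_shape[2]
  half <- d %/% 2L
  ridx <- rep(seq_len(rows) - 1L, each = cols)
  cidx <- rep(seq_len(cols) - 1L, times = rows)
  tab <- cbind(.sin_ladder(ridx, half), .sin_ladder(cidx, half))
  structure(list(table = tab, grid_shape = grid_shape),
            class = "positional_encoding")
}

# 1-D sin/cos ladder: n_channels must be even; channels interleave
# sin(p * w_k), cos(p * w_k). Wavelengths run geometrically from 2 cells
# (Nyquist, so single-cell structure is resolvable) up to twice the axis
# extent, so the code spans sharp and broad spatial scales on any grid.
.sin_ladder <- function(pos, n_channels, extent = max(pos) + 1) {
  n_freq <- n_channels %/% 2L
  lambda <- if (n_freq == 1L) 2 else
    2 * max(extent, 2) ^ ((seq_len(n_freq) - 1L) / (n_freq - 1L))
  w <- 2 * pi / lambda
  out <- matrix(0, length(pos), n_channels)
  for (k in seq_len(n_freq)) {
    out[, 2L * k - 1L] <- sin(pos * w[k])
    out[, 2L * k] <- cos(pos * w[k])
  }
  out
}

#' Sequence (1-D) positional encodings
#'
#' For token sequences without a spatial grid (e.g. text-caption backbones)
#' positions are encoded over the token index with the same sine/cosine
#' ladder, using all `d` channels.
#'
#' @param n_tokens sequence length.
#' @param d encoding dimension; must be even.
#' @return A `positional_encoding` with `grid_shape = NULL`.
#' @export
sequence_positions <- function(n_tokens, d) {
  if (d %% 2L != 0L) stop("sequence_positions: d must be even")
  tab <- .sin_ladder(seq_len(n_tokens) - 1L, d)
  structure(list(table = tab, grid_shape = NULL),
            class = "positional_encoding")
}

#' Positional encoding matched to a token grid
#'
#' Dispatches to [sinusoidal_positions()] for spatial grids and
#' [sequence_positions()] for grid-free sequences.
#'
#' @param grid a [token_grid] (only its shape is used).
#' @param d encoding dimension.
#' @return A `positional_encoding`.
#' @export
positions_for <- function(grid, d = ncol(grid$tokens)) {
  if (is.null(grid$grid_shape)) sequence_positions(nrow(grid$tokens), d)
  else sinusoidal_positions(grid$grid_shape, d)
}
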