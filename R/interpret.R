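#' Attention record of one (stimulus, query) pair
#'
#' A head-averaged cross-attention distribution over the tokens of one
#' stimulus for one query: nonnegative weights summing to one, reshaped to
#' the grid row-major when a grid shape is present.
#'
#' @param weights nonnegative numeric vector over tokens, summing to 1.
#' @param stimulus_id,query_name identifiers.
#' @param grid_shape optional `c(rows, cols)`.
#' @return An object of class `attention_record`.
#' @export
attention_record <- function(weights, stimulus_id, query_name,
                             grid_shape = NULL) {
  weights <- as.numeric(weights)
  if (any(weights < -1e-12)) stop("attention_record: negative weights")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("attention_record: weights must sum to 1")
  if (!is.null(grid_shape) && prod(grid_shape) != length(weights))
    stop("attention_record: grid_shape does not match weight length")
  structure(list(weights = pmax(weights, 0), stimulus_id = stimulus_id,
                 query_name = query_name, grid_shape = grid_shape),
            class = "attention_record")
}

#' @export
print.attention_record <- function(x, ...) {
  cat(sprintf("<attention_record: query '%s' on '%s', %d tokens, peak %.3f>\n",
              x$query_name, x$stimulus_id, length(x$weights), max(x$weights)))
  invisible(x)
}

#' @export
as.matrix.attention_record <- function(x, ...) {
  if (is.null(x$grid_shape)) return(matrix(x$weights, nrow = 1))
  matrix(x$weights, x$grid_shape[1], x$grid_shape[2], byrow = TRUE)
}

#' Extract the attention map of a named query
#'
#' Runs the transformer readout forward on one stimulus and returns the
#' head-averaged attention row of the named query — identical to the
#' distribution used inside the forward pass.
#'
#' @param model a fitted `attn_readout`.
#' @param grid a [token_grid].
#' @param query_name one of `model$query_names`.
#' @return An [attention_record].
#' @export
attention_map <- function(model, grid, query_name) {
  q <- match(query_name, model$query_names)
  if (is.na(q))
    stop(sprintf("attention_map: unknown query '%s' (available: %s)",
                 query_name, paste(model$query_names, collapse = ", ")))
  fw <- attn_forward(model, grid)
  attention_record(fw$attention[q, ], grid$stimulus_id, query_name,
                   grid$grid_shape)
}

#' Attention mass on a category, against chance
#'
#' Quantifies the category selectivity of a set of attention maps: over the
#' stimuli that contain category `category`, the mean attention mass falling
#' on that category's tokens. Chance level — the mass a uniform map would
#' collect, i.e. the mean fraction of tokens carrying the category — is
#' reported alongside.
#'
#' @param records list of [attention_record]s.
#' @param token_category `n_stimuli x n_tokens` label matrix with rownames
#'   (or list order) aligned to the records' stimulus ids.
#' @param category category index to score.
#' @param stimulus_ids ids of the label-matrix rows; default
#'   `rownames(token_category)` or record order.
#' @return `list(score, chance, n_stimuli)`.
#' @export
selectivity_score <- function(records, token_category, category,
                              stimulus_ids = NULL) {
  ids <- stimulus_ids %||% rownames(token_category)
  mass <- c(); frac <- c()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    row <- if (is.null(ids)) i else match(rec$stimulus_id, ids)
    if (is.na(row)) next
    lab <- token_category[row, ]
    if (!any(lab == category)) next
    mass <- c(mass, sum(rec$weights[lab == category]))
    frac <- c(frac, mean(lab == category))
  }
  if (!length(mass))
    stop("selectivity_score: no scored stimulus contains the category")
  list(score = mean(mass), chance = mean(frac), n_stimuli = length(mass))
}

#' Export an attention map as a heat-map overlay PNG
#'
#' Upsamples the attention grid to the stimulus resolution (nearest or
#' bilinear), maps it to a fixed linear color scale from 0 to the map
#' maximum, and alpha-blends it over the image (a grayscale sketch is
#' generated when none is supplied).
#'
#' @param record an [attention_record] with a grid shape.
#' @param path output PNG path.
#' @param image optional grayscale matrix or RGB array in `[0, 1]` at the
#'   target resolution.
#' @param upscale integer target pixels per grid cell when no image is given.
#' @param method `"bilinear"` or `"nearest"` upsampling.
#' @param alpha overlay opacity in `[0, 1]`.
#' @return invisibly, `path`.
#' @export
export_overlay <- function(record, path, image = NULL, upscale = 16L,
                           method = c("bilinear", "nearest"), alpha = 0.6) {
  method <- match.arg(method)
  if (is.null(record$grid_shape))
    stop("export_overlay: record has no spatial grid")
  amap <- as.matrix(record)
  if (is.null(image)) {
    image <- matrix(0.35, record$grid_shape[1] * upscale,
                    record$grid_shape[2] * upscale)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  up <- .upsample(amap, h, w, method)
  peak <- max(up)
  heat <- if (peak > 0) up / peak else up
  if (length(dim(image)) == 2)
    image <- array(rep(image, 3), c(h, w, 3))
  # fixed linear scale: black -> red -> yellow
  overlay <- array(0, c(h, w, 3))
  overlay[, , 1] <- pmin(1, 2 * heat)
  overlay[, , 2] <- pmax(0, 2 * heat - 1)
  out <- (1 - alpha) * image + alpha * overlay
  png::writePNG(pmin(pmax(out, 0), 1), path)
  invisible(path)
}

.upsample <- function(m, h, w, method) {
  r_src <- nrow(m); c_src <- ncol(m)
  rr <- (seq_len(h) - 0.5) / h * r_src + 0.5
  cc <- (seq_len(w) - 0.5) / w * c_src + 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(rr - 0.5 + 0.5), 1), r_src)
    ci <- pmin(pmax(round(cc - 0.5 + 0.5), 1), c_src)
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(0, h, w)
  rlo <- pmin(pmax(floor(rr - 0.5), 0), r_src - 1); rfr <- rr - 0.5 - rlo
  clo <- pmin(pmax(floor(cc - 0.5), 0), c_src - 1); cfr <- cc - 0.5 - clo
  rhi <- pmin(rlo + 1, r_src - 1); chi <- pmin(clo + 1, c_src - 1)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    fr <- rfr[i]; fc <- cfr[j]
    out[i, j] <-
      m[rlo[i] + 1, clo[j] + 1] * (1 - fr) * (1 - fc) +
      m[rhi[i] + 1, clo[j] + 1] * fr * (1 - fc) +
      m[rlo[i] + 1, chi[j] + 1] * (1 - fr) * fc +
      m[rhi[i] + 1, chi[j] + 1] * fr * fc
  }
  out
}
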