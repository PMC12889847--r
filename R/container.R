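#' Save / load an encoding-study container
#'
#' A container bundles everything one encoding study needs: per-stimulus
#' token grids (plus optional CLS vectors and grid shape), the repeat-level
#' response array with stimulus ids and split labels, the ROI atlas, and
#' optionally the synthetic ground truth that generated the responses. The
#' on-disk representation is a single R serialization file with a fixed
#' logical layout (`tokens/<stimulus_id>`, `cls/<stimulus_id>`,
#' `responses/repeats`, `responses/stimulus_ids`, `split`, `atlas`, `truth`);
#' loading re-validates every object and re-aligns responses to token order by
#' `stimulus_id`, never by array position.
#'
#' @param grids list of [token_grid] objects.
#' @param rset a [response_set] covering the same stimulus ids.
#' @param atlas an [roi_atlas] with one entry per response vertex.
#' @param path destination file path.
#' @param truth optional ground-truth object from the synthetic generator.
#' @return `save_container` invisibly returns `path`; `load_container`
#'   returns `list(grids, response_set, atlas, truth)`.
#' @export
save_container <- function(grids, rset, atlas, path, truth = NULL) {
  ids <- vapply(grids, function(g) g$stimulus_id, "")
  .check_alignment(ids, rset$stimulus_id)
  if (length(atlas$vertex_id) != dim(rset$repeats)[3])
    stop("save_container: atlas size does not match response vertices")
  obj <- list(
    format = "brainattn-container-v1",
    grid_shape = grids[[1]]$grid_shape,
    feature_dim = ncol(grids[[1]]$tokens),
    tokens = stats::setNames(lapply(grids, `[[`, "tokens"), ids),
    cls = if (!is.null(grids[[1]]$cls))
      stats::setNames(lapply(grids, `[[`, "cls"), ids),
    responses = list(repeats = rset$repeats,
                     stimulus_ids = rset$stimulus_id,
                     noise_ceiling = rset$noise_ceiling),
    split = rset$split,
    atlas = list(vertex_id = atlas$vertex_id, hemisphere = atlas$hemisphere,
                 roi_label = atlas$roi_label),
    truth = truth)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_container: no such file '%s'", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "brainattn-container-v1"))
    stop("load_container: not a brainattn container")
  for (ds in c("tokens", "responses", "split", "atlas"))
    if (is.null(obj[[ds]]))
      stop(sprintf("load_container: missing required dataset '%s'", ds))
  for (ds in c("repeats", "stimulus_ids"))
    if (is.null(obj$responses[[ds]]))
      stop(sprintf("load_container: missing required dataset 'responses/%s'", ds))
  ids <- names(obj$tokens)
  d <- obj$feature_dim
  grids <- lapply(ids, function(id) {
    tk <- obj$tokens[[id]]
    if (ncol(tk) != d)
      stop(sprintf("load_container: feature dim of '%s' (%d) != container dim (%d)",
                   id, ncol(tk), d))
    token_grid(tk, grid_shape = obj$grid_shape, cls = obj$cls[[id]],
               stimulus_id = id)
  })
  .check_alignment(ids, obj$responses$stimulus_ids)
  ord <- match(ids, obj$responses$stimulus_ids)
  rset <- response_set(obj$responses$repeats[ord, , , drop = FALSE],
                       stimulus_id = ids, split = obj$split[ord],
                       noise_ceiling = obj$responses$noise_ceiling)
  atlas <- roi_atlas(obj$atlas$vertex_id, obj$atlas$hemisphere,
                     obj$atlas$roi_label)
  if (length(atlas$vertex_id) != dim(rset$repeats)[3])
    stop("load_container: atlas size does not match response vertices")
  list(grids = grids, response_set = rset, atlas = atlas, truth = obj$truth)
}

.check_alignment <- function(token_ids, response_ids) {
  if (length(token_ids) != length(response_ids) ||
      !setequal(token_ids, response_ids)) {
    bad <- c(setdiff(response_ids, token_ids), setdiff(token_ids, response_ids))
    stop(sprintf(
      "container: stimulus ids of tokens and responses differ (first mismatch: '%s')",
      bad[1]))
  }
}
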