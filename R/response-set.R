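#' Repeat-level brain responses with train/test split
#'
#' Holds the measured responses of `n_vertices` vertices to `n_stimuli`
#' stimuli over `n_repeats` presentations. Missing repeats are `NA`; the
#' repeat-averaged matrix (the regression target) is the mean over available
#' repeats per (stimulus, vertex). Each stimulus belongs to either the train
#' or the test split.
#'
#' @param repeats numeric array `n_stimuli x n_repeats x n_vertices`; `NA`
#'   marks a missing repeat (a stimulus must have at least one available
#'   repeat at every vertex).
#' @param stimulus_id character vector of length `n_stimuli`.
#' @param split character vector in `{"train","test"}` per stimulus.
#' @param noise_ceiling optional per-vertex noise ceiling in `[0, 1]`; usually
#'   filled in later by [estimate_noise_ceiling()].
#' @return An object of class `response_set` with the fields above plus
#'   `averaged` (`n_stimuli x n_vertices`).
#' @export
response_set <- function(repeats, stimulus_id, split, noise_ceiling = NULL) {
  if (length(dim(repeats)) != 3L)
    stop("response_set: repeats must be a 3-d array (stimuli x repeats x vertices)")
  ns <- dim(repeats)[1]
  stimulus_id <- as.character(stimulus_id)
  split <- as.character(split)
  if (length(stimulus_id) != ns || length(split) != ns)
    stop("response_set: stimulus_id/split length must match stimuli")
  if (anyDuplicated(stimulus_id)) stop("response_set: duplicate stimulus ids")
  if (!all(split %in% c("train", "test")))
    stop("response_set: split labels must be 'train' or 'test'")
  avail <- apply(!is.na(repeats), c(1, 3), sum)
  if (any(avail == 0L))
    stop("response_set: every stimulus needs >= 1 available repeat per vertex")
  averaged <- apply(repeats, c(1, 3), mean, na.rm = TRUE)
  if (!is.null(noise_ceiling)) {
    noise_ceiling <- as.numeric(noise_ceiling)
    if (length(noise_ceiling) != dim(repeats)[3])
      stop("response_set: noise_ceiling length must equal n_vertices")
  }
  rownames(averaged) <- stimulus_id
  structure(list(repeats = repeats, averaged = averaged,
                 stimulus_id = stimulus_id, split = split,
                 noise_ceiling = noise_ceiling),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf(
    "<response_set: %d stimuli (%d train / %d test), %d repeats, %d vertices%s>\n",
    dim(x$repeats)[1], sum(x$split == "train"), sum(x$split == "test"),
    dim(x$repeats)[2], dim(x$repeats)[3],
    if (is.null(x$noise_ceiling)) "" else ", NC estimated"))
  invisible(x)
}

#' Assign train stimuli to cross-validation folds
#'
#' Uniform random assignment by stimulus with a stored seed; fold sizes differ
#' by at most one. Test stimuli are never assigned to a fold.
#'
#' @param rset a [response_set].
#' @param n_folds number of folds (default 10).
#' @param seed integer RNG seed; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: `n_folds`, `seed`, and `fold_of`, a
#'   named integer vector over train stimuli.
#' @export
make_folds <- function(rset, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("make_folds: n_folds must be >= 2")
  train_ids <- rset$stimulus_id[rset$split == "train"]
  n <- length(train_ids)
  if (n < n_folds) stop("make_folds: fewer train stimuli than folds")
  base <- rep(seq_len(n_folds), length.out = n)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  fold_of <- sample(base)
  names(fold_of) <- train_ids
  structure(list(n_folds = n_folds, fold_of = fold_of, seed = as.integer(seed)),
            class = "fold_plan")
}

# Save/restore the global RNG state so seeded helpers do not clobber it.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d folds over %d train stimuli (seed %d)>\n",
              x$n_folds, length(x$fold_of), x$seed))
  invisible(x)
}
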