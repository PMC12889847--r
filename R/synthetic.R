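#' Synthetic visual cortex with known routing ground truth
#'
#' The synthetic generator emulates, at desk scale, the two routing regimes
#' the encoding models are meant to dissociate:
#'
#' * **Early (retinotopic) vertices** have a small fixed spatial receptive
#'   field over the token grid — a Gaussian blob restricted to the
#'   contralateral half of the visual field (LH vertices see the right half,
#'   RH the left), with ventral/dorsal ROIs pinned to the upper/lower rows.
#'   Their clean response is a linear readout of the RF-weighted token sum, so
#'   a stimulus-independent spatial map is the correct model class.
#' * **Category vertices** (face/body/place-like ROIs) respond through
#'   content-gated pooling: tokens whose feature vector projects onto the
#'   ROI's preferred direction above a gate threshold are pooled with weights
#'   proportional to their (renormalized) similarity, wherever they sit on the
#'   grid. No fixed spatial map can capture this; a content-sensitive router
#'   can.
#'
#' Stimuli are token grids with 0–3 rectangular "objects" (contiguous token
#' patches carrying a category direction at random amplitude plus unit
#' isotropic noise) over an isotropic background scaled by `clutter`. Each
#' vertex receives i.i.d. Gaussian trial noise; with the default calibration
#' the noise sd equals the clean-signal sd, giving a noise ceiling of 0.75 for
#' three averaged repeats.
#'
#' @name synthetic_brain
NULL

#' Simulate backbone token grids with planted objects
#'
#' @param n_stimuli number of stimuli.
#' @param grid_shape integer `c(rows, cols)`; must admit a 2x2 object.
#' @param d token feature dimension; must be at least `n_categories + 2`.
#' @param n_categories number of object categories.
#' @param clutter background token scale in `[0, 1]`.
#' @param seed integer seed; output is bit-identical across runs for a seed.
#' @param directions optional `d x n_categories` matrix of unit category
#'   directions; defaults to a seeded random orthonormal set.
#' @param amplitude_range range of the object amplitude (uniform per object).
#' @param max_objects maximum number of objects per stimulus (uniform 0..max).
#' @return `list(grids, token_category, directions)`: `grids` is a list of
#'   [token_grid]; `token_category` an `n_stimuli x n_tokens` integer matrix
#'   (0 = background); `directions` the category directions used.
#' @export
simulate_stimuli <- function(n_stimuli, grid_shape = c(8, 8), d = 32,
                             n_categories = 3, clutter = 0.5, seed = 1L,
                             directions = NULL,
                             amplitude_range = c(2, 4), max_objects = 3L) {
  grid_shape <- as.integer(grid_shape)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (rows < 2L || cols < 2L)
    stop("simulate_stimuli: grid too small to place an object")
  if (d < n_categories + 2)
    stop("simulate_stimuli: d must be >= n_categories + 2")
  if (clutter < 0 || clutter > 1)
    stop("simulate_stimuli: clutter must be in [0, 1]")
  n_tok <- rows * cols
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  if (is.null(directions)) directions <- .random_directions(d, n_categories)
  grids <- vector("list", n_stimuli)
  token_category <- matrix(0L, n_stimuli, n_tok)
  for (s in seq_len(n_stimuli)) {
    X <- matrix(stats::rnorm(n_tok * d, sd = clutter), n_tok, d)
    lab <- integer(n_tok)
    n_obj <- sample(0:max_objects, 1L)
    for (o in seq_len(n_obj)) {
      cat_o <- sample.int(n_categories, 1L)
      h <- sample(2:min(3L, rows), 1L); w <- sample(2:min(3L, cols), 1L)
      r0 <- sample.int(rows - h + 1L, 1L); c0 <- sample.int(cols - w + 1L, 1L)
      amp <- stats::runif(1, amplitude_range[1], amplitude_range[2])
      cells <- as.vector(outer((r0:(r0 + h - 1L) - 1L) * cols,
                               c0:(c0 + w - 1L), `+`))
      X[cells, ] <- amp * matrix(directions[, cat_o], length(cells), d,
                                 byrow = TRUE) +
        matrix(stats::rnorm(length(cells) * d), length(cells), d)
      lab[cells] <- cat_o
    }
    token_category[s, ] <- lab
    grids[[s]] <- token_grid(X, grid_shape = grid_shape, cls = colMeans(X),
                             stimulus_id = sprintf("stim_%05d", s))
  }
  list(grids = grids, token_category = token_category, directions = directions)
}

.random_directions <- function(d, k) {
  qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))[, seq_len(k), drop = FALSE]
}

#' Synthetic ROI atlas
#'
#' Builds an atlas over both hemispheres using the NSD ROI vocabulary: early
#' retinotopic ROIs (`early_rois`) and category-selective ROIs
#' (`category_rois`, assigned to object categories 1, 2, ... in order).
#'
#' @param n_early vertices per early ROI per hemisphere.
#' @param n_category vertices per category ROI per hemisphere.
#' @param early_rois,category_rois ROI label vectors.
#' @return An [roi_atlas]; vertex ids are consecutive from 0.
#' @export
synthetic_atlas <- function(n_early = 12L, n_category = 8L,
                            early_rois = c("V1v", "V2d"),
                            category_rois = c("FFA-1", "EBA", "PPA")) {
  hemi <- c(); roi <- c()
  for (h in c("LH", "RH")) {
    hemi <- c(hemi, rep(h, n_early * length(early_rois) +
                           n_category * length(category_rois)))
    roi <- c(roi, rep(early_rois, each = n_early),
             rep(category_rois, each = n_category))
  }
  roi_atlas(seq_along(hemi) - 1L, hemi, roi)
}

#' Ground-truth routing parameters for a synthetic atlas
#'
#' @param atlas an [roi_atlas] whose early ROIs are in the `"early"` cluster
#'   of [nsd_roi_clusters()] and whose remaining ROIs map to object
#'   categories.
#' @param grid_shape token grid shape.
#' @param d feature dimension.
#' @param directions `d x n_categories` unit category directions (from
#'   [simulate_stimuli()]).
#' @param seed integer seed.
#' @param gate_threshold minimum token-direction similarity for a token to
#'   count as category content (default 1.5, half the mean object amplitude).
#' @param rf_sigma Gaussian RF width in grid cells.
#' @param category_map named vector mapping category ROI labels to category
#'   indices; defaults to order of appearance.
#' @return An object of class `ground_truth`: `rf_map` (`n_vertices x
#'   n_tokens`, rows of category vertices zero; early rows nonnegative,
#'   sum 1, supported on the contralateral half-grid), `readout_weights`
#'   (`n_vertices x d`), `vertex_category` (0 = early/fixed-RF),
#'   `category_directions`, `gate_threshold`, `noise_sd` (filled by
#'   [simulate_encoding_study()] once the clean-signal scale is known),
#'   `grid_shape`, `seed`.
#' @export
make_ground_truth <- function(atlas, grid_shape, d, directions, seed = 1L,
                              gate_threshold = 1.5, rf_sigma = 0.8,
                              category_map = NULL) {
  grid_shape <- as.integer(grid_shape)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  n_tok <- rows * cols
  V <- length(atlas$vertex_id)
  clusters <- nsd_roi_clusters()
  is_early <- clusters[atlas$roi_label] == "early"
  is_early[is.na(is_early)] <- FALSE
  cat_rois <- unique(atlas$roi_label[!is_early])
  if (is.null(category_map))
    category_map <- stats::setNames(seq_along(cat_rois), cat_rois)
  if (max(category_map) > ncol(directions))
    stop("make_ground_truth: more category ROIs than category directions")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  rf_map <- matrix(0, V, n_tok)
  vertex_category <- integer(V)
  rr <- rep(seq_len(rows), each = cols)   # row-major cell coordinates
  cc <- rep(seq_len(cols), times = rows)
  for (v in seq_len(V)) {
    if (is_early[v]) {
      colsel <- if (atlas$hemisphere[v] == "LH")
        (cols %/% 2 + 1):cols else 1:(cols %/% 2)
      rowsel <- if (grepl("v$", atlas$roi_label[v]))
        1:(rows %/% 2) else (rows %/% 2 + 1):rows
      cr <- stats::runif(1, min(rowsel) - 0.5, max(rowsel) + 0.5)
      ccen <- stats::runif(1, min(colsel) - 0.5, max(colsel) + 0.5)
      w <- exp(-((rr - cr)^2 + (cc - ccen)^2) / (2 * rf_sigma^2))
      w[!(cc %in% colsel)] <- 0     # contralateral half-field support
      rf_map[v, ] <- w / sum(w)
    } else {
      vertex_category[v] <- category_map[[atlas$roi_label[v]]]
    }
  }
  structure(list(rf_map = rf_map,
                 readout_weights = matrix(stats::rnorm(V * d), V, d),
                 vertex_category = vertex_category,
                 category_directions = directions,
                 gate_threshold = gate_threshold,
                 noise_sd = NULL, grid_shape = grid_shape,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Ground-truth gating weights of a category
#'
#' The renormalized positive above-threshold similarities that pool tokens
#' for category-`category` vertices — the synthetic analogue of an attention
#' map, used as the recovery target in interpretation tests.
#'
#' @param truth a `ground_truth`.
#' @param grids list of [token_grid].
#' @param category category index.
#' @return `n_stimuli x n_tokens` matrix; rows are zero when no token passes
#'   the gate.
#' @export
gating_weights <- function(truth, grids, category) {
  dir_c <- truth$category_directions[, category]
  out <- matrix(0, length(grids), nrow(grids[[1]]$tokens))
  for (s in seq_along(grids)) {
    sims <- as.numeric(grids[[s]]$tokens %*% dir_c)
    pass <- sims > truth$gate_threshold
    if (any(pass)) out[s, pass] <- sims[pass] / sum(sims[pass])
  }
  out
}

#' Clean (noise-free) responses implied by the ground truth
#'
#' @inheritParams gating_weights
#' @return `n_stimuli x n_vertices` matrix.
#' @export
clean_responses <- function(truth, grids) {
  V <- nrow(truth$readout_weights)
  S <- length(grids)
  early <- which(truth$vertex_category == 0L)
  cats <- sort(unique(truth$vertex_category[truth$vertex_category > 0L]))
  clean <- matrix(0, S, V)
  RF <- truth$rf_map[early, , drop = FALSE]
  W_early <- truth$readout_weights[early, , drop = FALSE]
  for (s in seq_len(S)) {
    X <- grids[[s]]$tokens
    if (length(early))
      clean[s, early] <- rowSums((RF %*% X) * W_early)
    for (ct in cats) {
      vs <- which(truth$vertex_category == ct)
      sims <- as.numeric(X %*% truth$category_directions[, ct])
      pass <- sims > truth$gate_threshold
      if (any(pass)) {
        g <- sims[pass] / sum(sims[pass])
        pooled <- as.numeric(g %*% X[pass, , drop = FALSE])
        clean[s, vs] <- as.numeric(
          truth$readout_weights[vs, , drop = FALSE] %*% pooled)
      }                                   # else baseline 0
    }
  }
  clean
}

#' Simulate repeat-level responses from ground truth
#'
#' Each repeat is the clean response plus i.i.d. Gaussian noise with per-
#' vertex sd `truth$noise_sd` (which must be set; see
#' [simulate_encoding_study()] for the signal-calibrated default).
#'
#' @inheritParams gating_weights
#' @param n_repeats repeats per stimulus.
#' @param split per-stimulus `"train"`/`"test"` labels; default holds out the
#'   last `test_fraction` of stimuli (stimuli are i.i.d.).
#' @param test_fraction used when `split` is `NULL`.
#' @param seed integer seed for the trial noise.
#' @return A [response_set].
#' @export
simulate_responses <- function(grids, truth, n_repeats = 3L, split = NULL,
                               test_fraction = 0.15, seed = 1L) {
  if (is.null(truth$noise_sd))
    stop("simulate_responses: truth$noise_sd not set; calibrate it first")
  clean <- clean_responses(truth, grids)
  S <- nrow(clean); V <- ncol(clean)
  if (is.null(split))
    split <- c(rep("train", S - round(S * test_fraction)),
               rep("test", round(S * test_fraction)))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  reps <- array(0, c(S, n_repeats, V))
  for (r in seq_len(n_repeats))
    reps[, r, ] <- clean +
      matrix(stats::rnorm(S * V), S, V) %*% diag(truth$noise_sd, V)
  response_set(reps, stimulus_id = vapply(grids, `[[`, "", "stimulus_id"),
               split = split)
}

#' Upper bound on attainable encoding accuracy
#'
#' Scores the true clean signal as a predictor of the measured test
#' responses with the same metric as the model evaluation (squared Pearson
#' over the test split, divided by the estimated noise ceiling). No encoder
#' can systematically exceed this per-vertex ceiling.
#'
#' @inheritParams gating_weights
#' @param rset the [response_set] generated from `truth` on `grids`.
#' @return per-vertex numeric vector of oracle accuracies.
#' @export
oracle_accuracy <- function(truth, rset, grids) {
  clean <- clean_responses(truth, grids)
  if (nrow(clean) != dim(rset$repeats)[1] ||
      ncol(clean) != dim(rset$repeats)[3])
    stop("oracle_accuracy: truth/response shapes do not match")
  nc <- if (is.null(rset$noise_ceiling))
    estimate_noise_ceiling(rset, n_averaged_repeats = dim(rset$repeats)[2])
  else rset$noise_ceiling
  test <- rset$split == "test"
  acc <- encoding_accuracy(clean[test, , drop = FALSE],
                           rset$averaged[test, , drop = FALSE], nc)
  acc$accuracy
}

#' One-call synthetic encoding study
#'
#' Generates stimuli, atlas, ground truth and responses under the package's
#' reference conditions: trial noise sd calibrated to `noise_scale` times the
#' clean-signal sd per vertex (floored at 1e-6 for degenerate vertices).
#'
#' @inheritParams simulate_stimuli
#' @inheritParams simulate_responses
#' @param n_early,n_category atlas sizes per ROI per hemisphere.
#' @param noise_scale trial-noise sd as a multiple of the clean-signal sd.
#' @param gate_threshold content-gate threshold.
#' @return `list(grids, tokens, token_category, atlas, truth, response_set)`
#'   where `tokens` is the stacked `n_stimuli x n_tokens x d` array.
#' @export
simulate_encoding_study <- function(n_stimuli = 2000L, grid_shape = c(8, 8),
                                    d = 32L, n_categories = 3L, clutter = 0.5,
                                    n_repeats = 3L, test_fraction = 0.15,
                                    n_early = 12L, n_category = 8L,
                                    noise_scale = 1, gate_threshold = 1.5,
                                    seed = 1L) {
  stim <- simulate_stimuli(n_stimuli, grid_shape, d, n_categories, clutter,
                           seed = seed)
  atlas <- synthetic_atlas(n_early = n_early, n_category = n_category)
  truth <- make_ground_truth(atlas, grid_shape, d, stim$directions,
                             seed = seed + 1L, gate_threshold = gate_threshold)
  clean <- clean_responses(truth, stim$grids)
  truth$noise_sd <- pmax(noise_scale * apply(clean, 2, stats::sd), 1e-6)
  rset <- simulate_responses(stim$grids, truth, n_repeats = n_repeats,
                             test_fraction = test_fraction, seed = seed + 2L)
  list(grids = stim$grids, tokens = grids_to_array(stim$grids),
       token_category = stim$token_category, atlas = atlas, truth = truth,
       response_set = rset)
}

#' Layered study for the backbone-layer ensemble
#'
#' Emulates a multi-layer backbone in which the signal for vertex group `l`
#' is carried exclusively by the layer-`l` token set: each layer is an
#' independent token array, and each vertex reads out (early-style, fixed
#' spatial weights) from its generating layer only. Used to test that the
#' per-vertex softmax ensemble recovers layer provenance.
#'
#' @param n_layers number of backbone layers.
#' @param n_stimuli,grid_shape,d,n_repeats,test_fraction,seed as elsewhere.
#' @param n_per_group vertices generated from each layer.
#' @param noise_scale trial-noise sd relative to clean-signal sd.
#' @return `list(layer_tokens, response_set, generating_layer)`:
#'   `layer_tokens` is a list of `n_stimuli x n_tokens x d` arrays,
#'   `generating_layer` the true layer index per vertex.
#' @export
simulate_layered_study <- function(n_layers = 3L, n_stimuli = 1200L,
                                   grid_shape = c(8, 8), d = 16L,
                                   n_per_group = 20L, n_repeats = 3L,
                                   test_fraction = 0.2, noise_scale = 1,
                                   seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n_tok <- prod(grid_shape)
  V <- n_layers * n_per_group
  layer_tokens <- lapply(seq_len(n_layers), function(l)
    array(stats::rnorm(n_stimuli * n_tok * d), c(n_stimuli, n_tok, d)))
  generating_layer <- rep(seq_len(n_layers), each = n_per_group)
  clean <- matrix(0, n_stimuli, V)
  for (v in seq_len(V)) {
    sp <- stats::rexp(n_tok)^2; sp <- sp / sum(sp)   # fixed spatial weights
    w <- stats::rnorm(d)
    Xl <- layer_tokens[[generating_layer[v]]]
    pooled <- apply(Xl, 1, function(x) as.numeric(sp %*% x) %*% w)
    clean[, v] <- pooled
  }
  noise_sd <- pmax(noise_scale * apply(clean, 2, stats::sd), 1e-6)
  reps <- array(0, c(n_stimuli, n_repeats, V))
  for (r in seq_len(n_repeats))
    reps[, r, ] <- clean + matrix(stats::rnorm(n_stimuli * V), n_stimuli, V) %*%
      diag(noise_sd, V)
  n_test <- round(n_stimuli * test_fraction)
  rset <- response_set(reps,
                       stimulus_id = sprintf("stim_%05d", seq_len(n_stimuli)),
                       split = c(rep("train", n_stimuli - n_test),
                                 rep("test", n_test)))
  list(layer_tokens = layer_tokens, response_set = rset,
       generating_layer = generating_layer)
}

#' Toy saliency maps from object labels
#'
#' A stand-in for an external bottom-up saliency model at test scale: the
#' binary object mask from the generator labels, box-blurred (3x3) on the
#' grid, plus a small uniform floor so empty scenes keep a valid map.
#'
#' @param token_category `n_stimuli x n_tokens` integer labels (0 =
#'   background).
#' @param grid_shape token grid shape.
#' @return `n_stimuli x n_tokens` nonnegative saliency matrix.
#' @export
toy_saliency <- function(token_category, grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  out <- matrix(0, nrow(token_category), ncol(token_category))
  for (s in seq_len(nrow(token_category))) {
    m <- matrix(as.numeric(token_category[s, ] > 0), rows, cols, byrow = TRUE)
    b <- m
    for (r in seq_len(rows)) for (cc in seq_len(cols)) {
      rs <- max(1, r - 1):min(rows, r + 1)
      cs <- max(1, cc - 1):min(cols, cc + 1)
      b[r, cc] <- mean(m[rs, cs])
    }
    out[s, ] <- as.vector(t(b)) + 0.05
  }
  out
}
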