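#' Cross-validated training of an encoding model
#'
#' The shared protocol for all readout families: the train split is divided
#' into folds ([make_folds()]); for each fold a model is fit on the remaining
#' folds and the held-out fold serves as validation (early stopping for the
#' gradient-trained families, penalty selection for the ridge-based ones —
#' the test split is never touched during fitting). The final test
#' prediction is the mean of the per-fold models' test predictions;
#' out-of-fold validation predictions are kept for ensemble weighting and
#' diagnostics.
#'
#' @param family one of `"transformer"` (transformer readout), `"factorized"`,
#'   `"ridge"`, `"cls"`, `"pca"`, `"saliency"`.
#' @param data named list: `tokens` (`n_stimuli x n_tokens x d` array,
#'   stimulus order = response order), `grid_shape`, `response_set`, `atlas`;
#'   plus `cls` (`n_stimuli x d`) for the CLS family and `saliency`
#'   (`n_stimuli x n_tokens`) for saliency pooling.
#' @param fold_plan a [make_folds()] plan over the train split.
#' @param granularity routing granularity for the masked families
#'   (`"roi"` or `"vertex"`).
#' @param config a [train_config()] (gradient families; its seed also makes
#'   ridge-family fits deterministic).
#' @param lambda_grid ridge penalty grid for the linear families.
#' @param n_components PCA components (default: the token feature dimension).
#' @param n_heads,d_model passed to [fit_attn_readout()].
#' @return An `encoder_cv` object: `test_pred` (fold-averaged,
#'   `n_test x n_vertices`), `val_pred` (out-of-fold, `n_train x
#'   n_vertices`), `val_r` (per-vertex out-of-fold Pearson r), `fold_models`,
#'   and bookkeeping fields.
#' @export
train_encoder <- function(family, data, fold_plan,
                          granularity = c("roi", "vertex"),
                          config = train_config(),
                          lambda_grid = 10^seq(-2, 6),
                          n_components = NULL, n_heads = 1L, d_model = NULL) {
  family <- match.arg(family, c("transformer", "factorized", "ridge", "cls", "pca",
                                "saliency"))
  granularity <- match.arg(granularity)
  rset <- data$response_set
  Y <- rset$averaged
  is_train <- rset$split == "train"
  train_ids <- rset$stimulus_id[is_train]
  test_idx <- which(!is_train)
  stopifnot(setequal(names(fold_plan$fold_of), train_ids))
  fold_of <- fold_plan$fold_of[train_ids]

  feats <- .encoder_features(family, data, n_components)
  masks <- if (family %in% c("transformer", "factorized"))
    build_masks(data$atlas, granularity)
  n_tr <- length(train_ids)
  V <- ncol(Y)
  val_pred <- matrix(NA_real_, n_tr, V)
  test_pred <- matrix(0, length(test_idx), V)
  fold_models <- vector("list", fold_plan$n_folds)
  train_pos <- which(is_train)

  for (k in seq_len(fold_plan$n_folds)) {
    tr <- train_pos[fold_of != k]
    va <- train_pos[fold_of == k]
    cfg <- config
    cfg$seed <- config$seed + k
    model <- .fit_one(family, feats, Y, tr, va, masks, cfg, lambda_grid,
                      n_components, n_heads, d_model, data)
    fold_models[[k]] <- model
    val_pred[which(fold_of == k), ] <- .predict_one(family, model, feats, va)
    test_pred <- test_pred + .predict_one(family, model, feats, test_idx)
  }
  test_pred <- test_pred / fold_plan$n_folds
  val_r <- colwise_pearson(val_pred, Y[train_pos, , drop = FALSE])
  structure(list(family = family, granularity = granularity,
                 fold_models = fold_models, test_pred = test_pred,
                 val_pred = val_pred, val_r = val_r,
                 test_ids = rset$stimulus_id[test_idx],
                 train_ids = train_ids, fold_plan = fold_plan),
            class = "encoder_cv")
}

#' @export
print.encoder_cv <- function(x, ...) {
  cat(sprintf(
    "<encoder_cv '%s'%s: %d folds, mean out-of-fold r = %.3f>\n",
    x$family,
    if (x$family %in% c("transformer", "factorized"))
      paste0(" (", x$granularity, ")") else "",
    x$fold_plan$n_folds, mean(x$val_r, na.rm = TRUE)))
  invisible(x)
}

.encoder_features <- function(family, data, n_components) {
  switch(family,
    transformer = , factorized = data$tokens,
    ridge = , pca = {
      dm <- dim(data$tokens)
      matrix(data$tokens, dm[1], dm[2] * dm[3])
    },
    cls = {
      if (is.null(data$cls)) stop("train_encoder: data$cls required for 'cls'")
      as.matrix(data$cls)
    },
    saliency = {
      if (is.null(data$saliency))
        stop("train_encoder: data$saliency required for 'saliency'")
      sal <- data$saliency
      if (any(rowSums(sal) <= 0)) stop("train_encoder: all-zero saliency map")
      sal <- sal / rowSums(sal)
      dm <- dim(data$tokens)
      out <- matrix(0, dm[1], dm[3])
      for (s in seq_len(dm[1])) out[s, ] <- sal[s, ] %*% data$tokens[s, , ]
      out
    })
}

.fit_one <- function(family, feats, Y, tr, va, masks, config, lambda_grid,
                     n_components, n_heads, d_model, data) {
  Ytr <- Y[tr, , drop = FALSE]; Yva <- Y[va, , drop = FALSE]
  if (family == "transformer") {
    pos_d <- if (is.null(d_model)) dim(feats)[3] else d_model
    positions <- sinusoidal_positions(data$grid_shape, pos_d)
    fit_attn_readout(feats[tr, , , drop = FALSE], Ytr, masks, positions, config,
             feats[va, , , drop = FALSE], Yva, n_heads = n_heads,
             d_model = d_model)
  } else if (family == "factorized") {
    fit_factorized(feats[tr, , , drop = FALSE], Ytr, masks, config,
                   feats[va, , , drop = FALSE], Yva)
  } else if (family == "pca") {
    nc <- n_components %||% min(dim(data$tokens)[3], length(tr), ncol(feats))
    fit_pca_regression(feats[tr, , drop = FALSE], Ytr, nc, lambda_grid,
                       feats[va, , drop = FALSE], Yva)
  } else {
    fit_ridge(feats[tr, , drop = FALSE], Ytr, lambda_grid,
              feats[va, , drop = FALSE], Yva)
  }
}

.predict_one <- function(family, model, feats, idx) {
  if (family %in% c("transformer", "factorized"))
    predict(model, feats[idx, , , drop = FALSE])
  else
    predict(model, feats[idx, , drop = FALSE])
}

#' Estimate per-vertex noise ceilings from repeats
#'
#' The NSD-style estimator: per vertex, the noise variance is the mean
#' within-stimulus variance across repeats; the signal variance is the total
#' variance of the repeat-means minus the residual noise it contains
#' (clipped at zero). With `ncsnr = sigma_signal / sigma_noise`, the ceiling
#' for responses averaged over `n` repeats is `ncsnr^2 / (ncsnr^2 + 1/n)` —
#' the maximum fraction of variance of the averaged response any model could
#' explain. Clipped to `[1e-3, 1]` so normalization never divides by zero.
#'
#' @param rset a [response_set]; at least half the stimuli need two or more
#'   available repeats.
#' @param n_averaged_repeats the `n` of the averaging actually used for the
#'   targets (default: the nominal repeat count).
#' @return per-vertex numeric vector in `[1e-3, 1]`.
#' @export
estimate_noise_ceiling <- function(rset, n_averaged_repeats = NULL) {
  reps <- rset$repeats
  n_rep_avail <- apply(!is.na(reps), c(1, 3), sum)
  if (mean(n_rep_avail[, 1] >= 2) < 0.5)
    stop(paste("estimate_noise_ceiling: fewer than half the stimuli have",
               ">= 2 repeats; use raw r^2 instead of normalized accuracy"))
  n_avg <- n_averaged_repeats %||% dim(reps)[2]
  V <- dim(reps)[3]
  nc <- numeric(V)
  for (v in seq_len(V)) {
    rv <- reps[, , v, drop = TRUE]
    wvar <- apply(rv, 1, stats::var, na.rm = TRUE)       # within-stimulus
    ok <- !is.na(wvar)
    sigma2_noise <- mean(wvar[ok])
    means <- rowMeans(rv, na.rm = TRUE)
    resid <- mean(1 / pmax(n_rep_avail[, v], 1))         # noise left in means
    sigma2_signal <- max(0, stats::var(means) - sigma2_noise * resid)
    nc[v] <- if (sigma2_noise <= 1e-300) as.numeric(sigma2_signal > 0)
    else {
      ncsnr2 <- sigma2_signal / sigma2_noise
      ncsnr2 / (ncsnr2 + 1 / n_avg)
    }
  }
  pmin(pmax(nc, 1e-3), 1)
}

#' Noise-ceiling-normalized encoding accuracy
#'
#' The evaluation metric: per vertex, the squared Pearson correlation
#' between predictions and measured responses on the test split, divided by
#' the noise ceiling — the fraction of explainable variance explained.
#' Negative correlations still yield positive squared values and are flagged;
#' degenerate (constant) predictions or targets score 0 with a flag.
#'
#' @param predictions,targets aligned `n_stimuli x n_vertices` matrices.
#' @param noise_ceiling per-vertex ceiling in `(0, 1]`.
#' @return data.frame with columns `r`, `r2`, `nc`, `accuracy`, `flag`
#'   (`""`, `"negative_r"`, or `"degenerate"`).
#' @export
encoding_accuracy <- function(predictions, targets, noise_ceiling) {
  predictions <- as.matrix(predictions); targets <- as.matrix(targets)
  if (!all(dim(predictions) == dim(targets)))
    stop("encoding_accuracy: prediction/target shapes differ")
  if (length(noise_ceiling) != ncol(targets))
    stop("encoding_accuracy: noise ceiling length mismatch")
  if (any(noise_ceiling <= 0)) stop("encoding_accuracy: noise ceiling must be > 0")
  r <- colwise_pearson(predictions, targets)
  flag <- ifelse(is.na(r), "degenerate", ifelse(r < 0, "negative_r", ""))
  r2 <- ifelse(is.na(r), 0, r^2)
  data.frame(r = ifelse(is.na(r), 0, r), r2 = r2, nc = noise_ceiling,
             accuracy = r2 / noise_ceiling, flag = flag,
             stringsAsFactors = FALSE)
}

#' Summarize accuracy per ROI and per selectivity cluster
#'
#' @param accuracy per-vertex accuracy vector (atlas order).
#' @param atlas an [roi_atlas].
#' @param cluster_map named ROI-to-cluster vector (default
#'   [nsd_roi_clusters()], with `"unlabeled"` its own cluster).
#' @return `list(roi, cluster)`: data.frames of vertex counts and mean
#'   accuracy per (hemisphere, ROI) and per cluster.
#' @export
roi_summary <- function(accuracy, atlas, cluster_map = nsd_roi_clusters()) {
  stopifnot(length(accuracy) == length(atlas$vertex_id))
  cluster_map <- c(cluster_map, unlabeled = "unlabeled")
  unknown <- setdiff(unique(atlas$roi_label), names(cluster_map))
  if (length(unknown))
    stop(sprintf("roi_summary: unknown ROI label(s): %s",
                 paste(unknown, collapse = ", ")))
  key <- paste(atlas$hemisphere, atlas$roi_label, sep = "/")
  roi_tab <- do.call(rbind, lapply(split(seq_along(accuracy), key), function(i)
    data.frame(hemisphere = atlas$hemisphere[i[1]],
               roi = atlas$roi_label[i[1]], n_vertices = length(i),
               mean_accuracy = mean(accuracy[i]))))
  rownames(roi_tab) <- NULL
  cl <- cluster_map[atlas$roi_label]
  cl_tab <- do.call(rbind, lapply(split(seq_along(accuracy), cl), function(i)
    data.frame(cluster = cl[i[1]], n_vertices = length(i),
               mean_accuracy = mean(accuracy[i]))))
  rownames(cl_tab) <- NULL
  list(roi = roi_tab, cluster = cl_tab)
}

#' Per-vertex softmax ensemble over backbone layers
#'
#' Combines the test predictions of several encoders (one per backbone
#' layer) with per-vertex softmax weights over each member's validation
#' goodness (out-of-fold Pearson r): `w_l(v) = softmax_l(r_l(v) / tau)`. A
#' small temperature makes the combination approach per-vertex selection of
#' the best layer while retaining smoothing.
#'
#' @param member_predictions list of aligned `n_stimuli x n_vertices` test
#'   prediction matrices, one per member.
#' @param validation_goodness list (or `L x n_vertices` matrix) of per-vertex
#'   validation Pearson r per member.
#' @param tau softmax temperature (> 0, default 0.05).
#' @return `list(pred, weights, best_layer)`: the combined prediction, the
#'   `L x n_vertices` weight matrix (columns on the simplex), and the argmax
#'   member per vertex.
#' @export
ensemble_predict <- function(member_predictions, validation_goodness,
                             tau = 0.05) {
  if (tau <= 0) stop("ensemble_predict: tau must be > 0")
  L <- length(member_predictions)
  if (is.list(validation_goodness))
    validation_goodness <- do.call(rbind, validation_goodness)
  stopifnot(nrow(validation_goodness) == L)
  dims <- dim(member_predictions[[1]])
  for (p in member_predictions) stopifnot(all(dim(p) == dims))
  Z <- validation_goodness / tau
  Z <- sweep(Z, 2, apply(Z, 2, max))
  W <- exp(Z)
  W <- sweep(W, 2, colSums(W), "/")
  pred <- matrix(0, dims[1], dims[2])
  for (l in seq_len(L))
    pred <- pred + sweep(member_predictions[[l]], 2, W[l, ], "*")
  list(pred = pred, weights = W, best_layer = apply(W, 2, which.max))
}

#' Write per-vertex metrics as a TSV table
#'
#' @param accuracy_df output of [encoding_accuracy()].
#' @param atlas an [roi_atlas] aligned with the vertices.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_metrics <- function(accuracy_df, atlas, path) {
  tab <- cbind(data.frame(vertex_id = atlas$vertex_id,
                          hemisphere = atlas$hemisphere,
                          roi = atlas$roi_label), accuracy_df)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
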