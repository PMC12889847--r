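#' Reference desk-scale encoding study
#'
#' Runs the package's full validation protocol on the synthetic brain at its
#' reference conditions and returns every quantity the comparison figures
#' need: per-family noise-ceiling-normalized accuracies split by early
#' (fixed-RF) vertices and content-gated category ROIs, the oracle ceiling,
#' recovered factorized spatial maps, and the fitted models themselves.
#'
#' Conditions (see the methods vignette for rationale): 2000 stimuli on an
#' 8x8 token grid with d = 32, 96 vertices (12 per early ROI and 8 per
#' category ROI per hemisphere), 3 repeats with trial noise calibrated to
#' the clean-signal sd, 15% test split, 3-fold cross-validation, decoder
#' width 64 with cosine-decayed Adam.
#'
#' @param families character vector of model families to fit; granularity
#'   variants are named `"transformer_roi"`, `"transformer_vertex"`, `"factorized_roi"`,
#'   `"factorized_vertex"`, `"ridge"`, `"cls"`, `"pca"`, `"saliency"`.
#' @param n_stimuli number of stimuli (2000 reference).
#' @param n_folds cross-validation folds (3 reference).
#' @param seed integer seed driving every random element.
#' @param d_model decoder width for the transformer readout.
#' @param epochs named list overriding per-family epoch budgets.
#' @return list with `study` (the generator output), `nc`, `oracle`,
#'   `is_early` (per-vertex), `fits` (per family `encoder_cv`), and
#'   `accuracy` (per family list with per-vertex vector plus `early` /
#'   `category` means).
#' @export
run_reference_study <- function(families = c("transformer_roi", "transformer_vertex",
                                             "factorized_roi",
                                             "factorized_vertex", "ridge"),
                                n_stimuli = 2000L, n_folds = 3L, seed = 1L,
                                d_model = 64L, epochs = list()) {
  study <- simulate_encoding_study(n_stimuli = n_stimuli, seed = seed)
  rset <- study$response_set
  nc <- estimate_noise_ceiling(rset)
  rset$noise_ceiling <- nc
  oracle <- oracle_accuracy(study$truth, rset, study$grids)
  is_early <- study$truth$vertex_category == 0L
  data <- list(tokens = study$tokens, grid_shape = study$truth$grid_shape,
               response_set = rset, atlas = study$atlas,
               cls = grids_to_cls(study$grids),
               saliency = toy_saliency(study$token_category,
                                       study$truth$grid_shape))
  fp <- make_folds(rset, n_folds = n_folds, seed = seed + 10L)
  ep <- function(nm, default) epochs[[nm]] %||% default
  te <- rset$split == "test"
  Yte <- rset$averaged[te, , drop = FALSE]

  fits <- list(); accuracy <- list()
  for (fam in families) {
    fit <- switch(fam,
      transformer_roi = train_encoder("transformer", data, fp, granularity = "roi",
        config = train_config(learning_rate = 5e-3, max_epochs = ep(fam, 200L),
                              early_stop_patience = ep(fam, 200L),
                              seed = seed + 20L, lr_schedule = "cosine"),
        d_model = d_model),
      transformer_vertex = train_encoder("transformer", data, fp, granularity = "vertex",
        config = train_config(learning_rate = 1e-2, max_epochs = ep(fam, 100L),
                              early_stop_patience = ep(fam, 100L),
                              seed = seed + 21L, lr_schedule = "cosine"),
        d_model = d_model),
      factorized_roi = train_encoder("factorized", data, fp,
        granularity = "roi",
        config = train_config(learning_rate = 1e-2, max_epochs = ep(fam, 60L),
                              early_stop_patience = 15L, seed = seed + 22L)),
      factorized_vertex = train_encoder("factorized", data, fp,
        granularity = "vertex",
        config = train_config(learning_rate = 1e-2, max_epochs = ep(fam, 60L),
                              early_stop_patience = 15L, seed = seed + 23L)),
      ridge = train_encoder("ridge", data, fp),
      cls = train_encoder("cls", data, fp),
      pca = train_encoder("pca", data, fp),
      saliency = train_encoder("saliency", data, fp),
      stop(sprintf("run_reference_study: unknown family '%s'", fam)))
    acc <- encoding_accuracy(fit$test_pred, Yte, nc)$accuracy
    fits[[fam]] <- fit
    accuracy[[fam]] <- list(per_vertex = acc,
                            early = mean(acc[is_early]),
                            category = mean(acc[!is_early]))
  }
  list(study = study, nc = nc, oracle = oracle, is_early = is_early,
       fold_plan = fp, fits = fits, accuracy = accuracy,
       oracle_early = mean(oracle[is_early]),
       oracle_category = mean(oracle[!is_early]))
}

#' Backbone-layer ensemble experiment
#'
#' Fits one encoder per synthetic backbone layer on the layered study
#' (signal for vertex group l carried by layer-l tokens only), combines them
#' with the per-vertex softmax ensemble, and reports how often the argmax
#' ensemble weight identifies the generating layer.
#'
#' @param n_layers,n_stimuli layered-study sizes.
#' @param n_folds cross-validation folds for the members.
#' @param tau ensemble softmax temperature.
#' @param seed integer seed.
#' @return list with `provenance_rate`, `ensemble_accuracy`,
#'   `member_accuracy` (per layer), and the underlying objects.
#' @export
run_layer_ensemble_study <- function(n_layers = 3L, n_stimuli = 1200L,
                                     n_folds = 3L, tau = 0.05, seed = 1L) {
  lay <- simulate_layered_study(n_layers = n_layers, n_stimuli = n_stimuli,
                                seed = seed)
  rset <- lay$response_set
  nc <- estimate_noise_ceiling(rset)
  fp <- make_folds(rset, n_folds = n_folds, seed = seed + 1L)
  atlas <- roi_atlas(seq_along(lay$generating_layer) - 1L,
                     rep("LH", length(lay$generating_layer)),
                     rep("unlabeled", length(lay$generating_layer)))
  te <- rset$split == "test"
  Yte <- rset$averaged[te, , drop = FALSE]
  fits <- lapply(seq_len(n_layers), function(l) {
    data <- list(tokens = lay$layer_tokens[[l]],
                 grid_shape = c(8L, 8L), response_set = rset, atlas = atlas)
    train_encoder("ridge", data, fp)
  })
  ens <- ensemble_predict(lapply(fits, `[[`, "test_pred"),
                          lapply(fits, `[[`, "val_r"), tau = tau)
  member_acc <- vapply(fits, function(f)
    mean(encoding_accuracy(f$test_pred, Yte, nc)$accuracy), 0)
  ens_acc <- mean(encoding_accuracy(ens$pred, Yte, nc)$accuracy)
  list(provenance_rate = mean(ens$best_layer == lay$generating_layer),
       ensemble_accuracy = ens_acc, member_accuracy = member_acc,
       weights = ens$weights, generating_layer = lay$generating_layer,
       fits = fits)
}

#' Training-set size sweep for the transformer readout
#'
#' Fits the ROI-granularity transformer readout on nested subsets of a large
#' synthetic study and evaluates each on the common test split — the desk-
#' scale analogue of a sample-efficiency table.
#'
#' @param sizes training-set sizes (nested subsets of the train split).
#' @param n_stimuli total stimuli to generate (must cover `max(sizes)` plus
#'   the test split).
#' @param n_folds folds per size.
#' @param seed integer seed.
#' @param max_epochs epoch budget per fit.
#' @param d_model decoder width.
#' @return data.frame with columns `size` and mean `accuracy`.
#' @export
run_size_sweep <- function(sizes = c(550L, 1100L, 2200L, 4400L),
                           n_stimuli = 5000L, n_folds = 2L, seed = 1L,
                           max_epochs = 40L, d_model = 64L) {
  stopifnot(max(sizes) <= n_stimuli * 0.88)
  study <- simulate_encoding_study(n_stimuli = n_stimuli, test_fraction = 0.12,
                                   seed = seed)
  rset <- study$response_set
  nc <- estimate_noise_ceiling(rset)
  te <- rset$split == "test"
  Yte <- rset$averaged[te, , drop = FALSE]
  out <- data.frame(size = sizes, accuracy = NA_real_)
  for (i in seq_along(sizes)) {
    keep <- c(which(rset$split == "train")[seq_len(sizes[i])], which(te))
    sub <- response_set(rset$repeats[keep, , , drop = FALSE],
                        rset$stimulus_id[keep], rset$split[keep])
    data <- list(tokens = study$tokens[keep, , , drop = FALSE],
                 grid_shape = study$truth$grid_shape,
                 response_set = sub, atlas = study$atlas)
    fp <- make_folds(sub, n_folds = n_folds, seed = seed + 30L + i)
    fit <- train_encoder("transformer", data, fp, granularity = "roi",
      config = train_config(learning_rate = 1e-2, max_epochs = max_epochs,
                            early_stop_patience = max_epochs,
                            seed = seed + 40L + i, lr_schedule = "cosine"),
      d_model = d_model)
    out$accuracy[i] <- mean(encoding_accuracy(fit$test_pred, Yte, nc)$accuracy)
  }
  out
}
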