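# Small fixtures shared across test files; everything is generated in code.

# A three-ROI two-hemisphere toy atlas (6 early + 4 category vertices).
toy_atlas <- function() {
  roi_atlas(vertex_id = 0:9,
            hemisphere = c(rep("LH", 5), rep("RH", 5)),
            roi_label = c("V1v", "V1v", "V2d", "FFA-1", "FFA-1",
                          "V1v", "V2d", "V2d", "PPA", "unlabeled"))
}

# A handful of random token grids with consistent shape.
toy_grids <- function(n = 3, grid_shape = c(2, 3), d = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tk <- matrix(rnorm(prod(grid_shape) * d), prod(grid_shape), d)
    token_grid(tk, grid_shape = grid_shape, cls = colMeans(tk),
               stimulus_id = sprintf("s%02d", i))
  })
}

toy_response_set <- function(n = 12, v = 10, reps = 3, seed = 2,
                             n_test = 3, ids = NULL) {
  set.seed(seed)
  arr <- array(rnorm(n * reps * v), c(n, reps, v))
  response_set(arr,
               stimulus_id = ids %||% sprintf("s%02d", seq_len(n)),
               split = c(rep("train", n - n_test), rep("test", n_test)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_simplex <- function(w, tol = 1e-10) {
  expect_true(all(w >= -tol))
  expect_equal(sum(w), 1, tolerance = 1e-8)
}
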