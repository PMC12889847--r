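test_that("token_grid validates shape, finiteness and CLS length", {
  tk <- matrix(1:12, 4, 3)
  g <- token_grid(tk, grid_shape = c(2, 2), stimulus_id = "a")
  expect_s3_class(g, "token_grid")
  expect_error(token_grid(tk, grid_shape = c(3, 2)), "grid_shape")
  expect_error(token_grid(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(token_grid(tk, cls = 1:2), "cls")
  # grid-free sequences are allowed
  expect_null(token_grid(tk)$grid_shape)
})

test_that("reshape_feature_map unrolls row-major with channels as features", {
  fm <- array(0, c(3, 2, 2))   # channels x rows x cols
  fm[, 1, 1] <- c(1, 2, 3); fm[, 1, 2] <- c(4, 5, 6)
  fm[, 2, 1] <- c(7, 8, 9); fm[, 2, 2] <- c(10, 11, 12)
  g <- reshape_feature_map(fm, "x")
  expect_equal(dim(g$tokens), c(4L, 3L))
  expect_equal(g$tokens[1, ], c(1, 2, 3))   # (1,1)
  expect_equal(g$tokens[2, ], c(4, 5, 6))   # (1,2)
  expect_equal(g$tokens[3, ], c(7, 8, 9))   # (2,1)
  # round-trip
  back <- array(0, c(3, 2, 2))
  k <- 0
  for (r in 1:2) for (cc in 1:2) { k <- k + 1; back[, r, cc] <- g$tokens[k, ] }
  expect_identical(back, fm)
  # standard convnet last-layer shape
  g2 <- reshape_feature_map(array(rnorm(2048 * 7 * 7), c(2048, 7, 7)))
  expect_equal(dim(g2$tokens), c(49L, 2048L))
})

test_that("roi_atlas enforces one assignment per vertex and valid hemispheres", {
  expect_error(roi_atlas(c(1, 1), c("LH", "LH"), c("A", "B")), "duplicate")
  expect_error(roi_atlas(1:2, c("XX", "LH"), c("A", "B")), "hemisphere")
  a <- toy_atlas()
  expect_equal(length(a$roi_index), 7L)
  expect_equal(a$roi_index[["LH/FFA-1"]], c(4L, 5L))
})

test_that("atlas TSV round-trips and rejects missing columns", {
  a <- toy_atlas()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_atlas(a, path)
  b <- read_roi_atlas(path)
  expect_identical(a$vertex_id, b$vertex_id)
  expect_identical(a$roi_label, b$roi_label)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("vertex_id\themisphere\n1\tLH", bad)
  expect_error(read_roi_atlas(bad), "roi_label")
})

test_that("ROI masks partition each hemisphere and vertex masks are singletons", {
  a <- toy_atlas()
  masks <- build_masks(a, "roi")
  expect_equal(length(masks), 7L)
  # within a hemisphere the masks sum to that hemisphere's indicator
  for (h in c("LH", "RH")) {
    hm <- masks[startsWith(names(masks), h)]
    expect_equal(Reduce(`+`, hm), as.numeric(a$hemisphere == h))
  }
  # explicit toy example: {v0,v1 -> A; v2 -> B}
  tiny <- roi_atlas(0:2, rep("LH", 3), c("A", "A", "B"))
  mt <- build_masks(tiny, "roi")
  expect_equal(as.numeric(mt[["LH/A"]]), c(1, 1, 0))
  expect_equal(as.numeric(mt[["LH/B"]]), c(0, 0, 1))
  vm <- build_masks(a, "vertex")
  expect_equal(length(vm), 10L)
  expect_true(all(vapply(vm, sum, 0) == 1))
  # random atlases keep the partition property
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:40, 1)
    ra <- roi_atlas(seq_len(n), sample(c("LH", "RH"), n, TRUE),
                    sample(c("V1v", "PPA", "unlabeled"), n, TRUE))
    rm <- build_masks(ra, "roi")
    expect_equal(Reduce(`+`, rm), rep(1, n))
  }
})

test_that("response_set averages available repeats and flags bad input", {
  arr <- array(NA_real_, c(2, 3, 2))
  arr[1, , 1] <- c(1, 2, 3); arr[1, , 2] <- c(2, NA, 4)
  arr[2, , 1] <- c(0, 0, 0); arr[2, , 2] <- c(5, 5, NA)
  rs <- response_set(arr, c("a", "b"), c("train", "test"))
  expect_equal(rs$averaged[1, ], c(2, 3))
  expect_equal(rs$averaged[2, ], c(0, 5))
  arr2 <- arr; arr2[2, , 2] <- NA
  expect_error(response_set(arr2, c("a", "b"), c("train", "test")), "repeat")
  expect_error(response_set(arr, c("a", "a"), c("train", "test")), "duplicate")
})

test_that("fold plans partition train stimuli with near-equal sizes", {
  rs <- toy_response_set(n = 103, v = 4, n_test = 3)
  fp <- make_folds(rs, n_folds = 10, seed = 9)
  expect_equal(sort(unique(fp$fold_of)), 1:10)
  expect_equal(length(fp$fold_of), 100L)
  expect_true(all(table(fp$fold_of) == 10))
  # deterministic given seed
  fp2 <- make_folds(rs, n_folds = 10, seed = 9)
  expect_identical(fp$fold_of, fp2$fold_of)
  # uneven case: sizes differ by at most one
  rs2 <- toy_response_set(n = 26, v = 4, n_test = 3)
  fp3 <- make_folds(rs2, n_folds = 10, seed = 1)
  expect_true(all(table(fp3$fold_of) %in% c(2, 3)))
  expect_error(make_folds(rs, n_folds = 1), "n_folds")
})

test_that("containers round-trip and misalignment is reported", {
  grids <- toy_grids(n = 4, d = 6)
  atlas <- toy_atlas()
  rs <- toy_response_set(n = 4, v = 10, n_test = 1,
                         ids = vapply(grids, `[[`, "", "stimulus_id"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_container(grids, rs, atlas, path, truth = list(note = "t"))
  out <- load_container(path)
  expect_equal(out$grids[[2]]$tokens, grids[[2]]$tokens)
  expect_equal(out$response_set$averaged, rs$averaged)
  expect_identical(out$atlas$roi_label, atlas$roi_label)
  expect_equal(out$truth$note, "t")
  # responses for an id absent from tokens -> alignment error
  rs_bad <- toy_response_set(n = 4, v = 10, n_test = 1,
                             ids = c("s01", "s02", "s03", "zzz"))
  expect_error(save_container(grids, rs_bad, atlas, path), "zzz")
  # loading re-orders responses by stimulus id
  obj <- readRDS(path)
  perm <- c(3, 1, 4, 2)
  obj$responses$repeats <- obj$responses$repeats[perm, , , drop = FALSE]
  obj$responses$stimulus_ids <- obj$responses$stimulus_ids[perm]
  obj$split <- obj$split[perm]
  saveRDS(obj, path)
  out2 <- load_container(path)
  expect_equal(out2$response_set$averaged, rs$averaged)
})
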