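test_that("noise ceiling closed forms hold", {
  # noiseless repeats -> ceiling 1
  set.seed(1)
  clean <- matrix(rnorm(200 * 4), 200, 4)
  reps <- array(0, c(200, 3, 4))
  for (r in 1:3) reps[, r, ] <- clean
  rs <- response_set(reps, sprintf("s%03d", 1:200),
                     c(rep("train", 150), rep("test", 50)))
  expect_equal(as.numeric(estimate_noise_ceiling(rs)), rep(1, 4))
  # ncsnr = 1 with 3 averaged repeats -> NC = 1 / (1 + 1/3) = 0.75
  set.seed(2)
  n <- 4000
  clean <- matrix(rnorm(n * 3), n, 3)           # signal sd 1
  reps <- array(0, c(n, 3, 3))
  for (r in 1:3) reps[, r, ] <- clean + matrix(rnorm(n * 3), n, 3)  # noise sd 1
  rs <- response_set(reps, sprintf("s%05d", 1:n), rep("train", n))
  nc <- estimate_noise_ceiling(rs, n_averaged_repeats = 3)
  expect_equal(mean(nc), 0.75, tolerance = 0.02)
  # single-repeat data cannot support the estimator
  rs1 <- response_set(array(rnorm(40), c(10, 1, 4)), sprintf("s%02d", 1:10),
                      rep("train", 10))
  expect_error(estimate_noise_ceiling(rs1), "repeats")
})

test_that("noise ceiling handles missing repeats through availability counts", {
  set.seed(3)
  n <- 3000
  clean <- rnorm(n)
  reps <- array(NA_real_, c(n, 3, 1))
  for (r in 1:3) reps[, r, 1] <- clean + rnorm(n)
  reps[seq(1, n, by = 3), 3, 1] <- NA          # a third have only 2 repeats
  rs <- response_set(reps, sprintf("s%05d", 1:n), rep("train", n))
  nc <- estimate_noise_ceiling(rs, n_averaged_repeats = 3)
  expect_equal(as.numeric(nc), 0.75, tolerance = 0.03)
})

test_that("encoding accuracy implements r^2 / NC with flags", {
  x <- rnorm(50)
  acc <- encoding_accuracy(cbind(x), cbind(x), 1)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$flag, "")
  acc_neg <- encoding_accuracy(cbind(-x), cbind(x), 1)
  expect_equal(acc_neg$accuracy, 1)
  expect_equal(acc_neg$flag, "negative_r")
  # r = 0.6, NC = 0.48 -> 0.36 / 0.48 = 0.75 (construct exact r)
  set.seed(4)
  a <- scale(rnorm(100))[, 1]
  b0 <- scale(resid(lm(rnorm(100) ~ a)))[, 1]
  y <- 0.6 * a + sqrt(1 - 0.36) * b0
  acc2 <- encoding_accuracy(cbind(a), cbind(y), 0.48)
  expect_equal(acc2$accuracy, 0.36 / 0.48, tolerance = 1e-10)
  # degenerate constant prediction scores 0 with a flag
  acc3 <- encoding_accuracy(cbind(rep(1, 50)), cbind(x), 0.5)
  expect_equal(acc3$accuracy, 0)
  expect_equal(acc3$flag, "degenerate")
  expect_error(encoding_accuracy(cbind(x), cbind(x), -1), "> 0")
})

test_that("roi_summary matches a brute-force group-by", {
  atlas <- toy_atlas()
  set.seed(5)
  acc <- runif(10)
  out <- roi_summary(acc, atlas)
  # brute force over every (hemisphere, roi)
  for (i in seq_len(nrow(out$roi))) {
    sel <- atlas$hemisphere == out$roi$hemisphere[i] &
      atlas$roi_label == out$roi$roi[i]
    expect_equal(out$roi$mean_accuracy[i], mean(acc[sel]))
  }
  # cluster mean equals vertex-count weighted mean of member ROI means
  cl <- out$cluster[out$cluster$cluster == "early", ]
  sel <- atlas$roi_label %in% c("V1v", "V2d")
  expect_equal(cl$mean_accuracy, mean(acc[sel]))
  expect_equal(cl$n_vertices, sum(sel))
  # uniform accuracy gives uniform means
  u <- roi_summary(rep(0.5, 10), atlas)
  expect_true(all(abs(u$roi$mean_accuracy - 0.5) < 1e-12))
  bad_atlas <- roi_atlas(1:2, c("LH", "LH"), c("V1v", "nonsense"))
  expect_error(roi_summary(c(1, 2), bad_atlas), "unknown ROI")
})

test_that("ensemble weighting follows the softmax of validation goodness", {
  set.seed(6)
  L <- 3; n <- 40; V <- 5
  preds <- lapply(1:L, function(l) matrix(rnorm(n * V), n, V))
  # equal goodness -> uniform weights
  eq <- ensemble_predict(preds, matrix(0.4, L, V), tau = 0.05)
  expect_true(all(abs(eq$weights - 1 / L) < 1e-12))
  expect_equal(eq$pred, (preds[[1]] + preds[[2]] + preds[[3]]) / 3)
  # tiny temperature -> hard per-vertex selection of the best member
  good <- matrix(runif(L * V), L, V)
  hard <- ensemble_predict(preds, good, tau = 1e-6)
  for (v in 1:V) {
    b <- which.max(good[, v])
    expect_equal(hard$pred[, v], preds[[b]][, v])
    expect_equal(hard$best_layer[v], b)
  }
  # weights are a simplex per vertex and the combination is the weighted sum
  soft <- ensemble_predict(preds, good, tau = 0.05)
  expect_equal(colSums(soft$weights), rep(1, V))
  brute <- matrix(0, n, V)
  for (v in 1:V) for (l in 1:L)
    brute[, v] <- brute[, v] + soft$weights[l, v] * preds[[l]][, v]
  expect_equal(soft$pred, brute)
  expect_error(ensemble_predict(preds, good, tau = 0), "tau")
})

test_that("metrics TSV export carries atlas annotation", {
  atlas <- toy_atlas()
  acc <- encoding_accuracy(matrix(rnorm(50), 5, 10),
                           matrix(rnorm(50), 5, 10), rep(0.5, 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(acc, atlas, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 10L)
  expect_true(all(c("vertex_id", "hemisphere", "roi", "r", "accuracy") %in%
                    names(tab)))
})
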