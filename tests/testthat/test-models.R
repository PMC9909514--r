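test_that("parameter counts match closed-form layer arithmetic", {
  m <- build_cnn(cnn_architecture(), seed = 1)
  expect_equal(n_params(m), oracle_cnn_params())
  lit <- build_cnn(cnn_architecture(stride_mode = "literal_1x2"), seed = 1)
  expect_equal(n_params(lit),
               oracle_cnn_params(pool_stride = c(1, 2)))
  expect_gt(n_params(lit), n_params(m))
})

test_that("untrained forward passes respect the probability contract", {
  m <- build_cnn(seed = 2)
  set.seed(2)
  segs <- lapply(1:7, function(i)
    structure(matrix(rnorm(64 * 200), 64, 200), label = i %% 2))
  p <- predict_segments(m, segs)
  expect_length(p, 7)
  expect_true(all(p > 0 & p < 1))
  # inference determinism and order preservation
  expect_identical(predict_segments(m, segs), p)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  expect_equal(predict_segments(m, segs[perm]), p[perm], tolerance = 1e-7)
  expect_error(predict_segments(m, list(matrix(0, 32, 200))), "shape")
})

test_that("impossible pooling geometries are rejected", {
  expect_error(build_cnn(cnn_architecture(input_mels = 8, input_frames = 8,
                                          conv_channels = c(4, 4, 4, 4))),
               "collapses")
})

test_that("the CNN fits a separable band-energy fixture", {
  segs <- make_separable_segments(20, seed = 5)
  labs <- vapply(segs, attr, numeric(1), which = "label")
  m <- build_cnn(seed = 6)
  m <- train_cnn(m, segs, segs, train_config(epochs = 20, patience = 20,
                                             seed = 6))
  expect_gte(max(m$history$train_acc), 0.95)
  p <- predict_segments(m, segs)
  expect_gt(mean((p >= 0.5) == (labs == 1)), 0.95)
})

test_that("early stopping obeys its patience contract", {
  segs <- make_separable_segments(6, seed = 8)
  m <- build_cnn(seed = 8)
  fit <- train_cnn(m, segs, segs, train_config(epochs = 6, patience = 1,
                                               seed = 8))
  expect_gte(nrow(fit$history), 2)
  expect_lte(nrow(fit$history), 6)
  expect_equal(nrow(fit$history), fit$history$epoch[nrow(fit$history)])
})

test_that("single-class training sets are rejected", {
  segs <- make_separable_segments(4, seed = 9)
  one <- segs[1:4]  # all label 1
  m <- build_cnn(seed = 9)
  expect_error(train_cnn(m, one, one, train_config(epochs = 1)),
               "both classes")
})

test_that("training is reproducible under a fixed seed", {
  segs <- make_separable_segments(6, seed = 10)
  f1 <- train_cnn(build_cnn(seed = 3), segs, segs,
                  train_config(epochs = 2, seed = 3))
  f2 <- train_cnn(build_cnn(seed = 3), segs, segs,
                  train_config(epochs = 2, seed = 3))
  expect_identical(f1$history, f2$history)
  expect_identical(predict_segments(f1, segs), predict_segments(f2, segs))
})

test_that("backpropagation matches finite-difference gradients", {
  arch <- cnn_architecture(input_mels = 12, input_frames = 16,
                           conv_channels = c(2, 3), dense = c(5),
                           dropout = 0)
  m <- build_cnn(arch, seed = 3)
  set.seed(42)
  X <- matrix(rnorm(12 * 16 * 6), ncol = 6)
  y <- c(1, 0, 1, 0, 1, 0)
  loss <- function(w) {
    p <- depspeech:::cpp_cnn_predict(w, unclass(arch), X)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    mean(-(y * log(p) + (1 - y) * log(1 - p)))
  }
  g <- depspeech:::cpp_cnn_grad(m$weights, unclass(arch), X, y)
  set.seed(7)
  for (li in seq_along(g$W)) {
    for (rep in 1:3) {
      i <- sample(length(g$W[[li]]), 1)
      eps <- 1e-3
      wp <- m$weights; wp$W[[li]][i] <- wp$W[[li]][i] + eps
      wm <- m$weights; wm$W[[li]][i] <- wm$W[[li]][i] - eps
      num <- (loss(wp) - loss(wm)) / (2 * eps)
      ana <- g$W[[li]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 0.05)
    }
  }
})

test_that("baselines separate an offset-cluster toy problem", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  y <- rep(c(1, 0), each = 20)
  svm_fit <- fit_baseline(baseline_spec("svm_linear"), X, y)
  pr <- predict_baseline(svm_fit, X)
  expect_equal(pr$label, y)
  expect_gt(min(pr$score[y == 1]), max(pr$score[y == 0]))
  lda_fit <- fit_baseline(baseline_spec("lda"), X, y)
  expect_equal(predict_baseline(lda_fit, X)$label, y)
})

test_that("kNN honours unanimous neighbourhoods", {
  X <- rbind(matrix(c(0, 0, 0.1, 0, 0, 0.1, 0.1, 0.1, 0.05, 0.05),
                    ncol = 2, byrow = TRUE),
             matrix(c(5, 5, 5.1, 5, 5, 5.1, 5.1, 5.1, 5.05, 5.05),
                    ncol = 2, byrow = TRUE))
  y <- rep(c(1, 0), each = 5)
  fit <- fit_baseline(baseline_spec("knn"), X, y)
  pr <- predict_baseline(fit, X[1, , drop = FALSE])
  expect_equal(pr$label, 1)
  expect_equal(pr$score, 1)
})

test_that("seeded random forests are accurate and reproducible", {
  set.seed(12)
  Xtr <- rbind(matrix(rnorm(60, 2), 30, 2), matrix(rnorm(60, -2), 30, 2))
  ytr <- rep(c(1, 0), each = 30)
  Xte <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  yte <- rep(c(1, 0), each = 20)
  f1 <- fit_baseline(baseline_spec("rf", seed = 99), Xtr, ytr)
  f2 <- fit_baseline(baseline_spec("rf", seed = 99), Xtr, ytr)
  p1 <- predict_baseline(f1, Xte)
  p2 <- predict_baseline(f2, Xte)
  expect_identical(p1$score, p2$score)
  expect_gte(mean(p1$label == yte), 0.95)
})

test_that("feature standardization is fitted on training data only", {
  set.seed(13)
  Xtr <- matrix(rnorm(40, 5, 2), 20, 2)
  ytr <- rep(c(0, 1), 10)
  fit <- fit_baseline(baseline_spec("svm_linear"), Xtr, ytr)
  expect_equal(fit$center, colMeans(Xtr))
  expect_equal(fit$scale, apply(Xtr, 2, sd))
  expect_error(predict_baseline(fit, matrix(0, 2, 5)), "width")
  expect_error(fit_baseline(baseline_spec("lda"), Xtr, rep(1, 20)),
               "both classes")
})

test_that("CNN checkpoints round-trip through plain-text serialization", {
  m <- build_cnn(cnn_architecture(input_mels = 12, input_frames = 16,
                                  conv_channels = c(2, 3), dense = c(5)),
                 seed = 4)
  set.seed(5)
  segs <- lapply(1:4, function(i)
    structure(matrix(rnorm(12 * 16), 12, 16), label = i %% 2))
  dir <- withr::local_tempdir()
  save_cnn(m, dir)
  m2 <- load_cnn(dir)
  p1 <- depspeech:::cpp_cnn_predict(m$weights, unclass(m$arch),
                                    depspeech:::segments_to_matrix(segs))
  p2 <- depspeech:::cpp_cnn_predict(m2$weights, unclass(m2$arch),
                                    depspeech:::segments_to_matrix(segs))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "architecture.json")))
  expect_true(file.exists(file.path(dir, "weights.json")))
})
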