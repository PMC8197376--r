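test_that("grouped 1-in-5 split is deterministic and leakage-free", {
  a <- fix_small_aug()                       # 5 origins per class
  sp <- split_dataset(a)
  # exactly one origin (11 clips) per class goes to test
  expect_equal(nrow(sp$test), 5L * 11L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(a))
  expect_length(intersect(sp$train$origin_id, sp$test$origin_id), 0L)
  # deterministic
  sp2 <- split_dataset(a)
  expect_identical(sp$test$origin_id, sp2$test$origin_id)
  # origins with a wrong member count are rejected
  expect_error(split_dataset(a[-1, ]), "exactly 11")
  # test fraction lands in [18 %, 22 %] at a larger, uneven scale
  big <- augment_dataset(generate_dataset(c(25, 10, 10, 40, 5), seed = 2))
  spb <- split_dataset(big)
  frac <- nrow(spb$test) / nrow(big)
  expect_gte(frac, 0.18)
  expect_lte(frac, 0.22)
})

test_that("network construction is seeded and softmax outputs normalize", {
  m1 <- build_cnn(c(32, 64), 5, seed = 7)
  m2 <- build_cnn(c(32, 64), 5, seed = 7)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_cnn(c(32, 64), 5, seed = 8)
  expect_false(identical(m1$weights$W1, m3$weights$W1))
  # softmax normalization holds even for an untrained net
  x <- array(stats::runif(32 * 64 * 7), c(32, 64, 7))
  p <- predict(m1, x, type = "prob")
  expect_equal(dim(p), c(7L, 5L))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
  # class counts outside the study tasks need the override
  expect_error(build_cnn(c(32, 64), 3), "allow_any_k")
  expect_s3_class(build_cnn(c(32, 64), 3, allow_any_k = TRUE), "anuran_cnn")
})

test_that("parameter count matches hand arithmetic at the full input size", {
  # valid 3x3 convs + 2x2 pools on 128 x 435 x 1:
  # conv1 32*(9*1)+32 = 320; conv2 64*(9*32)+64 = 18496;
  # conv3 128*(9*64)+128 = 73856; maps 126x433 -> 63x216 -> 61x214 ->
  # 30x107 -> 28x105 -> 14x52; flatten 14*52*128 = 93184;
  # dense 93184*512+512 = 47710720; softmax 512*5+5 = 2565
  m <- build_cnn(c(128L, 435L), 5, seed = 1)
  expect_equal(n_params(m), 320 + 18496 + 73856 + 47710720 + 2565)
  expect_identical(dim(m$weights$W4), c(512L, 93184L))
})

test_that("training lowers the loss and is reproducible for a fixed seed", {
  feats <- fix_small_features()
  fit <- anuran_cnn(feats$train$x, feats$train$y, epochs = 3, seed = 1)
  h <- fit$history
  expect_equal(nrow(h), 3L)
  expect_gt(h$accuracy[3], h$accuracy[1])
  expect_lt(h$loss[3], h$loss[1])
  # identical seeds give identical final losses (single-threaded numerics)
  again <- anuran_cnn(feats$train$x, feats$train$y, epochs = 3, seed = 1)
  expect_identical(h$loss[3], again$history$loss[3])
  # empty training set and inconsistent label sets error out
  m <- build_cnn(c(32, 64), 5)
  expect_error(train_cnn(m, feats$train$x, character(0)), "empty")
  expect_error(train_cnn(m, feats$train$x,
                         merge_class(feats$train$y)), "inconsistent")
})

test_that("the merged four-class task consumes merged labels", {
  feats <- fix_small_features()
  y4 <- merge_class(feats$train$y)
  expect_setequal(unique(y4), merged_classes())
  fit4 <- anuran_cnn(feats$train$x, y4, n_classes = 4, epochs = 2, seed = 1)
  expect_identical(fit4$classes, merged_classes())
  expect_identical(fit4$n_classes, 4L)
  p <- predict(fit4, feats$test$x, type = "prob")
  expect_identical(colnames(p), merged_classes())
})

test_that("exported models round-trip with identical predictions", {
  feats <- fix_small_features()
  fit <- anuran_cnn(feats$train$x, feats$train$y, epochs = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  info <- export_model(fit, path)
  expect_true(file.exists(info$path))
  expect_gt(info$bytes, 0)
  expect_identical(info$bytes, as.numeric(file.size(path)))
  reloaded <- load_model(path)
  batch <- feats$test$x[, , 1:10]
  expect_identical(predict(fit, batch, type = "prob"),
                   predict(reloaded, batch, type = "prob"))
})
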