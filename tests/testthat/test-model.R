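# Network topology, probability contracts, training behavior.

test_that("CNN topology follows the no-padding shape arithmetic", {
  m <- build_model(cnn_spec(n_channels = 1), seed = 1)
  s <- model_summary(m)
  conv <- s[s$type == "conv2d", ]
  expect_equal(conv$output, c("60x60x16", "26x26x32"))
  pool <- s[s$type == "maxpool2", ]
  expect_equal(pool$output, c("30x30x16", "13x13x32"))
  expect_equal(s$output[s$type == "flatten"], "5408")
  # conv parameter counts: 5*5*C*F + F
  expect_equal(s$n_params[s$type == "conv2d"],
               c(5 * 5 * 1 * 16 + 16, 5 * 5 * 16 * 32 + 32))

  m3 <- build_model(cnn_spec(n_channels = 3), seed = 1)
  s3 <- model_summary(m3)
  expect_equal(s3$n_params[s3$type == "conv2d"][1], 5 * 5 * 3 * 16 + 16)
})

test_that("MLP topology carries the declared widths and regularizers", {
  m <- build_model(mlp_spec(), seed = 1)
  s <- model_summary(m)
  expect_equal(s$output[s$type == "dense"], c("500", "250", "150", "50", "2"))
  dl <- m$layers[vapply(m$layers, function(l) l$type == "dense", logical(1))]
  expect_equal(vapply(dl, function(l) l$l1, numeric(1)),
               c(0, 0, 1e-5, 0, 0))
  expect_equal(vapply(dl, function(l) l$l2, numeric(1)),
               c(0, 0, 1e-4, 0, 0))
  drops <- vapply(m$layers, function(l)
    if (l$type == "dropout") l$rate else NA_real_, numeric(1))
  expect_equal(drops[!is.na(drops)], c(0.4, 0.4, 0.4))
})

test_that("combined model fuses branch outputs into the 128-unit head", {
  m <- build_model(combined_spec(n_channels = 2), seed = 1)
  s <- model_summary(m)
  head_dense <- s[s$branch == "head" & s$type == "dense", ]
  expect_equal(head_dense$output, c("128", "2"))
  expect_equal(m$head[[1]]$n_in, 4)  # 2 + 2 softmax outputs

  mp <- build_model(combined_spec(n_channels = 2, fusion = "penultimate"),
                    seed = 1)
  expect_equal(mp$head[[1]]$n_in, 66)  # 50 + 16 hidden units
})

test_that("probabilities are normalized and symmetric at zeroed output weights", {
  set.seed(2)
  m <- build_model(mlp_spec(), seed = 2)
  X <- matrix(runif(10 * 15), 10)
  p <- predict_proba(m, X)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)

  # zero the output dense layer: softmax of (0,0) is (0.5, 0.5)
  k <- length(m$layers) - 1L
  m$layers[[k]]$params$W[] <- 0
  m$layers[[k]]$params$b[] <- 0
  p0 <- predict_proba(m, X)
  expect_true(all(abs(p0 - 0.5) < 1e-12))
})

test_that("input validation rejects mismatched shapes and degenerate labels", {
  m <- build_model(mlp_spec(), seed = 1)
  expect_error(predict_proba(m, matrix(1, 3, 7)), "feature width")
  mc <- build_model(cnn_spec(n_channels = 3), seed = 1)
  expect_error(predict_proba(mc, array(0, c(64, 64, 2, 3))), "64 x 64 x 3")
  X <- matrix(runif(20 * 15), 20)
  expect_error(train_model(m, X, rep(1, 20)), "single class")
  expect_error(train_model(m, X[0, ], integer(0)), "empty")
})

test_that("zero-epoch training is the identity on the weights", {
  m <- build_model(mlp_spec(), seed = 3)
  w_before <- m$layers[[1]]$params$W
  mt <- train_model(m, matrix(runif(40 * 15), 40), rep(c(0, 1), 20),
                    training_config(max_epochs = 0))
  expect_identical(mt$layers[[1]]$params$W, w_before)
  expect_equal(nrow(mt$history), 0)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(77)
  X <- matrix(runif(120 * 15), 120)
  y <- rep(c(0, 1), 60)
  cfg <- training_config(lr = 1e-3, max_epochs = 3, seed = 42)
  m1 <- train_model(build_model(mlp_spec(), seed = 42), X, y, cfg)
  m2 <- train_model(build_model(mlp_spec(), seed = 42), X, y, cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$layers[[1]]$params$W, m2$layers[[1]]$params$W)
})

test_that("the MLP separates well-separated Gaussian classes", {
  set.seed(7)
  n <- 1000
  X <- rbind(matrix(rnorm(n * 15, 0, 1), n), matrix(rnorm(n * 15, 1.5, 1), n))
  X <- (X - min(X)) / (max(X) - min(X))
  y <- rep(c(0, 1), each = n)
  m <- build_model(mlp_spec(), seed = 1)
  m <- train_model(m, X, y,
                   training_config(lr = 1e-3, max_epochs = 50, seed = 1))
  # training accuracy evaluated in inference mode
  acc <- mean(predict_label(m, X) == y)
  expect_gt(acc, 0.95)
  expect_lte(max(m$history$epoch), 50)
})

test_that("early stopping halts after patience epochs without improvement", {
  set.seed(19)
  # pure-noise labels: validation loss cannot improve for long
  X <- matrix(runif(200 * 15), 200)
  y <- rep(c(0, 1), 100)
  cfg <- training_config(lr = 1e-2, max_epochs = 40, patience = 2, seed = 3)
  m <- train_model(build_model(mlp_spec(), seed = 3), X, y, cfg)
  h <- m$history
  n_ep <- max(h$epoch)
  expect_lt(n_ep, 40)
  best <- which.min(h$val_loss)
  expect_equal(n_ep, best + 2)  # stopped exactly `patience` epochs later
})

test_that("combined model degrades gracefully with a zeroed image branch", {
  m <- build_model(combined_spec(n_channels = 3), seed = 5)
  x <- list(features = matrix(runif(4 * 15), 4),
            images = array(0, c(64, 64, 3, 4)))
  p <- predict_proba(m, x)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
})
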