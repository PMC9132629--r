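test_that("sigmoid is correct and stable at extreme inputs", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3.2, -0.5, 0.1, 7)
  expect_equal(sigmoid(-x), 1 - sigmoid(x))
  expect_equal(sigmoid(500), 1, tolerance = 1e-12)
  expect_gt(sigmoid(-500), 0)
  expect_lt(sigmoid(-500), 1e-200)
})

test_that("rmse matches hand computations", {
  expect_equal(rmse(matrix(c(1, 0)), matrix(c(1, 0))), 0)
  expect_equal(rmse(matrix(0.5), matrix(1)), 0.5)
  expect_equal(rmse(matrix(c(0, 1), 1), matrix(c(1, 1), 1)), sqrt(0.5))
  expect_error(rmse(matrix(numeric(0)), matrix(numeric(0))), "empty")
})

test_that("forward pass computes sigmoid layers and net excitation", {
  m <- bpnn_init(2, 3, 2, weight_init_scale = 1e-12, seed = 1)
  out <- bpnn_forward(m, c(0, 0))
  expect_equal(drop(out$output), c(0.5, 0.5), tolerance = 1e-9)
  # 1-1-1 net, unit weights, zero bias, x = 0: h = 0.5, o = sigmoid(0.5)
  m1 <- bpnn_init(1, 1, 1, seed = 1)
  m1$W_in_hidden[] <- 1; m1$W_hidden_out[] <- 1
  out1 <- bpnn_forward(m1, 0)
  expect_equal(drop(out1$hidden), 0.5)
  expect_equal(drop(out1$output), sigmoid(0.5))
  expect_equal(drop(out1$output), 0.62245933, tolerance = 1e-7)
  expect_true(all(out1$output > 0 & out1$output < 1))
  expect_error(bpnn_forward(m1, c(1, 2)), "features")
})

test_that("backward gradients vanish at a perfect fit and match structure", {
  m <- bpnn_init(3, 2, 2, seed = 3)
  x <- c(0.3, -1, 2)
  o <- drop(bpnn_forward(m, x)$output)
  g0 <- bpnn_backward(m, x, target = o)  # output equals target
  expect_true(all(abs(unlist(g0)) < 1e-15))
  # zero input: input-to-hidden weight gradients are exactly zero,
  # hidden bias gradients generally are not
  gz <- bpnn_backward(m, c(0, 0, 0), target = c(1, 0))
  expect_true(all(gz$W_in_hidden == 0))
  expect_true(any(gz$b_hidden != 0))
})

test_that("backward matches central finite differences on random nets", {
  set.seed(12)
  for (i in 1:5) {
    n_in <- sample(2:4, 1); n_h <- sample(2:4, 1); n_out <- sample(2:3, 1)
    m <- bpnn_init(n_in, n_h, n_out, weight_init_scale = 2, seed = i)
    x <- stats::rnorm(n_in)
    target <- as.numeric(seq_len(n_out) == sample(n_out, 1))
    expect_lt(gradient_gap(m, x, target), 1e-6)
  }
})

test_that("training is deterministic, inert at zero learning rate", {
  fm <- separable_fm(6)
  cfg <- bpnn_config(hidden_sizes_grid = 4, max_epochs = 30,
                     learning_rate = 0, seed = 9)
  m0 <- bpnn(fm, 4, cfg)
  expect_equal(length(unique(m0$history$train_rmse)), 1L)
  init <- bpnn_init(4, 4, 2, fm$class_names, 1,
                    stage_seed(9L, "bpnn_init4"))
  expect_equal(m0$W_in_hidden, init$W_in_hidden)
  cfg2 <- bpnn_config(hidden_sizes_grid = 4, max_epochs = 40, seed = 9)
  ma <- bpnn(fm, 4, cfg2); mb <- bpnn(fm, 4, cfg2)
  expect_identical(ma$W_in_hidden, mb$W_in_hidden)
  expect_identical(ma$history, mb$history)
  expect_error(bpnn(feature_matrix(matrix(1:4, 2), c("a", "a")), 4, cfg),
               "two classes")
})

test_that("a separable toy trains to low RMSE", {
  V <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  fm <- feature_matrix(V, c("a", "a", "b", "b"))
  cfg <- bpnn_config(hidden_sizes_grid = 4, max_epochs = 2000,
                     early_stop_patience = 2000, standardize = FALSE,
                     seed = 2)
  m <- bpnn(fm, 4, cfg)
  expect_lt(min(m$history$train_rmse), 0.15)
})

test_that("full-batch training reduces the loss on fixed data", {
  fm <- separable_fm(6)
  cfg <- bpnn_config(hidden_sizes_grid = 4, max_epochs = 100,
                     batch_mode = "full_batch", learning_rate = 0.5,
                     momentum = 0, early_stop_patience = 100, seed = 3)
  m <- bpnn(fm, 4, cfg)
  h <- m$history$train_rmse
  expect_lt(h[length(h)], h[1])
})

test_that("hidden-size selection minimizes validation RMSE with ties small", {
  fm <- separable_fm(8)
  cfg <- bpnn_config(hidden_sizes_grid = 4, max_epochs = 30, seed = 5)
  expect_identical(select_hidden_size(fm, cfg)$best, 4L)
  # identical sizes produce identical RMSE; the first (smaller) wins
  cfg2 <- bpnn_config(hidden_sizes_grid = c(4, 4), max_epochs = 20, seed = 5)
  sel2 <- select_hidden_size(fm, cfg2)
  expect_identical(sel2$table$val_rmse[1], sel2$table$val_rmse[2])
  expect_identical(sel2$best, 4L)
})

test_that("one hidden node cannot fit XOR but eight can", {
  V <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  V <- V[rep(1:4, each = 3), ] + 0  # replicate points for a sturdier fit
  fm <- feature_matrix(V, rep(c("a", "b", "b", "a"), each = 3))
  cfg <- bpnn_config(hidden_sizes_grid = c(1, 8), max_epochs = 1500,
                     early_stop_patience = 1500, standardize = FALSE,
                     learning_rate = 0.5, seed = 4)
  sel <- select_hidden_size(fm, cfg)
  expect_identical(sel$best, 8L)
  expect_lt(sel$table$val_rmse[sel$table$n_hidden == 8],
            sel$table$val_rmse[sel$table$n_hidden == 1])
})

test_that("prediction takes the argmax with ties to the lowest class", {
  m <- bpnn_init(2, 3, 2, weight_init_scale = 1e-14, seed = 6)
  # all outputs ~0.5: tie -> class 0
  expect_identical(predict(m, matrix(stats::rnorm(6), 3, 2)),
                   c(0L, 0L, 0L))
  m$W_hidden_out[, 2] <- 5  # output 2 dominates
  expect_identical(predict(m, matrix(stats::rnorm(4), 2, 2)), c(1L, 1L))
  expect_identical(predict(m, matrix(1, 1, 2), type = "label"),
                   m$class_names[2])
  expect_error(predict(m, matrix(1, 1, 3)), "features")
})

test_that("models persist through the JSON format", {
  fm <- separable_fm(5)
  m <- bpnn(fm, 4, bpnn_config(hidden_sizes_grid = 4, max_epochs = 20,
                               seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_bpnn(m, path)
  back <- read_bpnn(path)
  X <- matrix(stats::runif(12), 3, 4)
  expect_equal(predict(back, X, type = "prob"), predict(m, X, type = "prob"))
})
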