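test_that("geometric pyramid rule sizes the hidden layer", {
  expect_identical(hidden_size(100, 4), 20L)
  expect_identical(hidden_size(4465, 31), 372L)
  expect_identical(hidden_size(1900, 31), 243L)
  expect_identical(hidden_size(2, 1), 1L)
  expect_error(hidden_size(0, 3))
})

test_that("initialisation is seeded, bounded, and reproducible", {
  cfg <- mlp_config(20, 3, seed = 9)
  m1 <- init_mlp(cfg); m2 <- init_mlp(cfg)
  expect_identical(m1$hidden_weights, m2$hidden_weights)
  expect_identical(m1$output_weights, m2$output_weights)
  m3 <- init_mlp(mlp_config(20, 3, seed = 10))
  expect_false(identical(m1$hidden_weights, m3$hidden_weights))
  w <- c(m1$hidden_weights, m1$output_weights)
  expect_true(all(w >= -0.5 & w <= 0.5))
  expect_identical(dim(m1$hidden_weights),
                   c(cfg$n_hidden, 21L))  # bias column appended
  expect_identical(dim(m1$output_weights), c(3L, cfg$n_hidden + 1L))
})

test_that("forward pass stays strictly inside (0,1); zero weights give 0.5", {
  cfg <- mlp_config(10, 4, seed = 2)
  m <- init_mlp(cfg)
  set.seed(5)
  for (i in 1:5) {
    y <- mlp_forward(m, sample(0:1, 10, replace = TRUE))
    expect_true(all(y > 0 & y < 1))
  }
  m$hidden_weights[] <- 0
  m$output_weights[] <- 0
  expect_equal(unname(mlp_forward(m, rep(0, 10))), rep(0.5, 4))
})

test_that("permuting hidden units leaves the outputs unchanged", {
  cfg <- mlp_config(12, 3, n_hidden = 6, seed = 4)
  m <- init_mlp(cfg)
  x <- rep(c(1, 0), 6)
  y0 <- mlp_forward(m, x)
  perm <- c(3, 1, 6, 2, 4, 5)
  m2 <- m
  m2$hidden_weights <- m$hidden_weights[perm, , drop = FALSE]
  m2$output_weights <- cbind(m$output_weights[, perm, drop = FALSE],
                             m$output_weights[, 7])
  expect_equal(mlp_forward(m2, x), y0, tolerance = 1e-12)
})

test_that("rmse matches hand-computed arithmetic", {
  cfg <- mlp_config(2, 2, n_hidden = 2, seed = 1)
  m <- init_mlp(cfg)
  X <- rbind(c(0, 1), c(1, 0))
  Y <- rbind(mlp_forward(m, X[1, ]), mlp_forward(m, X[2, ]))
  # targets equal to outputs -> 0
  expect_equal(mlp_rmse(m, X, Y), 0)
  # one sample, one output unit, error 0.5 -> 0.5
  cfg1 <- mlp_config(2, 1, n_hidden = 2, seed = 1)
  m1 <- init_mlp(cfg1)
  y1 <- mlp_forward(m1, c(1, 0))
  expect_equal(mlp_rmse(m1, rbind(c(1, 0)), rbind(y1 + 0.5)), 0.5)
  # 2-sample 2-output case against direct arithmetic
  T2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(mlp_rmse(m, X, T2), sqrt(mean((Y - T2)^2)))
  expect_error(mlp_rmse(m, X[0, , drop = FALSE], T2[0, , drop = FALSE]),
               "empty")
})

test_that("backprop gradients agree with central finite differences", {
  cfg <- mlp_config(4, 2, n_hidden = 3, seed = 12)
  m <- init_mlp(cfg)
  x <- c(1, 0, 1, 1); t <- c(1, 0)
  g <- mlp_gradient(m, x, t)
  loss <- function(model) 0.5 * sum((mlp_forward(model, x) - t)^2)
  eps <- 1e-6
  num_grad <- function(field, i, j) {
    mp <- m; mp[[field]][i, j] <- mp[[field]][i, j] + eps
    mm <- m; mm[[field]][i, j] <- mm[[field]][i, j] - eps
    (loss(mp) - loss(mm)) / (2 * eps)
  }
  for (i in 1:3) for (j in 1:5)
    expect_equal(g$G1[i, j], num_grad("hidden_weights", i, j),
                 tolerance = 1e-6)
  for (i in 1:2) for (j in 1:4)
    expect_equal(g$G2[i, j], num_grad("output_weights", i, j),
                 tolerance = 1e-6)
})

test_that("online training converges on a small one-hot task", {
  set.seed(33)
  X <- matrix(sample(0:1, 3 * 250, replace = TRUE), nrow = 3)
  labels <- c("a", "b", "c")
  targets <- one_hot_targets(labels, labels)
  cfg <- mlp_config(250, 3, seed = 7)
  m <- train_online(init_mlp(cfg, labels), X, targets)
  expect_lte(mlp_rmse(m, X, targets), 0.01)
  preds <- apply(rbind(mlp_forward(m, X[1, ]), mlp_forward(m, X[2, ]),
                       mlp_forward(m, X[3, ])), 1, which.max)
  expect_identical(unname(preds), 1:3)  # 100% training argmax accuracy
  log <- attr(m, "rmse_log")
  expect_identical(length(log), attr(m, "epochs"))
  expect_lte(log[length(log)], 0.01)
})

test_that("training is deterministic given the seed", {
  set.seed(8)
  X <- matrix(sample(0:1, 2 * 100, replace = TRUE), nrow = 2)
  targets <- diag(2)
  cfg <- mlp_config(100, 2, seed = 21)
  m1 <- train_online(init_mlp(cfg), X, targets)
  m2 <- train_online(init_mlp(cfg), X, targets)
  expect_identical(m1$hidden_weights, m2$hidden_weights)
  expect_identical(attr(m1, "rmse_log"), attr(m2, "rmse_log"))
})

test_that("zero learning rate leaves the error log flat", {
  set.seed(9)
  X <- matrix(sample(0:1, 2 * 50, replace = TRUE), nrow = 2)
  cfg <- mlp_config(50, 2, learning_rate = 0, momentum = 0, max_epochs = 20)
  m <- train_online(init_mlp(cfg), X, diag(2))
  log <- attr(m, "rmse_log")
  expect_identical(length(log), 20L)
  expect_true(all(abs(log - log[1]) < 1e-12))
})

test_that("hitting the epoch cap raises an explicit non-convergence error", {
  set.seed(10)
  X <- matrix(sample(0:1, 2 * 50, replace = TRUE), nrow = 2)
  cfg <- mlp_config(50, 2, max_epochs = 2, seed = 3)
  expect_error(train_online(init_mlp(cfg), X, diag(2)),
               class = "genimage_nonconvergence")
})

test_that("model serialization round-trips exactly", {
  set.seed(11)
  X <- matrix(sample(0:1, 2 * 60, replace = TRUE), nrow = 2)
  cfg <- mlp_config(60, 2, seed = 5)
  m <- train_online(init_mlp(cfg, c("x", "y")), X, diag(2))
  path <- tempfile(fileext = ".json")
  save_mlp(m, path)
  m2 <- load_mlp(path)
  expect_equal(m2$hidden_weights, m$hidden_weights)
  expect_equal(m2$output_weights, m$output_weights)
  expect_identical(m2$label_order, m$label_order)
  expect_equal(mlp_forward(m2, X[1, ]), mlp_forward(m, X[1, ]))
})
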