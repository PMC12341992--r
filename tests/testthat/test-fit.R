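test_that("training on a constant target converges toward the constant", {
  n <- 60
  x <- matrix(rep(c(0.3, -0.2), each = n), n, 2)
  y <- rep(1.7, n)
  fit <- relu_net(x, y, spec = relu_spec(2, 8),
                  control = fast_control(seed = 2, n_restarts = 1))
  expect_lt(fit$train_mse, fit$epoch_loss[1])
  expect_lt(max(abs(fitted(fit) - 1.7)), 0.2)
})

test_that("training is reproducible given the seed", {
  d <- gen_sim1(120, "quadratic", seed = 5)
  f1 <- relu_net(d$x, d$y, kind = "shallow", control = fast_control(seed = 9))
  f2 <- relu_net(d$x, d$y, kind = "shallow", control = fast_control(seed = 9))
  expect_identical(coef(f1), coef(f2))
  p1 <- predict(f1, d$x)
  expect_identical(p1, predict(f1, d$x))
  f3 <- relu_net(d$x, d$y, kind = "shallow", control = fast_control(seed = 10))
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("the shallow fit reaches the irreducible noise level on quadratic data", {
  d <- gen_sim1(2000, "quadratic", seed = 11)
  fit <- relu_net(d$x, d$y, kind = "shallow",
                  control = relu_control(n_restarts = 3, seed = 11))
  # Bayes mean squared error is Var(eps) = 0.25
  expect_lt(abs(fit$train_mse - 0.25), 0.05)
})

test_that("training loss does not diverge on any simulation scenario", {
  scenarios <- list(
    gen_sim1(200, "quadratic", seed = 1),
    gen_sim1(200, "cosine", seed = 2),
    gen_sim2(200, seed = 3)
  )
  for (d in scenarios) {
    fit <- relu_net(d$x, d$y, kind = "shallow",
                    control = fast_control(seed = 4, n_restarts = 1))
    nl <- length(fit$epoch_loss)
    expect_lte(fit$epoch_loss[nl], fit$epoch_loss[1])
  }
})

test_that("the forward map implements the ReLU composition", {
  d <- gen_sim1(80, "quadratic", seed = 6)
  fit <- relu_net(d$x, d$y, spec = relu_spec(2, 6),
                  control = fast_control(seed = 6, n_restarts = 1))

  # all-zero parameters predict 0 everywhere
  zero <- fit
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  zero$biases <- lapply(zero$biases, function(b) b * 0)
  expect_equal(predict(zero, d$x), rep(0, nrow(d$x)))

  # single hidden unit, unit weights, zero biases: x -> max(x, 0)
  one <- fit
  one$spec <- relu_spec(1, 1)
  one$weights <- list(matrix(1, 1, 1), matrix(1, 1, 1))
  one$biases <- list(0, 0)
  xs <- matrix(seq(-2, 2, by = 0.5), ncol = 1)
  expect_equal(predict(one, xs), pmax(xs[, 1], 0))
})

test_that("bias terms break positive homogeneity; removing them restores it", {
  d <- gen_sim1(150, "quadratic", seed = 8)
  fit <- relu_net(d$x, d$y, kind = "shallow", control = fast_control(seed = 8))
  x <- matrix(c(0.4, -0.7, 0.1, 0.9), 2, 2)
  a <- 3
  # a bias-free ReLU network is positively homogeneous: f(a x) = a f(x)
  nobias <- fit
  nobias$biases <- lapply(nobias$biases, function(b) b * 0)
  expect_equal(predict(nobias, a * x), a * predict(nobias, x),
               tolerance = 1e-10)
  # the shipped default (biases trained) must violate homogeneity
  expect_gt(max(abs(predict(fit, a * x) - a * predict(fit, x))), 1e-4)
})

test_that("input validation rejects malformed fits and predictions", {
  d <- gen_sim1(50, "quadratic", seed = 1)
  expect_error(relu_net(d$x, d$y[-1]), "length")
  bad <- d$x; bad[1, 1] <- NA
  expect_error(relu_net(bad, d$y), "non-finite")
  fit <- relu_net(d$x, d$y, spec = relu_spec(2, 4),
                  control = fast_control(n_restarts = 1))
  expect_error(predict(fit, d$x[, 1, drop = FALSE]), "input_dim")
})

test_that("control objects validate and batch size covers the data", {
  expect_error(relu_control(epochs = 0), "epochs")
  expect_error(relu_control(learning_rate = -1), "learning_rate")
  expect_error(relu_control(dropout = 1), "dropout")
  ctl <- relu_control()
  expect_identical(ctl$epochs, 200L)
  expect_identical(ctl$num_batches, 20L)
  expect_identical(ctl$dropout, 0.05)
  # derived batch size ceiling(n / num_batches) covers the data each epoch
  for (n in c(100, 101, 119))
    expect_gte(ceiling(n / ctl$num_batches) * ctl$num_batches, n)
})
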