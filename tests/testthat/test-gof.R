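test_that("splits have the prescribed sizes and partition the sample", {
  s <- make_split(200, 0.1, seed = 1)
  expect_identical(s$m, 20L)
  expect_length(s$part2, 180L)

  s5 <- make_split(5, 0.5, seed = 1)
  expect_identical(s5$m, 2L)
  expect_length(s5$part2, 3L)

  expect_identical(make_split(100, 0.3, seed = 7),
                   make_split(100, 0.3, seed = 7))

  # partition invariants over random configurations
  set.seed(42)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    gamma <- runif(1, 0.05, 0.5)
    if (floor(gamma * n) < 2 || n - floor(gamma * n) < 2) next
    s <- make_split(n, gamma, seed = i)
    expect_identical(s$m, as.integer(floor(gamma * n)))
    expect_length(s$part1, s$m)
    expect_length(intersect(s$part1, s$part2), 0L)
    expect_setequal(c(s$part1, s$part2), seq_len(n))
  }

  expect_error(make_split(100, 0.6, seed = 1), "gamma")
  expect_error(make_split(100, 0, seed = 1), "gamma")
  expect_error(make_split(6, 0.1, seed = 1), "at least 2")
})

test_that("feature restriction drops exactly the tested columns", {
  x <- matrix(1:20, 5, 4, dimnames = list(NULL, paste0("x", 0:3)))
  expect_identical(restrict_features(x, "x0"),
                   x[, c("x1", "x2", "x3"), drop = FALSE])
  expect_identical(colnames(restrict_features(x, 3L)),
                   c("x0", "x1", "x3"))
  expect_error(restrict_features(x, 1:4), "at least one covariate")
  expect_error(restrict_features(x, integer(0)), "non-empty")
  expect_error(restrict_features(x, "x9"), "unknown column")
})

test_that("split_mse is the mean of squared residuals", {
  expect_identical(split_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(split_mse(c(1, 0, 2), c(0, 1, 2)), 2 / 3)
  expect_equal(split_mse(3.2, 0), 3.2^2)
  expect_error(split_mse(1:3, 1:2), "equal length")
})

test_that("kappa_hat matches its closed forms and is never negative", {
  expect_equal(kappa_hat(c(1, -1, 1, -1)), 0)
  expect_equal(kappa_hat(c(1, -1, 2, -2)), 2.25)
  # for Gaussian residuals kappa estimates Var(eps^2) = 2 sigma^4
  set.seed(1)
  r <- rnorm(1e5, 0, 0.5)
  expect_lt(abs(kappa_hat(r) - 0.125), 0.01)
  # fuzz: non-negativity is the power-mean inequality
  set.seed(2)
  for (i in 1:200) {
    v <- rnorm(sample(2:50, 1), sd = runif(1, 0.01, 10))
    expect_gte(kappa_hat(v), 0)
  }
  expect_error(kappa_hat(1), "at least 2")
})

test_that("the standardized statistic follows its definition", {
  expect_equal(gof_statistic(0.4, 0.4, 10, 30, 1), 0)
  expect_equal(gof_statistic(0.5, 0.3, 50, 100, 1), 1)
  expect_equal(gof_statistic(0.30, 0.25, 20, 200, 0.125), 0.6)
  # antisymmetry under exchanging the two parts
  set.seed(3)
  for (i in 1:50) {
    T0 <- runif(1); T1 <- runif(1)
    m <- sample(2:99, 1); n <- 100
    k <- runif(1, 0.01, 2)
    expect_equal(gof_statistic(T0, T1, m, n, k),
                 -gof_statistic(T1, T0, n - m, n, k))
  }
  expect_error(gof_statistic(1, 1, 10, 20, 0), "degenerate")
})

test_that("p-values are two-sided standard normal tails", {
  expect_identical(gof_pvalue(0), 1)
  expect_lt(abs(gof_pvalue(1.959964) - 0.05), 1e-4)
  expect_lt(gof_pvalue(10), 1e-20)
  expect_error(gof_pvalue(Inf), "finite")
})

test_that("oracle-predictor null statistics are standard normal", {
  # with the true regression function in place of both fits, the statistic
  # isolates the distribution theory: KS against N(0,1) must pass
  set.seed(2024)
  stats <- replicate(5000, oracle_gof_statistic(n = 2000, gamma = 0.5))
  ks <- suppressWarnings(stats::ks.test(stats, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(stats)), 0.05)
  expect_lt(abs(sd(stats) - 1), 0.05)
})

test_that("the linear t-test matches the reference least-squares fit", {
  # exact symmetry: slope 0, p = 1
  expect_equal(linear_t_test(matrix(c(-1, 0, 1)), c(1, 0, 1), 1), 1)

  set.seed(10)
  x <- matrix(runif(100, -1, 1), 50, 2)
  y <- 0.8 * x[, 1] + rnorm(50, 0, 0.5)
  ref <- summary(lm(y ~ x))$coefficients
  expect_equal(linear_t_test(x, y, 1), ref[2, 4], tolerance = 1e-8)
  expect_equal(linear_t_test(x, y, 2), ref[3, 4], tolerance = 1e-8)

  # rank deficiency is an input error
  xd <- cbind(x, x[, 1])
  expect_error(linear_t_test(xd, y, 1), "rank deficient")
})

test_that("linear t-test p-values are uniform under the null", {
  set.seed(11)
  ps <- replicate(2000, {
    x <- matrix(runif(120, -1, 1), 60, 2)
    y <- x[, 2]^2 + rnorm(60, 0, 0.5)
    linear_t_test(x, y, 1)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("gof_test runs end to end and reports a coherent result bundle", {
  d <- gen_sim1(300, "quadratic", seed = 21)
  res <- gof_test(d$x, d$y, S = "x1", kind = "shallow", gamma = 0.5,
                  control = fast_control(seed = 21))
  expect_s3_class(res, "gof_test")
  expect_s3_class(res, "htest")
  expect_gte(res$p.value, 0)
  expect_lte(res$p.value, 1)
  expect_gte(res$estimate[["kappa.hat"]], 0)
  expect_identical(unname(res$parameter[["m"]]), 150)
  # statistic consistent with its components
  expect_equal(
    unname(res$statistic),
    gof_statistic(res$estimate[["T0"]], res$estimate[["T1"]],
                  150, 300, res$estimate[["kappa.hat"]])
  )
  # the null network never sees the tested covariate
  expect_identical(res$fit_null$spec$input_dim, 1L)
  expect_identical(res$fit_alt$spec$input_dim, 2L)
  # determinism of the full pipeline
  res2 <- gof_test(d$x, d$y, S = "x1", kind = "shallow", gamma = 0.5,
                   control = fast_control(seed = 21))
  expect_identical(res$p.value, res2$p.value)
  # tidy serialization
  row <- as.data.frame(res)
  expect_identical(nrow(row), 1L)
  expect_named(row, c("n", "gamma", "kind", "S", "T0", "T1", "kappa_hat",
                      "statistic", "p_value", "seed"))
})

test_that("a degenerate response raises the degenerate-variance error", {
  x <- matrix(runif(200, -1, 1), 100, 2)
  y <- rep(0, 100)
  expect_error(
    gof_test(x, y, S = 1L, control = fast_control(n_restarts = 1)),
    "degenerate"
  )
})

test_that("per-split architecture sizing uses each part's own sample size", {
  d <- gen_sim1(1000, "quadratic", seed = 30)
  res <- gof_test(d$x, d$y, S = "x0", kind = "shallow", gamma = 0.1,
                  control = fast_control(seed = 30, n_restarts = 1))
  # m = 100 -> width 4; n - m = 900 -> width 9
  expect_identical(res$fit_null$spec$hidden_widths, 4L)
  expect_identical(res$fit_alt$spec$hidden_widths, 9L)
  res_tot <- gof_test(d$x, d$y, S = "x0", kind = "shallow", gamma = 0.1,
                      control = fast_control(seed = 30, n_restarts = 1),
                      arch_n = "total")
  expect_identical(res_tot$fit_null$spec$hidden_widths, 10L)
  expect_identical(res_tot$fit_alt$spec$hidden_widths, 10L)
})
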