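#' Randomly split a sample into two parts
#'
#' Draws a uniformly random partition of `1:n` into a first part of size
#' `m = floor(gamma * n)` and a second part of size `n - m`, reproducibly
#' given `seed`. The first part fits the null model, the second the
#' alternative.
#'
#' @param n Total sample size.
#' @param gamma Proportion of the first part, in `(0, 0.5]`.
#' @param seed Integer seed.
#' @return An object of class `"gof_split"`: a list with `n`, `gamma`, `m`,
#'   `part1`, `part2`.
#' @examples
#' s <- make_split(200, 0.1, seed = 1)
#' s$m            # 20
#' length(s$part2) # 180
#' @export
make_split <- function(n, gamma, seed = 1L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 0.5)
    stop("`gamma` must be in (0, 0.5]", call. = FALSE)
  n <- as.integer(n)
  m <- as.integer(floor(gamma * n))
  if (m < 2L || n - m < 2L)
    stop("both parts of the split must have at least 2 points ",
         "(n = ", n, ", gamma = ", gamma, " gives m = ", m, ")",
         call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  structure(
    list(n = n, gamma = gamma, m = m, seed = as.integer(seed),
         part1 = sort(idx[seq_len(m)]), part2 = sort(idx[(m + 1L):n])),
    class = "gof_split"
  )
}

#' Drop the covariate columns under test
#'
#' Returns the covariate matrix with the columns in `S` removed, preserving
#' the order of the remaining columns; the result is the input matrix of
#' the null-model network.
#'
#' @param x Covariate matrix.
#' @param S Columns under test: integer positions (1-based) or column names.
#' @return The matrix without the `S` columns.
#' @export
restrict_features <- function(x, S) {
  x <- as.matrix(x)
  S <- resolve_columns(x, S)
  if (length(S) >= ncol(x))
    stop("`S` must leave at least one covariate for the null model; ",
         "an input-free network is not supported", call. = FALSE)
  x[, -S, drop = FALSE]
}

# S as names or 1-based positions -> validated integer positions
resolve_columns <- function(x, S) {
  if (length(S) < 1L) stop("`S` must be non-empty", call. = FALSE)
  if (is.character(S)) {
    pos <- match(S, colnames(x))
    if (anyNA(pos))
      stop("unknown column(s): ", paste(S[is.na(pos)], collapse = ", "),
           call. = FALSE)
    S <- pos
  }
  S <- as.integer(S)
  if (anyNA(S) || any(S < 1L) || any(S > ncol(x)) || anyDuplicated(S))
    stop("`S` must be distinct column positions in 1..", ncol(x),
         call. = FALSE)
  S
}

#' Mean squared error of a fit
#'
#' @param y Observed responses.
#' @param yhat Fitted values of the same length.
#' @return `mean((y - yhat)^2)`.
#' @export
split_mse <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("`y` and `yhat` must have equal length", call. = FALSE)
  if (length(y) < 1L) stop("empty input", call. = FALSE)
  mean((y - yhat)^2)
}

#' Variance-of-squared-residuals estimator
#'
#' The plug-in normalizer of the goodness-of-fit statistic,
#' \deqn{\hat\kappa_n = \frac1n \sum r_i^4 - \Big(\frac1n \sum r_i^2\Big)^2,}
#' computed from the null-model residuals over all \eqn{n} points. It is
#' non-negative for any real residual vector (power-mean inequality) and
#' estimates \eqn{Var(\epsilon^2)}, the asymptotic variance driver of each
#' split-specific mean squared error.
#'
#' @param residuals Numeric vector of residuals, length >= 2.
#' @return A non-negative number.
#' @examples
#' kappa_hat(c(1, -1, 2, -2)) # 8.5 - 6.25 = 2.25
#' @export
kappa_hat <- function(residuals) {
  if (length(residuals) < 2L)
    stop("need at least 2 residuals", call. = FALSE)
  mean(residuals^4) - mean(residuals^2)^2
}

#' Standardized goodness-of-fit statistic
#'
#' \deqn{T = \frac{T_0 - T_1}{\sqrt{(1/m + 1/(n-m))\,\hat\kappa}},}
#' where \eqn{T_0} is the null-model MSE on the first part (size \eqn{m})
#' and \eqn{T_1} the alternative-model MSE on the second part. Under the
#' null and the growth condition, \eqn{T} is asymptotically standard
#' normal.
#'
#' @param T0,T1 The two split-specific mean squared errors.
#' @param m,n First-part and total sample sizes, `0 < m < n`.
#' @param kappa Positive variance estimate (see [kappa_hat()]).
#' @return The standardized statistic.
#' @export
gof_statistic <- function(T0, T1, m, n, kappa) {
  if (!(m > 0 && m < n)) stop("need 0 < m < n", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0)
    stop("`kappa` must be finite and non-negative", call. = FALSE)
  if (kappa == 0)
    stop("degenerate variance: kappa_hat is 0, residuals are numerically ",
         "constant; the standardized statistic is undefined", call. = FALSE)
  (T0 - T1) / sqrt((1 / m + 1 / (n - m)) * kappa)
}

#' Two-sided normal p-value
#'
#' `2 * (1 - pnorm(abs(t)))`, the p-value of a two-sided Z-test.
#'
#' @param t Observed statistic (finite).
#' @return A p-value in `[0, 1]`.
#' @export
gof_pvalue <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a single finite number", call. = FALSE)
  2 * pnorm(-abs(t))
}

#' Goodness-of-fit significance test for covariates
#'
#' Tests the null hypothesis that the covariates in `S` are not significant
#' in the nonparametric regression of `y` on `x`. The sample is randomly
#' split; the first part (proportion `gamma`) trains a ReLU network on the
#' covariates *not* in `S` and yields `T0`, its in-sample mean squared
#' error; the second part trains a network on all covariates and yields
#' `T1`. The standardized difference (see [gof_statistic()]) is referred to
#' a standard normal, two-sided.
#'
#' The architecture of each network follows the `kind` rule
#' ([build_architecture()]) scaled, by default, to its own training-part
#' size (`arch_n = "split"`); `arch_n = "total"` scales both to `n`.
#' `evaluation = "heldout_null"` is an alternative convention in which both
#' networks are trained on the second part and `T0` is computed
#' out-of-sample on the first part; the default trains and evaluates each
#' network on its own part, matching the statistic's definition.
#'
#' @param x Covariate matrix (samples in rows; column names optional).
#' @param y Response vector.
#' @param S Covariates under test: column names or 1-based positions. Must
#'   leave at least one covariate for the null model.
#' @param kind Architecture rule: `"shallow"`, `"deep1"` or `"deep2"`.
#' @param gamma Split proportion in `(0, 0.5]` (default 0.5).
#' @param control A [relu_control()]; its `seed` drives the split and both
#'   trainings.
#' @param arch_n `"split"` (default) or `"total"`: which sample size the
#'   architecture rule is applied to.
#' @param evaluation `"in_sample"` (default) or `"heldout_null"`.
#' @return An object of classes `"gof_test"` and `"htest"` with components
#'   `statistic` (T), `p.value`, `estimate` (T0, T1, kappa_hat),
#'   `parameter` (m, n, gamma), plus `split`, `fit_null`, `fit_alt`.
#' @examples
#' d <- gen_sim1(400, "quadratic", seed = 7)
#' gof_test(d$x, d$y, S = "x1", gamma = 0.5,
#'          control = relu_control(n_restarts = 2, seed = 7))
#' @export
gof_test <- function(x, y, S, kind = c("shallow", "deep1", "deep2"),
                     gamma = 0.5, control = relu_control(),
                     arch_n = c("split", "total"),
                     evaluation = c("in_sample", "heldout_null")) {
  kind <- match.arg(kind)
  arch_n <- match.arg(arch_n)
  evaluation <- match.arg(evaluation)
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("rows(x) must equal length(y)", call. = FALSE)
  S <- resolve_columns(x, S)
  if (stats::var(y) == 0)
    stop("degenerate response: `y` is constant, every fit is exact and ",
         "kappa_hat is 0, so the standardized statistic is undefined",
         call. = FALSE)
  x_null <- restrict_features(x, S)

  split <- make_split(n, gamma, seed = control$seed)
  m <- split$m
  p1 <- split$part1
  p2 <- split$part2

  size_null <- if (arch_n == "split") {
    if (evaluation == "heldout_null") n - m else m
  } else n
  size_alt <- if (arch_n == "split") n - m else n

  ctl_null <- control
  ctl_alt <- control
  ctl_alt$seed <- restart_seed(control$seed, 5000L)

  spec_null <- build_architecture(kind, n = size_null,
                                  input_dim = ncol(x_null),
                                  dropout_rate = control$dropout)
  spec_alt <- build_architecture(kind, n = size_alt, input_dim = ncol(x),
                                 dropout_rate = control$dropout)

  if (evaluation == "in_sample") {
    fit_null <- relu_net(x_null[p1, , drop = FALSE], y[p1], spec = spec_null,
                         control = ctl_null)
    T0 <- split_mse(y[p1], predict(fit_null, x_null[p1, , drop = FALSE]))
  } else {
    fit_null <- relu_net(x_null[p2, , drop = FALSE], y[p2], spec = spec_null,
                         control = ctl_null)
    T0 <- split_mse(y[p1], predict(fit_null, x_null[p1, , drop = FALSE]))
  }
  fit_alt <- relu_net(x[p2, , drop = FALSE], y[p2], spec = spec_alt,
                      control = ctl_alt)
  T1 <- split_mse(y[p2], predict(fit_alt, x[p2, , drop = FALSE]))

  resid_all <- y - predict(fit_null, x_null)
  kap <- kappa_hat(resid_all)
  stat <- gof_statistic(T0, T1, m, n, kap)

  cols <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  out <- list(
    statistic = c(T = stat),
    p.value = gof_pvalue(stat),
    estimate = c(T0 = T0, T1 = T1, kappa.hat = kap),
    parameter = c(m = m, n = n, gamma = gamma),
    alternative = "two.sided",
    method = paste0("Split-sample goodness-of-fit test (", kind,
                    " ReLU network)"),
    data.name = paste0("y on ", ncol(x), " covariates; S = {",
                       paste(cols[S], collapse = ", "), "}"),
    S = S, kind = kind, split = split,
    fit_null = fit_null, fit_alt = fit_alt,
    seed = control$seed
  )
  class(out) <- c("gof_test", "htest")
  out
}

#' One-row data frame summary of a test
#'
#' Serializes a [gof_test()] result to a tidy row suitable for CSV output.
#'
#' @param x A `"gof_test"` object.
#' @param ... Unused.
#' @export
as.data.frame.gof_test <- function(x, ...) {
  data.frame(
    n = unname(x$parameter["n"]), gamma = unname(x$parameter["gamma"]),
    kind = x$kind, S = paste(x$S, collapse = ";"),
    T0 = unname(x$estimate["T0"]), T1 = unname(x$estimate["T1"]),
    kappa_hat = unname(x$estimate["kappa.hat"]),
    statistic = unname(x$statistic), p_value = x$p.value, seed = x$seed,
    stringsAsFactors = FALSE
  )
}

#' Linear-regression t-test baseline
#'
#' Two-sided p-value of the t-test for the coefficient of covariate `j` in
#' an ordinary least-squares fit of `y` on all columns of `x` plus an
#' intercept — the standard linear-model screen the goodness-of-fit test is
#' compared against.
#'
#' @param x Covariate matrix.
#' @param y Response vector.
#' @param j Column under test: 1-based position or column name.
#' @return A p-value in `[0, 1]`.
#' @export
linear_t_test <- function(x, y, j) {
  x <- as.matrix(x)
  j <- resolve_columns(x, j)
  if (length(j) != 1L) stop("`j` must be a single column", call. = FALSE)
  if (nrow(x) <= ncol(x) + 1L)
    stop("need n > p + 1 for the t-test", call. = FALSE)
  fit <- stats::lm(y ~ x)
  if (anyNA(coef(fit)))
    stop("design matrix (with intercept) is rank deficient", call. = FALSE)
  unname(summary(fit)$coefficients[j + 1L, 4L])
}
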