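#' Describe a feed-forward ReLU network architecture
#'
#' A network specification records the input dimension, the widths of the
#' hidden layers and the dropout rate of the class of regression networks
#' \deqn{f(x) = W_{L+1}\,\sigma(W_L\,\sigma(\cdots W_2\,\sigma(W_1 x)))}
#' with \eqn{\sigma(x) = \max(x, 0)} applied elementwise, a single linear
#' output unit, and bias terms in every layer.
#'
#' @param input_dim Number of input covariates (positive integer).
#' @param hidden_widths Integer vector of hidden-layer widths, one entry per
#'   hidden layer; must be non-empty and all positive.
#' @param dropout_rate Dropout probability applied to every hidden unit
#'   during training, in `[0, 1)`.
#' @return An object of class `"relu_spec"`.
#' @seealso [build_architecture()] for the sample-size indexed rules,
#'   [count_parameters()], [growth_condition_ratio()].
#' @examples
#' relu_spec(2, c(10))
#' relu_spec(4, rep(18, 5), dropout_rate = 0.05)
#' @export
relu_spec <- function(input_dim, hidden_widths, dropout_rate = 0.05) {
  input_dim <- as.integer(input_dim)
  hidden_widths <- as.integer(hidden_widths)
  if (length(input_dim) != 1L || is.na(input_dim) || input_dim < 1L)
    stop("`input_dim` must be a single positive integer", call. = FALSE)
  if (length(hidden_widths) < 1L || anyNA(hidden_widths) ||
      any(hidden_widths < 1L))
    stop("`hidden_widths` must be a non-empty vector of positive integers",
         call. = FALSE)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be a probability in [0, 1)", call. = FALSE)
  structure(
    list(input_dim = input_dim, hidden_widths = hidden_widths,
         dropout_rate = dropout_rate, activation = "relu", output_dim = 1L),
    class = "relu_spec"
  )
}

#' @export
print.relu_spec <- function(x, ...) {
  cat("ReLU network spec:", x$input_dim, "->",
      paste(x$hidden_widths, collapse = " -> "), "-> 1 (linear)\n")
  cat("  hidden layers:", length(x$hidden_widths),
      " dropout:", x$dropout_rate,
      " parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Sample-size indexed architecture rules
#'
#' Three admissible ways to grow a ReLU network with the sample size, all
#' satisfying the growth condition sufficient for asymptotic normality of
#' the goodness-of-fit statistic (see [growth_condition_ratio()]):
#' \describe{
#'   \item{`shallow`}{one hidden layer of \eqn{\lfloor n^{1/3} \rfloor} units
#'     (bounded depth, growing width);}
#'   \item{`deep1`}{\eqn{\lfloor n^{1/3} \rfloor} hidden layers of 18 units
#'     each (bounded width, growing depth);}
#'   \item{`deep2`}{\eqn{\lfloor n^{1/4} \rfloor} hidden layers of
#'     \eqn{\lfloor n^{1/4} \rfloor} units each (both growing).}
#' }
#'
#' @param kind One of `"shallow"`, `"deep1"`, `"deep2"`.
#' @param n Sample size the architecture is scaled to; must be at least 8 so
#'   every floor is positive.
#' @param input_dim Number of input covariates.
#' @param dropout_rate Dropout probability; default 0.05.
#' @return A [relu_spec()] object.
#' @examples
#' build_architecture("shallow", n = 1000, input_dim = 2) # one layer of 10
#' build_architecture("deep2", n = 2000, input_dim = 4)   # 6 layers of 6
#' @export
build_architecture <- function(kind = c("shallow", "deep1", "deep2"), n,
                               input_dim, dropout_rate = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 8)
    stop("`n` must be a single sample size >= 8", call. = FALSE)
  # guard against 1000^(1/3) = 9.999... flooring to 9
  root <- function(n, k) as.integer(floor(n^(1 / k) + 1e-9))
  widths <- switch(kind,
    shallow = root(n, 3),
    deep1   = rep(18L, root(n, 3)),
    deep2   = rep(root(n, 4), root(n, 4))
  )
  relu_spec(input_dim, widths, dropout_rate)
}

#' Count trainable parameters of a network specification
#'
#' Total number of weights and biases across all layers, i.e. the length of
#' the flattened parameter vector that training optimizes.
#'
#' @param spec A [relu_spec()] object.
#' @return A non-negative integer.
#' @examples
#' count_parameters(relu_spec(2, 10)) # (2*10+10) + (10*1+1) = 41
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "relu_spec"))
  dims <- c(spec$input_dim, spec$hidden_widths, 1L)
  total <- 0L
  for (l in seq_len(length(dims) - 1L))
    total <- total + dims[l] * dims[l + 1L] + dims[l + 1L]
  as.integer(total)
}

#' Growth-condition diagnostic for a network/sample-size pair
#'
#' The asymptotic normality of the split-sample goodness-of-fit statistic
#' holds when \eqn{B_n L_n \log(B_n) \log(n) = o(n)}, where \eqn{B_n} is the
#' number of network parameters and \eqn{L_n} the number of hidden layers.
#' This returns the finite-sample ratio
#' \eqn{B_n L_n \ln(B_n) \ln(n) / n} as a diagnostic; smaller is better, and
#' for the shipped architecture rules it decreases in \eqn{n}. It is a
#' guide, not a hard gate.
#'
#' @param spec A [relu_spec()] object with at least 2 parameters.
#' @param n Sample size (>= 2).
#' @return A non-negative number.
#' @examples
#' growth_condition_ratio(build_architecture("shallow", 1000, 2), 1000)
#' @export
growth_condition_ratio <- function(spec, n) {
  stopifnot(inherits(spec, "relu_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single sample size >= 2", call. = FALSE)
  B <- count_parameters(spec)
  if (B < 2) stop("spec must have at least 2 parameters", call. = FALSE)
  L <- length(spec$hidden_widths)
  B * L * log(B) * log(n) / n
}
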