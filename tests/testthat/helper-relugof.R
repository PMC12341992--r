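# Shared helpers for the test suite.

# fast training control for tests that only need a working fit
fast_control <- function(seed = 1L, n_restarts = 2L, ...) {
  relu_control(n_restarts = n_restarts, seed = seed, ...)
}

# the study-condition control (shipped defaults)
study_control <- function(seed = 1L) relu_control(seed = seed)

# oracle split-statistic: both model fits replaced by the true regression
# function, isolating the distribution theory of the statistic from
# network training. Returns one standardized statistic.
oracle_gof_statistic <- function(n, gamma, noise_sd = 0.5) {
  m <- floor(gamma * n)
  eps <- rnorm(n, 0, noise_sd)  # residuals under a perfect fit
  T0 <- mean(eps[seq_len(m)]^2)
  T1 <- mean(eps[(m + 1):n]^2)
  gof_statistic(T0, T1, m, n, kappa_hat(eps))
}

# empirical rejection rate helper shared by the acceptance-style tests
gof_rate <- function(reps, method, signal, n, S, gamma, base_seed = 0L) {
  rejection_rate(method, signal, n = n, S = S, gamma = gamma, reps = reps,
                 base_seed = base_seed)$rate
}
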