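# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the tetrachoric oracle maximizes the
# multinomial likelihood by golden-section search with mvtnorm orthants,
# the logistic oracle is a generic optimizer on the Bernoulli
# log-likelihood, and the orthant oracle is plain Monte Carlo.

oracle_tetrachoric <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  t1 <- qnorm(1 - (n11 + n10) / n)
  t2 <- qnorm(1 - (n11 + n01) / n)
  loglik <- function(r) {
    S <- matrix(c(1, r, r, 1), 2)
    p11 <- mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf), corr = S,
                            algorithm = mvtnorm::Miwa(steps = 512))[1]
    p10 <- mvtnorm::pmvnorm(lower = c(t1, -Inf), upper = c(Inf, t2), corr = S,
                            algorithm = mvtnorm::Miwa(steps = 512))[1]
    p01 <- mvtnorm::pmvnorm(lower = c(-Inf, t2), upper = c(t1, Inf), corr = S,
                            algorithm = mvtnorm::Miwa(steps = 512))[1]
    p00 <- 1 - p11 - p10 - p01
    sum(c(n11, n10, n01, n00) * log(pmax(c(p11, p10, p01, p00), 1e-300)))
  }
  stats::optimize(loglik, c(-0.999, 0.999), maximum = TRUE,
                  tol = 1e-10)$maximum
}

oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  o <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  o$par
}

mc_orthant <- function(S, lower, upper, n_draws, seed) {
  set.seed(seed)
  L <- chol(S)
  hits <- 0
  per <- 2e6
  left <- n_draws
  while (left > 0) {
    m <- min(per, left)
    Z <- matrix(rnorm(m * 4), ncol = 4) %*% L
    ok <- rep(TRUE, m)
    for (j in 1:4) ok <- ok & Z[, j] > lower[j] & Z[, j] <= upper[j]
    hits <- hits + sum(ok)
    left <- left - m
  }
  hits / n_draws
}

# small shared simulation used by several files (memoized per session)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fn()
  .sim_cache[[key]]
}

sibling_architecture <- function() {
  acde_params(A = c(0.59, 0.75), C = c(0.04, 0.05),
              r_A = 0.2, r_C = 0.03, r_E = -0.14)
}

register_thresholds <- function(shared = FALSE) {
  if (shared) threshold_spec(c(0.15, 0.0185))
  else threshold_spec(rbind(asthma = c(0.13, 0.17), asd = c(0.011, 0.026)))
}
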