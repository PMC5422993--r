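# Independent numeric likelihood-maximization oracle: BFGS (chained restarts,
# analytic gradient) on the same family log-likelihood kernels the IRLS
# fitter maximizes. For the gamma log link the shape-free kernel has the same
# maximizer as the full likelihood.
oracle_glm <- function(x, y, family) {
  negll <- function(b) {
    eta <- drop(x %*% b)
    switch(family,
           poisson = -sum(y * eta - exp(eta)),
           binomial = sum(log1p(exp(eta))) - sum(y * eta),
           gamma = sum(eta + y * exp(-eta)))
  }
  grad <- function(b) {
    eta <- drop(x %*% b)
    switch(family,
           poisson = -drop(crossprod(x, y - exp(eta))),
           binomial = -drop(crossprod(x, y - stats::plogis(eta))),
           gamma = drop(crossprod(x, 1 - y / exp(eta))))
  }
  b <- numeric(ncol(x))
  for (k in 1:3) {
    b <- stats::optim(b, negll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))$par
  }
  stats::setNames(b, colnames(x))
}

random_glm_dataset <- function(n, family, seed) {
  set.seed(seed)
  x <- cbind(1, matrix(stats::rnorm(n * 3), n))
  colnames(x) <- c("(Intercept)", "x1", "x2", "x3")
  eta <- drop(x %*% c(0.3, 0.4, -0.3, 0.2))
  y <- switch(family,
              poisson = stats::rpois(n, exp(eta)),
              binomial = stats::rbinom(n, 1, stats::plogis(eta)),
              gamma = stats::rgamma(n, 2, rate = 2 / exp(eta)))
  list(x = x, y = y)
}
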