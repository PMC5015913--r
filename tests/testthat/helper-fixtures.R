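# Shared fixture builders; everything is generated in code under fixed seeds.

tiny_registry <- function(n = 3, seed = 101) make_state_registry(n, seed = seed)

# a registry with hand-set latent weights, for closed-form checks
manual_registry <- function(d_sub) {
  n <- length(d_sub)
  reg <- make_state_registry(n, seed = 1)
  reg$truth[paste0("S", sprintf("%03d", seq_len(n)))] <- d_sub
  reg
}

# brute-force probit log-likelihood over a design, used as the grid oracle
probit_loglik_oracle <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * pnorm(eta, log.p = TRUE) + (1 - y) * pnorm(-eta, log.p = TRUE))
}

# coordinate-refined exhaustive grid search maximising the probit likelihood
probit_grid_oracle <- function(X, y, lower = -3, upper = 5) {
  p <- ncol(X)
  beta <- rep(0, p)
  width <- (upper - lower) / 2
  centre <- rep((upper + lower) / 2, p)
  for (stage in 1:5) {
    step <- width / 10
    for (sweep in 1:3) {
      for (j in seq_len(p)) {
        grid <- seq(centre[j] - width, centre[j] + width, by = step)
        ll <- vapply(grid, function(b) {
          bb <- beta; bb[j] <- b
          probit_loglik_oracle(bb, X, y)
        }, numeric(1))
        beta[j] <- grid[which.max(ll)]
      }
    }
    centre <- beta
    width <- step * 2
  }
  beta
}

# interval-censored log-normal likelihood on a single state: grid oracle
interval_grid_oracle <- function(lo, hi, mu_range, sigma_range) {
  grid_mu <- seq(mu_range[1], mu_range[2], length.out = 201)
  grid_sd <- seq(sigma_range[1], sigma_range[2], length.out = 101)
  ll <- outer(grid_mu, grid_sd, Vectorize(function(m, s)
    sum(log(pmax(pnorm((log(hi) - m) / s) - pnorm((log(lo) - m) / s),
                 1e-300)))))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  list(mu = grid_mu[best[1]], sigma = grid_sd[best[2]], loglik = max(ll))
}
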