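# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# NB density straight from the Gamma-term formula, no log-space tricks.
oracle_nb_density <- function(x, mu, theta) {
  gamma(x + theta) / (gamma(theta) * gamma(x + 1)) *
    (mu / (theta + mu))^x * (theta / (theta + mu))^theta
}

# Dense grid-search maximizer of the NB profile log-likelihood over log theta.
oracle_theta_grid <- function(x, lo = 1e-3, hi = 1e5, n_grid = 4000) {
  lt <- seq(log(lo), log(hi), length.out = n_grid)
  ll <- vapply(lt, function(l) {
    th <- exp(l)
    m <- mean(x)
    sum(lgamma(x + th) - lgamma(th) - lgamma(x + 1) +
          x * log(m / (th + m)) + th * log(th / (th + m)))
  }, numeric(1))
  list(log_theta = lt[which.max(ll)], step = lt[2] - lt[1],
       max_ll = max(ll))
}

# ARI by exhaustive pair counting: classify every sample pair as
# together/apart in each partition and apply the Hubert-Arabie closed form.
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)  # both partitions degenerate alike
  2 * (n11 * n00 - n10 * n01) / denom
}

# A small, quickly separable simulated dataset for EM tests.
quick_sim <- function(n = 40, g = 30, k = 2, delta_mu = 2, seed = 1, ...) {
  simulate_nbmix_counts(
    nbmix_scenario(n = n, g = g, k = k, delta_mu = delta_mu, seed = seed,
                   ...))
}
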