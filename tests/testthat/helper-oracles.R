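# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive loops / exhaustive sums.

# likelihood of one pattern given a full coupling assignment (scalar, naive)
oracle_pattern_lik <- function(J, x, x0hat, sigma, tau = 0) {
  arg <- x0hat * (sum(J * x) + tau)
  if (sigma == 0) {
    if (arg > 0) 1 else if (arg < 0) 0 else 0.5
  } else pnorm(arg / sigma)
}

# exact factor->variable message (exhaustive sum over all cavity couplings)
oracle_factor_message <- function(p_msgs, x, x0hat, i, mu, sigma, tau = 0) {
  N <- nrow(x)
  others <- setdiff(seq_len(N), i)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), length(others))))
  out <- numeric(3)
  for (jv in 1:3) {
    J_i <- c(-1, 0, 1)[jv]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      J <- numeric(N)
      J[others] <- grid[g, ]
      J[i] <- J_i
      w <- prod(vapply(seq_along(others), function(k)
        p_msgs[others[k], mu, grid[g, k] + 2], numeric(1)))
      tot <- tot + w * oracle_pattern_lik(J, x[, mu], x0hat[mu], sigma, tau)
    }
    out[jv] <- tot
  }
  out / sum(out)
}

# cavity means/variances by the naive O(N^2) double loop
oracle_cavity <- function(p_msgs, x) {
  N <- nrow(x); M <- ncol(x)
  t_cav <- matrix(0, N, M); d2 <- matrix(0, N, M)
  for (i in seq_len(N)) for (mu in seq_len(M)) {
    for (j in seq_len(N)) {
      if (j == i) next
      pj <- p_msgs[j, mu, ]
      m1 <- pj[3] - pj[1]
      m2 <- pj[3] + pj[1]
      t_cav[i, mu] <- t_cav[i, mu] + m1 * x[j, mu]
      d2[i, mu] <- d2[i, mu] + (m2 - m1^2) * x[j, mu]^2
    }
  }
  list(t = t_cav, delta2 = d2)
}

# deterministic error count by a per-pattern loop
oracle_cost <- function(J, x, x0hat, tau = 0) {
  n <- 0
  for (mu in seq_len(ncol(x))) {
    lam <- sum(J * x[, mu]) + tau
    if (x0hat[mu] * lam <= 0) n <- n + 1
  }
  n
}

# small random steady-state problem drawn from the planted model
random_problem <- function(N, M, sigma_gen = 0.3, seed = 1) {
  pl <- generate_planted_dataset(n_regulators = N, n_targets = 1,
                                 n_eff_true = min(2, N), M = M,
                                 sigma_gen = sigma_gen, seed = seed)
  bp_problem(pl$data, "T1", pl$candidates)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
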