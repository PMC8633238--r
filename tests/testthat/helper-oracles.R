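# Independent oracles used across the suite. Each is written from the
# definition it checks (brute force / enumeration / numerical
# differentiation), not by calling the package's own code path.

# Exact per-block binomial log-likelihood (includes the constant; the
# argmax is unaffected).
oracle_loglik <- function(alpha, k, n, p_T, p_N) {
  th <- pmin(pmax(alpha * p_T + (1 - alpha) * p_N, 1e-6), 1 - 1e-6)
  sum(dbinom(k, n, th, log = TRUE))
}

# Grid-search MLE on a fixed step; smallest alpha among tied maxima.
oracle_grid_fit <- function(blocks, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, oracle_loglik, numeric(1),
               k = blocks$k, n = blocks$n,
               p_T = blocks$p_T, p_N = blocks$p_N)
  grid[which(ll >= max(ll) - 1e-9)[1L]]
}

# Central-difference curvature of the EXPECTED log-likelihood at alpha0:
# E[l(a)] = sum_j n_j [ theta_j(a0) log theta_j(a) +
#                       (1 - theta_j(a0)) log(1 - theta_j(a)) ].
oracle_expected_curvature <- function(alpha0, blocks, h = 1e-5) {
  ell <- function(a) {
    th0 <- pmin(pmax(alpha0 * blocks$p_T + (1 - alpha0) * blocks$p_N,
                     1e-6), 1 - 1e-6)
    th  <- pmin(pmax(a * blocks$p_T + (1 - a) * blocks$p_N, 1e-6),
                1 - 1e-6)
    sum(blocks$n * (th0 * log(th) + (1 - th0) * log(1 - th)))
  }
  -(ell(alpha0 + h) - 2 * ell(alpha0) + ell(alpha0 - h)) / h^2
}

# Two-sided Fisher exact p for a 2x2 by direct hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  p_obs <- pr[xs == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating every assignment of the
# pooled ranks to group x (no ties assumed).
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U
  all_u <- apply(combn(N, nx), 2, function(idx) {
    sum(idx) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(all_u <= w_obs), mean(all_u >= w_obs)))
}

# Random small mixture-block instances for oracle-equivalence checks.
random_instance <- function(n_blocks_max = 20, n_max = 500) {
  nb <- sample(1:n_blocks_max, 1)
  n <- sample(1:n_max, nb, replace = TRUE)
  p_T <- runif(nb); p_N <- runif(nb)
  true_a <- runif(1)
  k <- rbinom(nb, n, pmin(pmax(true_a * p_T + (1 - true_a) * p_N, 0), 1))
  data.frame(k = k, n = n, p_T = p_T, p_N = p_N)
}
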