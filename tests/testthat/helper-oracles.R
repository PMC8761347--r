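# Independent oracles used to cross-check the package's own algorithms.

# Bracketing-bisection root of sum_k alive_k exp(-r_k m) = target, via
# stats::uniroot (independent of the package's safeguarded-Newton solver).
oracle_solve_rate <- function(alive, ratios, target, tol = 1e-14) {
  g <- function(m) sum(alive * exp(-ratios * m)) - target
  hi <- 1
  while (g(hi) > 0) hi <- hi * 2
  stats::uniroot(g, c(0, hi), tol = tol)$root
}

# Step-by-step loop simulation of the mortality recursion (independent of the
# vectorised cumulative-sum implementation).
oracle_simulate_alive <- function(N, m) {
  A <- numeric(length(m) + 1)
  A[1] <- N
  for (t in seq_along(m)) A[t + 1] <- A[t] * exp(-m[t])
  A
}

# Category-by-category summation of the RR-shift PIF.
oracle_pif <- function(p, means, rr, multiplier) {
  num <- 0
  den <- 0
  for (c in seq_along(p)) {
    den <- den + p[c] * rr^means[c]
    num <- num + p[c] * (rr^means[c] - rr^(means[c] * multiplier))
  }
  num / den
}

# Random solver instance with a known planted root.
random_solver_instance <- function(n, ratio_range = c(0.1, 10)) {
  alive <- stats::runif(n, 10, 1000)
  r <- c(1, stats::runif(n - 1, ratio_range[1], ratio_range[2]))
  m_true <- stats::runif(1, 0.001, 0.5)
  list(alive = alive, ratios = r, m_true = m_true,
       target = sum(alive * exp(-r * m_true)))
}
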