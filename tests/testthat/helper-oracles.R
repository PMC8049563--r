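# Independent oracles and parameter generators shared across the test files.

# Exact polymorphic configuration probabilities for outgroup-ascertained
# sites, built directly from the conditional-probability table (coalescence
# events H1/H2 with probabilities 1-alpha) with all new-mutation and
# within-branch terms set to zero, and hypergeometric downsampling of an
# ascertained four-sample spectrum b = (b1, b2, b3). Written independently
# of the package's estimator algebra.
ascertained_probs <- function(a1, a2, b) {
  b1 <- b[1]; b2 <- b[2]; b3 <- b[3]
  a21 <- b1 / 2 + 2 * b2 / 3 + b3 / 2
  a31 <- 3 * b1 / 4 + b2 / 2
  a32 <- b2 / 2 + 3 * b3 / 4
  h1 <- 1 - a1  # P(pair-1 coalesces before the split)
  h2 <- 1 - a2
  p <- c(
    p10 = a1 * h2 * (2 / 3) * a31 + a1 * a2 * b1 / 2,
    p01 = h1 * a2 * (2 / 3) * a31 + a1 * a2 * b1 / 2,
    p20 = h1 * h2 * a21 / 2 + h1 * a2 * a31 / 3 +
      a1 * h2 * a32 / 3 + a1 * a2 * b2 / 6,
    p02 = h1 * h2 * a21 / 2 + a1 * h2 * a31 / 3 +
      h1 * a2 * a32 / 3 + a1 * a2 * b2 / 6,
    p11 = a1 * a2 * 2 * b2 / 3,
    p21 = h1 * a2 * (2 / 3) * a32 + a1 * a2 * b3 / 2,
    p12 = a1 * h2 * (2 / 3) * a32 + a1 * a2 * b3 / 2
  )
  p
}

# counts object with expectations proportional to ascertained_probs()
ascertained_counts <- function(a1, a2, b, m_tot = 1e7) {
  p <- ascertained_probs(a1, a2, b)
  cells <- stats::setNames(p * m_tot, sub("^p", "m", names(p)))
  config_counts(cells, m_tot = m_tot)
}

# random valid constant-ancestor parameter sets for property sweeps
rand_tt_params <- function(rng_n = 1) {
  alpha1 <- runif(1, 0.15, 0.95)
  alpha2 <- runif(1, 0.15, 0.95)
  theta <- runif(1, 1e-4, 2e-3)
  T1 <- runif(1, 1e-5, 5e-4)
  T2 <- runif(1, 1e-5, 5e-4)
  tt_params(alpha1, alpha2, theta = theta, T1 = T1, T2 = T2,
            V1 = runif(1, 0, T1), V2 = runif(1, 0, T2))
}
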