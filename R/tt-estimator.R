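#' TT estimates: closed-form divergence model parameters from counts
#'
#' Solves the constant-ancestor forward model (see [tt_forward_probs()]) by
#' the method of moments on the observed configuration frequencies
#' `m[i][j] / m_tot` — which, because the model is saturated in the
#' polymorphic cells, are also the maximum-likelihood estimates:
#' \deqn{\hat\alpha_1 = \frac{2 m_{1,1}}{2 m_{2,1} + m_{1,1}}, \quad
#'       \hat\theta = \frac{3}{8 m_{tot}}
#'       \frac{(2 m_{2,1}+m_{1,1})(2 m_{1,2}+m_{1,1})}{m_{1,1}}}
#' and so on for \eqn{T}, \eqn{V}. Negative time or drift estimates are
#' legitimate signals of model violation (e.g. a severe ancestral bottleneck)
#' and are reported as-is with a diagnostic flag, never clamped.
#'
#' Estimator preconditions: `m11 > 0` for any estimate; the `V` estimates
#' additionally need `2*m21 - m11 > 0` (resp. `2*m12 - m11`), failing which
#' the corresponding `V` is `NA` with a flag (this is the `alpha -> 1`
#' boundary, where `V` is unidentifiable).
#'
#' @param counts a [config_counts] object (real-valued cells allowed).
#' @param mu per-site per-generation mutation rate (default 1.25e-8).
#' @param G generation time in years (default 30).
#' @return object of class `tt_estimates`: `alpha1`, `alpha2`, `theta`,
#'   `T1`, `T2`, `V1`, `V2` (mutation units), `NA_diploid` (`theta/(2 mu)`),
#'   `t1_gen`, `t2_gen` (generations, `T/mu`), `t1_years`, `t2_years`
#'   (`G T / mu`), and `flags`, a character vector of diagnostics.
#' @examples
#' cc <- config_counts(c(m11 = 400, m21 = 400, m12 = 400), m_tot = 1e6)
#' est <- estimate_tt(cc)
#' est$alpha1  # 2/3
#' @seealso [estimate_tto()] for the outgroup-based variant,
#'   [block_jackknife()] for standard errors.
#' @export
estimate_tt <- function(counts, mu = 1.25e-8, G = 30) {
  stopifnot(inherits(counts, "config_counts"), mu > 0, G > 0)
  m <- counts$m
  mtot <- counts$m_tot
  m11 <- m[2, 2]; m21 <- m[3, 2]; m12 <- m[2, 3]
  m10 <- m[2, 1]; m01 <- m[1, 2]; m20 <- m[3, 1]; m02 <- m[1, 3]
  if (m11 <= 0) {
    stop("insufficient shared polymorphism: m[1,1] = 0, the TT estimators ",
         "are undefined")
  }
  flags <- character(0)

  alpha1 <- 2 * m11 / (2 * m21 + m11)
  alpha2 <- 2 * m11 / (2 * m12 + m11)
  theta <- 3 / 8 * (2 * m21 + m11) * (2 * m12 + m11) / (m11 * mtot)
  T1 <- (m10 / 2 + m20 - (2 * m21 + m11) * (6 * m12 + m11) / (8 * m11)) / mtot
  T2 <- (m01 / 2 + m02 - (6 * m21 + m11) * (2 * m12 + m11) / (8 * m11)) / mtot

  # V_k solves p10/2 + (p12 - 2*alpha1*p20) / (2*(1-alpha1)) = V1 (and the
  # index swap); identifiable only away from the alpha = 1 boundary.
  d1 <- 2 * m21 - m11
  d2 <- 2 * m12 - m11
  V1 <- V2 <- NA_real_
  if (d1 > 0) {
    V1 <- (m10 / 2 + (m12 * (2 * m21 + m11) - 4 * m11 * m20) / (2 * d1)) / mtot
  } else {
    flags <- c(flags, "V1_undefined")
    warning("V1 undefined: 2*m21 - m11 <= 0 (alpha1 at or above 1)")
  }
  if (d2 > 0) {
    V2 <- (m01 / 2 + (m21 * (2 * m12 + m11) - 4 * m11 * m02) / (2 * d2)) / mtot
  } else {
    flags <- c(flags, "V2_undefined")
    warning("V2 undefined: 2*m12 - m11 <= 0 (alpha2 at or above 1)")
  }

  if (alpha1 > 1) flags <- c(flags, "alpha1_gt_1")
  if (alpha2 > 1) flags <- c(flags, "alpha2_gt_1")
  if (T1 < 0) flags <- c(flags, "negative_T1")
  if (T2 < 0) flags <- c(flags, "negative_T2")
  if (!is.na(V1) && V1 < 0) flags <- c(flags, "negative_V1")
  if (!is.na(V2) && V2 < 0) flags <- c(flags, "negative_V2")

  structure(list(
    alpha1 = alpha1, alpha2 = alpha2, theta = theta,
    T1 = T1, T2 = T2, V1 = V1, V2 = V2,
    NA_diploid = theta / (2 * mu),
    t1_gen = T1 / mu, t2_gen = T2 / mu,
    t1_years = mutation_time_to_years(T1, mu, G),
    t2_years = mutation_time_to_years(T2, mu, G),
    mu = mu, G = G, flags = flags
  ), class = "tt_estimates")
}

#' Convert a mutation-scaled time to years
#'
#' `t_years = (G / mu) * T` for a mutation-scaled time `T = mu * t`.
#'
#' @param T time in mutation units.
#' @param mu per-site per-generation mutation rate (> 0).
#' @param G generation time in years.
#' @return time in years (same sign as `T`).
#' @examples
#' mutation_time_to_years(1.25e-4, mu = 1.25e-8, G = 30)  # 300000
#' @export
mutation_time_to_years <- function(T, mu = 1.25e-8, G = 30) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a single positive mutation rate")
  }
  stopifnot(G > 0)
  (G / mu) * T
}

#' @export
print.tt_estimates <- function(x, ...) {
  cat("TT estimates (constant ancestral population size)\n")
  tab <- data.frame(
    parameter = c("alpha1", "alpha2", "theta", "N_A (diploid)",
                  "T1", "T2", "V1", "V2",
                  "t1 (generations)", "t2 (generations)",
                  "t1 (years)", "t2 (years)"),
    estimate = c(x$alpha1, x$alpha2, x$theta, x$NA_diploid,
                 x$T1, x$T2, x$V1, x$V2,
                 x$t1_gen, x$t2_gen, x$t1_years, x$t2_years)
  )
  print(tab, row.names = FALSE, digits = 6)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Named-scalar view of an estimate object, used by the jackknife wrappers.
.tt_stat_vector <- function(est) {
  c(alpha1 = est$alpha1, alpha2 = est$alpha2, theta = est$theta,
    NA_diploid = est$NA_diploid, T1 = est$T1, T2 = est$T2,
    V1 = est$V1, V2 = est$V2,
    t1_gen = est$t1_gen, t2_gen = est$t2_gen,
    t1_years = est$t1_years, t2_years = est$t2_years)
}
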