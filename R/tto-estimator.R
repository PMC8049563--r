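#' Drift estimates from outgroup-ascertained counts
#'
#' For sites ascertained as carrying the derived allele in a true outgroup,
#' every derived variant predates the split, so the new-mutation and
#' within-branch terms (`mu*t`, `mu*nu`) vanish and the drift parameters are
#' identified without any assumption on the ancestral population:
#' \deqn{\hat\alpha_1^* = \frac{2 (m^*_{1,0} + m^*_{1,2} + m^*_{1,1})}
#'       {2 (m^*_{1,0} + 2 m^*_{2,0} + m^*_{2,1}) + m^*_{1,1}}}
#' and the index-swapped \eqn{\hat\alpha_2^*}. (Both numerator and
#' denominator equal \eqn{\alpha_1 (b_1 + \tfrac43 b_2 + b_3)} and
#' \eqn{b_1 + \tfrac43 b_2 + b_3} respectively under the ascertained model,
#' with `b_i` the ascertained four-sample spectrum, which is what makes the
#' ratio a consistent drift estimator.)
#'
#' @param counts_star a [config_counts] object of *ascertained* counts (sites
#'   with the derived allele present in the outgroup, see
#'   [ascertained_tally()]).
#' @return list with `alpha1`, `alpha2` and `flags` (`"alpha1_gt_1"` /
#'   `"alpha2_gt_1"` under sampling noise; values are not truncated).
#' @export
estimate_alpha_ascertained <- function(counts_star) {
  stopifnot(inherits(counts_star, "config_counts"))
  m <- counts_star$m
  m11 <- m[2, 2]
  den1 <- 2 * (m[2, 1] + 2 * m[3, 1] + m[3, 2]) + m11
  den2 <- 2 * (m[1, 2] + 2 * m[1, 3] + m[2, 3]) + m11
  if (den1 <= 0 || den2 <= 0) {
    stop("ascertained drift estimate undefined: empty denominator (no ",
         "ascertained sites in the relevant configurations)")
  }
  alpha1 <- 2 * (m[2, 1] + m[2, 3] + m11) / den1
  alpha2 <- 2 * (m[1, 2] + m[3, 2] + m11) / den2
  flags <- character(0)
  if (alpha1 > 1) flags <- c(flags, "alpha1_gt_1")
  if (alpha2 > 1) flags <- c(flags, "alpha2_gt_1")
  list(alpha1 = alpha1, alpha2 = alpha2, flags = flags)
}

#' Tree-ness tests of the outgroup topology
#'
#' Under a correct outgroup and a strictly bifurcating history with no gene
#' flow, ascertained counts are symmetric between the two in-group
#' populations and both statistics have expectation zero:
#' \deqn{Y_1 = \frac{2 m^*_{1,0}+m^*_{1,1}}{2 m^*_{0,1}+m^*_{1,1}} -
#'             \frac{2 m^*_{1,2}+m^*_{1,1}}{2 m^*_{2,1}+m^*_{1,1}}, \qquad
#'       Y_2 = \frac{(m^*_{1,0}-m^*_{0,1}) + 2(m^*_{2,0}-m^*_{0,2}) +
#'             (m^*_{2,1}-m^*_{1,2})}{m^*_{tot}}.}
#' `Y2` is closely related to the D-statistic; gene flow from the outgroup
#' lineage into population 2 drives it negative (into population 1,
#' positive). Use [block_jackknife()] on `treeness_tests` to obtain the
#' standard errors needed for a Z-score; a common working rule is to reject
#' tree-ness when `|Y| / SE > 3`.
#'
#' @inheritParams estimate_alpha_ascertained
#' @return named numeric vector `c(Y1, Y2)`.
#' @export
treeness_tests <- function(counts_star) {
  stopifnot(inherits(counts_star, "config_counts"))
  m <- counts_star$m
  m11 <- m[2, 2]
  den_a <- 2 * m[1, 2] + m11   # 2*m01 + m11
  den_b <- 2 * m[3, 2] + m11   # 2*m21 + m11
  if (den_a <= 0 || den_b <= 0) {
    empty <- if (den_a <= 0) "m01/m11" else "m21/m11"
    stop("Y1 undefined: empty configuration cells (", empty, ")")
  }
  Y1 <- (2 * m[2, 1] + m11) / den_a - (2 * m[2, 3] + m11) / den_b
  Y2 <- ((m[2, 1] - m[1, 2]) + 2 * (m[3, 1] - m[1, 3]) +
           (m[3, 2] - m[2, 3])) / counts_star$m_tot
  c(Y1 = Y1, Y2 = Y2)
}

#' TTo estimates: divergence times without assuming a constant ancestor
#'
#' Given externally obtained drift parameters (either
#' [estimate_alpha_ascertained()] on outgroup-ascertained counts, or known
#' true values), solves the general forward model on the *full* counts for
#' the mutation-scaled ancestral durations and the split times:
#' \deqn{\hat\tau_2^* = \frac{3}{2 m_{tot}}\Big(\frac{2 m_{2,1}+m_{1,1}}
#'   {\alpha_2} - \frac{m_{1,1}}{\alpha_1\alpha_2}\Big)}
#' (and the `m12` variant; both variants are averaged and retained),
#' similarly \eqn{\hat\tau_3^*}; the compounds
#' \eqn{\hat B_i^* = \mu t_i + \tau_4} from the row sums; and the
#' approximation \eqn{\hat\tau_4^* = \tfrac32 (\hat\tau_3^*)^2 / \hat\tau_2^*}
#' (exact for a constant ancestor, where
#' \eqn{E[T4_3]/E[T4_2] = 1/3} and \eqn{E[T4_4]/E[T4_3] = 1/2}), giving
#' \eqn{\hat T_i^* = \hat B_i^* - \hat\tau_4^*}.
#'
#' @param counts full (unascertained) [config_counts].
#' @param alpha1,alpha2 drift parameters in (0, 1].
#' @param mu,G mutation rate and generation time, as in [estimate_tt()].
#' @return object of class `tto_estimates`: `tau2`, `tau3` (averages),
#'   `tau2_variants`, `tau3_variants` (the `m21`- and `m12`-based forms),
#'   `tau4`, `B1`, `B2`, `V1`, `V2`, `T1`, `T2`, `NA_diploid_tau4`
#'   (`6 tau4 / (2 mu)`, the tau4-implied diploid ancestral size), times in
#'   generations and years, and `flags`.
#' @export
estimate_tto <- function(counts, alpha1, alpha2, mu = 1.25e-8, G = 30) {
  stopifnot(inherits(counts, "config_counts"), mu > 0, G > 0)
  if (!(alpha1 > 0 && alpha1 <= 1) || !(alpha2 > 0 && alpha2 <= 1)) {
    stop("alpha1 and alpha2 must lie in (0, 1]")
  }
  m <- counts$m
  mtot <- counts$m_tot
  m11 <- m[2, 2]; m21 <- m[3, 2]; m12 <- m[2, 3]
  m10 <- m[2, 1]; m01 <- m[1, 2]; m20 <- m[3, 1]; m02 <- m[1, 3]
  if (m11 <= 0) {
    stop("insufficient shared polymorphism: m[1,1] = 0, the TTo estimators ",
         "are undefined")
  }
  flags <- character(0)

  shared <- m11 / (alpha1 * alpha2)
  tau2_v <- c(m21 = 3 / 2 * ((2 * m21 + m11) / alpha2 - shared) / mtot,
              m12 = 3 / 2 * ((2 * m12 + m11) / alpha1 - shared) / mtot)
  tau3_v <- c(m21 = (5 / 2 * shared - (2 * m21 + m11) / alpha2) / mtot,
              m12 = (5 / 2 * shared - (2 * m12 + m11) / alpha1) / mtot)
  tau2 <- mean(tau2_v)
  tau3 <- mean(tau3_v)

  B1 <- (m10 / 2 + m20 + m21 / 2 -
           (5 - alpha1 * alpha2) / (alpha1 * alpha2) * m11 / 4) / mtot
  B2 <- (m01 / 2 + m02 + m12 / 2 -
           (5 - alpha1 * alpha2) / (alpha1 * alpha2) * m11 / 4) / mtot

  V1 <- V2 <- NA_real_
  if (alpha1 < 1) {
    V1 <- (m10 / 2 - alpha1 * m20 / (1 - alpha1) +
             m12 / (2 * (1 - alpha1))) / mtot
  } else {
    flags <- c(flags, "V1_undefined")
  }
  if (alpha2 < 1) {
    V2 <- (m01 / 2 - alpha2 * m02 / (1 - alpha2) +
             m21 / (2 * (1 - alpha2))) / mtot
  } else {
    flags <- c(flags, "V2_undefined")
  }

  if (tau2 > 0) {
    tau4 <- 3 / 2 * tau3^2 / tau2
    T1 <- B1 - tau4
    T2 <- B2 - tau4
  } else {
    flags <- c(flags, "tau2_nonpositive")
    warning("tau2 estimate is nonpositive; tau4 and the split times are ",
            "undefined")
    tau4 <- T1 <- T2 <- NA_real_
  }
  if (!is.na(tau3) && tau3 < 0) flags <- c(flags, "negative_tau3")
  if (!is.na(T1) && T1 < 0) flags <- c(flags, "negative_T1")
  if (!is.na(T2) && T2 < 0) flags <- c(flags, "negative_T2")

  structure(list(
    alpha1 = alpha1, alpha2 = alpha2,
    tau2 = tau2, tau3 = tau3, tau4 = tau4,
    tau2_variants = tau2_v, tau3_variants = tau3_v,
    B1 = B1, B2 = B2, V1 = V1, V2 = V2, T1 = T1, T2 = T2,
    NA_diploid_tau4 = if (is.na(tau4)) NA_real_ else 6 * tau4 / (2 * mu),
    t1_gen = T1 / mu, t2_gen = T2 / mu,
    t1_years = mutation_time_to_years(T1, mu, G),
    t2_years = mutation_time_to_years(T2, mu, G),
    mu = mu, G = G, flags = flags
  ), class = "tto_estimates")
}

#' @export
print.tto_estimates <- function(x, ...) {
  cat("TTo estimates (drift supplied externally; ancestral size free)\n")
  tab <- data.frame(
    parameter = c("alpha1 (input)", "alpha2 (input)",
                  "tau2", "tau3", "tau4", "B1", "B2", "V1", "V2",
                  "T1", "T2", "t1 (generations)", "t2 (generations)",
                  "t1 (years)", "t2 (years)", "N_A (diploid, via tau4)"),
    estimate = c(x$alpha1, x$alpha2, x$tau2, x$tau3, x$tau4, x$B1, x$B2,
                 x$V1, x$V2, x$T1, x$T2, x$t1_gen, x$t2_gen,
                 x$t1_years, x$t2_years, x$NA_diploid_tau4)
  )
  print(tab, row.names = FALSE, digits = 6)
  cat("tau2 variants (m21, m12):", format(x$tau2_variants, digits = 6), "\n")
  cat("tau3 variants (m21, m12):", format(x$tau3_variants, digits = 6), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.tto_stat_vector <- function(est) {
  c(tau2 = est$tau2, tau3 = est$tau3, tau4 = est$tau4,
    B1 = est$B1, B2 = est$B2, V1 = est$V1, V2 = est$V2,
    T1 = est$T1, T2 = est$T2, t1_gen = est$t1_gen, t2_gen = est$t2_gen,
    t1_years = est$t1_years, t2_years = est$t2_years)
}
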