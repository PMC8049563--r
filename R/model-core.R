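#' Parameters of the constant-ancestor (TT) divergence model
#'
#' The two-population split model with a panmictic, constant-size ancestral
#' population. Times and sizes are mutation-scaled:
#' * `alpha1`, `alpha2`: probability that the two lineages sampled in
#'   population 1 (resp. 2) do *not* coalesce before the split ("drift"
#'   parameters; 1 means no drift).
#' * `T1`, `T2`: split times in mutation units, `T = mu * t` with `t` in
#'   generations (the two may differ, e.g. for temporally structured samples).
#' * `V1`, `V2`: `mu * nu`, where `nu` is the expected within-population
#'   coalescence time conditional on coalescing before the split.
#' * `theta`: `mu * N_A` with `N_A` the ancestral population size counted in
#'   *chromosomes*; the diploid size is `theta / (2 * mu)`.
#'
#' @param alpha1,alpha2 drift parameters in (0, 1].
#' @param theta mutation-scaled ancestral size (chromosomes), >= 0.
#' @param T1,T2 mutation-scaled split times, >= 0.
#' @param V1,V2 mutation-scaled conditional coalescence times, >= 0.
#' @param mu per-site, per-generation mutation rate.
#' @param G generation time in years.
#' @return an object of class `tt_params`.
#' @export
tt_params <- function(alpha1, alpha2, theta, T1, T2, V1 = 0, V2 = 0,
                      mu = 1.25e-8, G = 30) {
  stopifnot(alpha1 > 0, alpha1 <= 1, alpha2 > 0, alpha2 <= 1,
            theta >= 0, T1 >= 0, T2 >= 0, V1 >= 0, V2 >= 0, mu > 0, G > 0)
  if (alpha1 < 1 && V1 > T1) {
    warning("V1 > T1: conditional coalescence time exceeds the branch length")
  }
  if (alpha2 < 1 && V2 > T2) {
    warning("V2 > T2: conditional coalescence time exceeds the branch length")
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, theta = theta,
                 T1 = T1, T2 = T2, V1 = V1, V2 = V2, mu = mu, G = G),
            class = "tt_params")
}

#' Parameters of the general split model (arbitrary ancestral size history)
#'
#' Generalizes [tt_params()]: the ancestral population enters only through
#' `tau2`, `tau3`, `tau4`, the mutation-scaled expected durations
#' `tau_i = mu * E[T4_i]` that a four-lineage coalescent started at the split
#' spends with `i` lineages. For a constant ancestral size these reduce to
#' `(theta, theta/3, theta/6)`. The compound `B_k = mu * t_k + tau4` is what
#' the data identify; split times are carried separately here.
#'
#' @inheritParams tt_params
#' @param tau2,tau3,tau4 mutation-scaled expected inter-coalescent durations,
#'   each >= 0.
#' @return an object of class `general_params`.
#' @export
general_params <- function(alpha1, alpha2, V1 = 0, V2 = 0,
                           tau2, tau3, tau4, mu = 1.25e-8, G = 30) {
  stopifnot(alpha1 > 0, alpha1 <= 1, alpha2 > 0, alpha2 <= 1,
            V1 >= 0, V2 >= 0, tau2 >= 0, tau3 >= 0, tau4 >= 0, mu > 0, G > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, V1 = V1, V2 = V2,
                 tau2 = tau2, tau3 = tau3, tau4 = tau4, mu = mu, G = G),
            class = "general_params")
}

#' Forward map: constant-ancestor model parameters to configuration probabilities
#'
#' Evaluates the closed-form per-site probabilities of the seven polymorphic
#' 2+2 sample configurations under the constant-ancestral-size split model,
#' in the linear-in-mu (composite likelihood, infinite sites) regime where a
#' mutation probability equals mutation rate times expected branch length:
#' \deqn{p_{1,0} = 2\alpha_1 T_1 + 2(1-\alpha_1)V_1 +
#'       \tfrac13 \alpha_1 (4-\alpha_2)\theta}
#' and similarly for the other configurations; the monomorphic remainder is
#' returned as the lump `p00_p22`.
#'
#' @param params a [tt_params] object.
#' @return a [config_probs] object.
#' @examples
#' p <- tt_forward_probs(tt_params(0.8, 0.5, theta = 1e-3,
#'                                 T1 = 1.25e-4, T2 = 1.25e-4))
#' p$p["1", "1"]  # 2/3 * 0.8 * 0.5 * 1e-3
#' @export
tt_forward_probs <- function(params) {
  stopifnot(inherits(params, "tt_params"))
  a1 <- params$alpha1; a2 <- params$alpha2; th <- params$theta
  T1 <- params$T1; T2 <- params$T2; V1 <- params$V1; V2 <- params$V2
  p <- c(
    p10 = 2 * a1 * T1 + 2 * (1 - a1) * V1 + a1 * (4 - a2) * th / 3,
    p01 = 2 * a2 * T2 + 2 * (1 - a2) * V2 + a2 * (4 - a1) * th / 3,
    p20 = (1 - a1) * (T1 - V1) + (6 - 4 * a1 - 2 * a2 + a1 * a2) * th / 6,
    p02 = (1 - a2) * (T2 - V2) + (6 - 2 * a1 - 4 * a2 + a1 * a2) * th / 6,
    p11 = 2 / 3 * a1 * a2 * th,
    p21 = (2 - a1) * a2 * th / 3,
    p12 = (2 - a2) * a1 * th / 3
  )
  .check_poly_probs(p)
  config_probs(p)
}

#' Forward map: general split model to configuration probabilities
#'
#' Evaluates the polymorphic configuration probabilities under the general
#' model, where the ancestral population contributes only through
#' `tau2`, `tau3`, `tau4` (see [general_params()]). With
#' `(tau2, tau3, tau4) = (theta, theta/3, theta/6)` this reproduces
#' [tt_forward_probs()] exactly.
#'
#' @param params a [general_params] object.
#' @param T1,T2 mutation-scaled split times (`mu * t`).
#' @return a [config_probs] object.
#' @export
general_forward_probs <- function(params, T1, T2) {
  stopifnot(inherits(params, "general_params"), T1 >= 0, T2 >= 0)
  a1 <- params$alpha1; a2 <- params$alpha2
  V1 <- params$V1; V2 <- params$V2
  t2 <- params$tau2; t3 <- params$tau3; t4 <- params$tau4
  X <- 2 * t2 + 3 * t3
  p <- c(
    p10 = 2 * (1 - a1) * V1 + 2 * a1 * (T1 + t4) +
      a1 * (4 - a2) * X / 9 - a1 * t2 / 3,
    p01 = 2 * (1 - a2) * V2 + 2 * a2 * (T2 + t4) +
      a2 * (4 - a1) * X / 9 - a2 * t2 / 3,
    p20 = (1 - a1) * (T1 + t4 - V1) +
      (5 - 4 * a1 - a2 + a1 * a2) * X / 18 + (a1 - a2) * t2 / 6,
    p02 = (1 - a2) * (T2 + t4 - V2) +
      (5 - a1 - 4 * a2 + a1 * a2) * X / 18 + (a2 - a1) * t2 / 6,
    p11 = 2 / 9 * a1 * a2 * X,
    p21 = a2 * (1 - a1) * X / 9 + a2 * t2 / 3,
    p12 = a1 * (1 - a2) * X / 9 + a1 * t2 / 3
  )
  .check_poly_probs(p)
  config_probs(p)
}

.check_poly_probs <- function(p) {
  bad <- names(p)[p < 0]
  if (length(bad) > 0L) {
    stop("parameters yield a negative probability for configuration ",
         bad[1L], " (", format(p[[bad[1L]]]), "); outside the linear-in-mu ",
         "regime or invalid parameters")
  }
  if (sum(p) >= 1) {
    stop("polymorphic probabilities sum to >= 1; parameters are outside the ",
         "linear-in-mu regime")
  }
  invisible(p)
}

#' Constant-population ancestral durations and four-sample spectrum
#'
#' Under a constant ancestral size, the expected durations with k lineages
#' are `E[T4_k] = 2 N_A / (k (k-1))` (with `N_A` in chromosomes), so the
#' mutation-scaled durations are `(tau2, tau3, tau4) = (theta, theta/3,
#' theta/6)`, and the probabilities that a size-4 sample drawn at the split
#' carries 1, 2 or 3 derived variants are
#' `b1 = (2/3) tau2 + 2 tau3 + 4 tau4`, `b2 = (2/3) tau2 + tau3`,
#' `b3 = (2/3) tau2`, i.e. `(2 theta, theta, (2/3) theta)`.
#'
#' @param theta mutation-scaled ancestral size `mu * N_A` (chromosomes).
#' @return list with `tau2`, `tau3`, `tau4` and `b` = `c(b1, b2, b3)`.
#' @export
constant_tau_and_b <- function(theta) {
  stopifnot(length(theta) == 1L, !is.na(theta))
  if (theta < 0) stop("theta must be nonnegative")
  tau <- c(tau2 = theta, tau3 = theta / 3, tau4 = theta / 6)
  list(tau2 = tau[["tau2"]], tau3 = tau[["tau3"]], tau4 = tau[["tau4"]],
       b = ancestral_spectrum(tau[["tau2"]], tau[["tau3"]], tau[["tau4"]]))
}

#' Four-sample ancestral spectrum from the inter-coalescent durations
#'
#' @param tau2,tau3,tau4 mutation-scaled expected durations (see
#'   [general_params()]).
#' @return named vector `c(b1, b2, b3)` of probabilities that a size-4 sample
#'   drawn at the split carries 1, 2, 3 derived variants.
#' @export
ancestral_spectrum <- function(tau2, tau3, tau4) {
  stopifnot(tau2 >= 0, tau3 >= 0, tau4 >= 0)
  c(b1 = 2 / 3 * tau2 + 2 * tau3 + 4 * tau4,
    b2 = 2 / 3 * tau2 + tau3,
    b3 = 2 / 3 * tau2)
}

#' Downsample the four-sample ancestral spectrum to sizes 2 and 3
#'
#' A random subsample of a coalescent sample is distributed as a direct
#' sample, so the size-2 and size-3 derived-allele probabilities follow from
#' the size-4 spectrum by hypergeometric downsampling:
#' `a2_1 = b1/2 + 2 b2/3 + b3/2`, `a3_1 = 3 b1/4 + b2/2`,
#' `a3_2 = b2/2 + 3 b3/4`.
#'
#' @param b numeric vector `c(b1, b2, b3)` (as from [ancestral_spectrum()]).
#' @return named vector `c(a2_1, a3_1, a3_2)`.
#' @export
downsample_spectrum <- function(b) {
  stopifnot(length(b) == 3L, all(b >= 0), sum(b) <= 1 + 1e-12)
  b1 <- b[[1L]]; b2 <- b[[2L]]; b3 <- b[[3L]]
  c(a2_1 = b1 / 2 + 2 * b2 / 3 + b3 / 2,
    a3_1 = 3 * b1 / 4 + b2 / 2,
    a3_2 = b2 / 2 + 3 * b3 / 4)
}

#' @rdname tt_params
#' @param x object to convert.
#' @export
as_general_params <- function(x) {
  stopifnot(inherits(x, "tt_params"))
  general_params(alpha1 = x$alpha1, alpha2 = x$alpha2, V1 = x$V1, V2 = x$V2,
                 tau2 = x$theta, tau3 = x$theta / 3, tau4 = x$theta / 6,
                 mu = x$mu, G = x$G)
}
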