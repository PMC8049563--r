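#' Weighted block-jackknife standard errors
#'
#' Leave-one-genomic-block-out resampling for any statistic of configuration
#' counts, with blocks weighted by their site totals (unequal block sizes are
#' the norm for physical blocks). For each block j the statistic is
#' recomputed on the total counts minus block j; with `n` the total site
#' count, `m_j` the block site count and `h_j = n / m_j`, the weighted
#' delete-one jackknife estimate and variance are
#' \deqn{\hat\theta_J = g\,\hat\theta - \sum_j (1 - m_j/n)\,\hat\theta_{-j},
#'  \qquad
#'  \widehat{var} = \frac{1}{g} \sum_j
#'  \frac{(h_j\hat\theta - (h_j - 1)\hat\theta_{-j} - \hat\theta_J)^2}
#'       {h_j - 1}}
#' which reduces to the classical delete-one jackknife for equal blocks.
#'
#' Replicates on which the statistic is undefined (error or `NA`) are
#' excluded with a warning, and the weighting is renormalized over the usable
#' blocks; at least two usable replicates are required.
#'
#' @param blocked a [blocked_counts] object with at least two blocks.
#' @param statistic function taking a [config_counts] and returning a single
#'   number or a named numeric vector (every component gets its own SD).
#' @param ... passed on to `statistic`.
#' @return object of class `jackknife_result`: `estimate` (statistic on the
#'   full data), `sd`, `n_blocks` (usable), `replicates` (blocks x components
#'   matrix of leave-one-out estimates), `weights` (block site counts), and
#'   `excluded` (names of dropped blocks).
#' @examples
#' cfg <- demography_config(t_split = 2000, m_tot = 1e6, R = 2000,
#'                          mode = "multinomial", n_blocks = 20, seed = 3)
#' sim <- simulate_counts(cfg)
#' jk <- block_jackknife(sim$counts, function(cc) estimate_tt(cc)$theta)
#' c(jk$estimate, jk$sd)
#' @export
block_jackknife <- function(blocked, statistic, ...) {
  stopifnot(inherits(blocked, "blocked_counts"), is.function(statistic))
  g_all <- length(blocked$blocks)
  if (g_all < 2L) stop("the block jackknife needs at least 2 blocks")
  w_all <- vapply(blocked$blocks, `[[`, 0, "m_tot")
  if (any(w_all <= 0)) stop("every block must have a positive site total")

  full <- .as_named(statistic(blocked$total, ...))
  k <- length(full)

  loo <- matrix(NA_real_, g_all, k,
                dimnames = list(names(blocked$blocks), names(full)))
  for (j in seq_len(g_all)) {
    mj <- blocked$total$m - blocked$blocks[[j]]$m
    rep_j <- tryCatch(
      suppressWarnings(.as_named(
        statistic(config_counts(mj, m_tot = blocked$total$m_tot - w_all[j]),
                  ...))),
      error = function(e) rep(NA_real_, k))
    loo[j, ] <- rep_j
  }

  usable <- stats::complete.cases(loo)
  if (sum(usable) < 2L) {
    stop("fewer than 2 usable leave-one-out replicates")
  }
  if (any(!usable)) {
    warning("statistic undefined on ", sum(!usable),
            " leave-one-out replicate(s); excluded from the jackknife")
  }
  w <- w_all[usable]
  th <- loo[usable, , drop = FALSE]
  g <- sum(usable)
  n <- sum(w)
  h <- n / w

  est_j <- g * full - colSums((1 - w / n) * th)
  # pseudovalues: pseudo_j = h_j * full - (h_j - 1) * loo_j
  pseudo <- outer(h, full) - (h - 1) * th
  dev <- sweep(pseudo, 2, est_j, `-`)
  v <- colSums(dev^2 / (h - 1)) / g

  structure(list(estimate = full, sd = sqrt(v), n_blocks = g,
                 replicates = loo, weights = w_all,
                 excluded = names(blocked$blocks)[!usable]),
            class = "jackknife_result")
}

.as_named <- function(x) {
  x <- unlist(x)
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1L) "statistic" else
      paste0("statistic", seq_along(x))
  }
  x
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat("weighted block jackknife (", x$n_blocks, "blocks )\n")
  print(data.frame(estimate = x$estimate, sd = x$sd), digits = 6)
  if (length(x$excluded)) {
    cat("excluded blocks:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Jackknifed TT / TTo / tree-ness reports
#'
#' Convenience wrappers applying [block_jackknife()] to every scalar
#' component of an estimator at once.
#'
#' @param blocked a [blocked_counts] object.
#' @param mu,G mutation rate and generation time.
#' @return data frame with columns `parameter`, `estimate`, `sd` (and for
#'   [jackknife_treeness()], `Z = estimate / sd`).
#' @export
jackknife_tt <- function(blocked, mu = 1.25e-8, G = 30) {
  jk <- block_jackknife(blocked,
                        function(cc) .tt_stat_vector(estimate_tt(cc, mu, G)))
  data.frame(parameter = names(jk$estimate), estimate = jk$estimate,
             sd = jk$sd, row.names = NULL)
}

#' @param alpha1,alpha2 externally obtained drift parameters (see
#'   [estimate_tto()]).
#' @rdname jackknife_tt
#' @export
jackknife_tto <- function(blocked, alpha1, alpha2, mu = 1.25e-8, G = 30) {
  jk <- block_jackknife(blocked, function(cc) {
    .tto_stat_vector(estimate_tto(cc, alpha1, alpha2, mu, G))
  })
  data.frame(parameter = names(jk$estimate), estimate = jk$estimate,
             sd = jk$sd, row.names = NULL)
}

#' @rdname jackknife_tt
#' @export
jackknife_treeness <- function(blocked) {
  jk <- block_jackknife(blocked, treeness_tests)
  data.frame(parameter = names(jk$estimate), estimate = jk$estimate,
             sd = jk$sd, Z = jk$estimate / jk$sd, row.names = NULL)
}
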