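#' Demographic scenario for the per-site coalescent simulator
#'
#' Describes a two-population split with an optional piecewise-constant
#' ancestral size change (a bottleneck or expansion), an optional single
#' pulse of admixture, and an optional outgroup population branching off
#' deeper than the split. Time runs backwards from the present in
#' generations; all sizes are diploid individuals.
#'
#' The ancestral size schedule, looking backwards from the split, is: `N_anc`
#' for `phi` generations, then `lambda * N_anc` for `tau_b` generations, then
#' `N_anc` again. The admixture pulse moves each lineage present in the
#' `recipient` daughter at time `delta` to the `donor` population with
#' probability `gamma`.
#'
#' @param N1,N2,N_anc diploid sizes of the daughter populations and the
#'   ancestral population.
#' @param t_split split time in generations.
#' @param lambda ancestral size multiplier during the size-change epoch.
#' @param tau_b duration (generations) of the size-change epoch.
#' @param phi generations between the split and the size change (backwards).
#' @param gamma migrant fraction of the admixture pulse, in \[0, 1\].
#' @param delta time of the admixture pulse, in \[0, t_split\].
#' @param recipient daughter population receiving migrants (1 or 2).
#' @param donor source population of the migrants: 1, 2, or 3 (the outgroup
#'   lineage); defaults to the other daughter.
#' @param outgroup `NULL`, or a list with `t_out` (outgroup split time,
#'   > `t_split` and after the ancestral size-change epoch), and optionally
#'   `N_out` and `N_root` (default `N_anc`).
#' @param mu per-site per-generation mutation rate.
#' @param m_tot number of sites to emit.
#' @param R number of Monte-Carlo genealogies to average over (>= 1000).
#' @param mode `"expected"` (real-valued expected counts `m_tot * p`) or
#'   `"multinomial"` (integer sampled counts).
#' @param n_blocks number of equal-size blocks to split the counts into
#'   (for jackknife experiments on simulated data).
#' @param seed optional integer seed applied by [simulate_counts()].
#' @return an object of class `demography_config`.
#' @export
demography_config <- function(N1 = 17000, N2 = 17000, N_anc = 17000,
                              t_split = 10000, lambda = 1, tau_b = 0,
                              phi = 0, gamma = 0, delta = 0, recipient = 2,
                              donor = NULL, outgroup = NULL, mu = 1.25e-8,
                              m_tot = 1e6, R = 1e5,
                              mode = c("expected", "multinomial"),
                              n_blocks = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(N1 > 0, N2 > 0, N_anc > 0, t_split >= 0, lambda > 0, tau_b >= 0,
            phi >= 0, gamma >= 0, gamma <= 1, delta >= 0, delta <= t_split,
            recipient %in% 1:2, mu > 0, m_tot > 0, n_blocks >= 1)
  if (is.null(donor)) donor <- 3L - as.integer(recipient)
  stopifnot(donor %in% 1:3, donor != recipient)
  if (!is.null(outgroup)) {
    stopifnot(is.list(outgroup), !is.null(outgroup$t_out))
    if (is.null(outgroup$N_out)) outgroup$N_out <- N_anc
    if (is.null(outgroup$N_root)) outgroup$N_root <- N_anc
    stopifnot(outgroup$t_out > t_split, outgroup$N_out > 0,
              outgroup$N_root > 0)
    if (lambda != 1 && t_split + phi + tau_b > outgroup$t_out) {
      stop("the ancestral size-change epoch must end before the outgroup ",
           "split time t_out")
    }
  } else if (donor == 3) {
    stop("donor = 3 (outgroup) requires an outgroup in the configuration")
  }
  structure(list(N1 = N1, N2 = N2, N_anc = N_anc, t_split = t_split,
                 lambda = lambda, tau_b = tau_b, phi = phi, gamma = gamma,
                 delta = delta, recipient = as.integer(recipient),
                 donor = as.integer(donor), outgroup = outgroup, mu = mu,
                 m_tot = m_tot, R = as.integer(R), mode = mode,
                 n_blocks = as.integer(n_blocks), seed = seed),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat("demography_config: N1 =", x$N1, ", N2 =", x$N2, ", N_anc =", x$N_anc,
      "diploids; split", x$t_split, "generations\n")
  if (x$lambda != 1 && x$tau_b > 0) {
    cat("  ancestral size change: x", x$lambda, "for", x$tau_b,
        "generations,", x$phi, "generations before the split\n")
  }
  if (x$gamma > 0) {
    cat("  admixture pulse: gamma =", x$gamma, "at", x$delta,
        "generations into population", x$recipient, "from", x$donor, "\n")
  }
  if (!is.null(x$outgroup)) {
    cat("  outgroup split:", x$outgroup$t_out, "generations (N_out =",
        x$outgroup$N_out, ")\n")
  }
  cat("  mu =", x$mu, ", m_tot =", x$m_tot, ", R =", x$R, ", mode =",
      x$mode, "\n")
  invisible(x)
}

# Monte-Carlo mean branch lengths by configuration, as a 3x3x3 array
# (pop1 x pop2 x outgroup derived counts), plus the per-site probability
# array with the monomorphic lump in cell [1,1,1].
.sim_probs <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  if (config$R < 1000) stop("R must be at least 1000 Monte-Carlo genealogies")
  og <- config$outgroup
  res <- sim_batch_cpp(
    R = config$R, N1 = config$N1, N2 = config$N2, Na = config$N_anc,
    t_split = config$t_split, lambda = config$lambda, tau_b = config$tau_b,
    phi = config$phi, gamma = config$gamma, delta = config$delta,
    recipient = config$recipient, donor = config$donor,
    has_out = !is.null(og),
    t_out = if (is.null(og)) 0 else og$t_out,
    N_out = if (is.null(og)) 1 else og$N_out,
    N_root = if (is.null(og)) 1 else og$N_root)
  if (config$mu * res$mean_total_length > 0.1) {
    stop("mu times the mean total branch length exceeds 0.1; the ",
         "linear-in-mu approximation is not valid for this configuration")
  }
  p <- config$mu * res$L
  se <- config$mu * res$L_se
  rel <- se[p > 0] / p[p > 0]
  if (any(rel > 0.01)) {
    warning("Monte-Carlo standard error exceeds 1% of the value for some ",
            "configuration probabilities; consider increasing R")
  }
  lump <- 1 - sum(p[-1])  # cell [1,1,1] is (0,0,0): never on a branch
  p[1] <- lump
  list(p = p, alpha1_mc = res$alpha1_mc, alpha2_mc = res$alpha2_mc,
       mean_total_length = res$mean_total_length)
}

#' Simulate 2+2 configuration counts under a split demography
#'
#' Averages per-genealogy configuration probabilities over `R` independent
#' Monte-Carlo genealogies (each genealogy contributes mutation rate times
#' branch length for every leaf subset), then either scales by `m_tot`
#' (`mode = "expected"`, real-valued counts) or samples a multinomial
#' (`mode = "multinomial"`). Sites are independent, matching the composite
#' likelihood assumption of the estimators, so a single per-site probability
#' vector is statistically equivalent to simulating one genealogy per site.
#'
#' @param config a [demography_config].
#' @return list with elements
#'   * `counts`: full [config_counts] (or [blocked_counts] if
#'     `n_blocks > 1`);
#'   * `counts_ascertained`: counts restricted to sites with at least one
#'     derived allele in the outgroup sample (`NULL` without an outgroup);
#'   * `truth`: generative ground truth — `alpha` (analytic
#'     `exp(-t_split/(2N))` for constant daughters without admixture, else
#'     `NA`), `alpha_mc` (Monte-Carlo), `T1`, `T2` (mutation-scaled split
#'     times), `theta` (`mu * 2 * N_anc`), and Monte-Carlo `tau2`, `tau3`,
#'     `tau4` from a four-lineage coalescent started at the split.
#' @examples
#' cfg <- demography_config(t_split = 2000, m_tot = 1e5, R = 2000,
#'                          seed = 7)
#' sim <- simulate_counts(cfg)
#' estimate_tt(sim$counts)$t1_gen
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sp <- .sim_probs(config)
  p <- sp$p

  if (config$mode == "expected") {
    cell27 <- p * config$m_tot
    split27 <- replicate(config$n_blocks, cell27 / config$n_blocks,
                         simplify = FALSE)
  } else {
    sizes <- rep(floor(config$m_tot / config$n_blocks), config$n_blocks)
    extra <- config$m_tot - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    split27 <- lapply(sizes, function(n) {
      array(stats::rmultinom(1, n, as.vector(p)), dim = c(3, 3, 3))
    })
    cell27 <- Reduce(`+`, split27)
  }

  to_counts <- function(a) {
    config_counts(apply(a, c(1, 2), sum))
  }
  to_ascertained <- function(a) {
    m <- apply(a[, , 2:3, drop = FALSE], c(1, 2), sum)
    config_counts(m)
  }
  counts <- if (config$n_blocks > 1) {
    blocked_counts(lapply(split27, to_counts))
  } else {
    to_counts(cell27)
  }
  counts_star <- NULL
  if (!is.null(config$outgroup)) {
    counts_star <- if (config$n_blocks > 1) {
      blocked_counts(lapply(split27, to_ascertained))
    } else {
      to_ascertained(cell27)
    }
  }

  tau <- ancestral_t4_moments(config, R = config$R)
  alpha_cf <- if (config$gamma == 0) {
    c(exp(-config$t_split / (2 * config$N1)),
      exp(-config$t_split / (2 * config$N2)))
  } else {
    c(NA_real_, NA_real_)
  }
  truth <- list(
    alpha = alpha_cf,
    alpha_mc = c(sp$alpha1_mc, sp$alpha2_mc),
    T1 = config$mu * config$t_split, T2 = config$mu * config$t_split,
    theta = config$mu * 2 * config$N_anc,
    tau2 = tau$tau2, tau3 = tau$tau3, tau4 = tau$tau4,
    config = config)
  list(counts = counts, counts_ascertained = counts_star, truth = truth)
}

#' Moments of the four-lineage coalescent in the ancestral population
#'
#' Starts four lineages at the split and runs them through the ancestral
#' size schedule of `config`, returning Monte-Carlo means of the durations
#' `T4_k` spent with k lineages and the mutation-scaled `tau_k = mu E[T4_k]`.
#' For a constant ancestral size `E[T4_k] = 2 N_A / (k(k-1))` generations
#' with `N_A` in chromosomes (`= 4 N_diploid / (k(k-1))`).
#'
#' @param config a [demography_config] (only the ancestral schedule is used).
#' @param R number of Monte-Carlo replicates.
#' @return list with `ET44`, `ET43`, `ET42` (generations) and `tau4`, `tau3`,
#'   `tau2`.
#' @export
ancestral_t4_moments <- function(config, R = config$R) {
  stopifnot(inherits(config, "demography_config"))
  breaks <- numeric(0)
  sizes <- config$N_anc
  if (config$lambda != 1 && config$tau_b > 0) {
    breaks <- c(config$phi, config$phi + config$tau_b)
    sizes <- c(config$N_anc, config$lambda * config$N_anc, config$N_anc)
  }
  if (!is.null(config$outgroup)) {
    breaks <- c(breaks, config$outgroup$t_out - config$t_split)
    sizes <- c(sizes, config$outgroup$N_root)
  }
  res <- sim_t4_cpp(as.integer(R), breaks, sizes)
  list(ET44 = res$ET44, ET43 = res$ET43, ET42 = res$ET42,
       tau4 = config$mu * res$ET44, tau3 = config$mu * res$ET43,
       tau2 = config$mu * res$ET42)
}

#' True drift parameters of a simulated demography
#'
#' The drift parameter `alpha_k` is the probability that the two lineages
#' sampled in daughter population k do not coalesce with each other before
#' the split. For constant daughter sizes and no admixture this is the
#' closed form `exp(-t_split / (2 N_k))`; with an admixture pulse it is
#' estimated by Monte Carlo (the fraction of replicate genealogies without a
#' within-pair coalescence before `t_split`).
#'
#' @param config a [demography_config].
#' @param R Monte-Carlo replicates for the simulation-based estimate.
#' @return named vector `c(alpha1, alpha2)` with attribute `method`
#'   (`"closed_form"` or `"monte_carlo"`).
#' @export
true_alpha <- function(config, R = config$R) {
  stopifnot(inherits(config, "demography_config"))
  if (config$gamma == 0) {
    a <- c(alpha1 = exp(-config$t_split / (2 * config$N1)),
           alpha2 = exp(-config$t_split / (2 * config$N2)))
    attr(a, "method") <- "closed_form"
    return(a)
  }
  cfg <- config
  cfg$R <- as.integer(R)
  sp <- .sim_probs(cfg)
  a <- c(alpha1 = sp$alpha1_mc, alpha2 = sp$alpha2_mc)
  attr(a, "method") <- "monte_carlo"
  a
}

#' Simulate a single four(or six)-leaf genealogy
#'
#' Pure-R event-driven reference implementation of the same structured
#' coalescent that [simulate_counts()] integrates over. Returns the full
#' genealogy, useful for inspecting individual realizations and as an
#' independent check of the batch simulator.
#'
#' @param config a [demography_config].
#' @return object of class `genealogy4`: `segments` (data frame with one row
#'   per non-root branch: derived counts `d1`, `d2`, `d_out` of the subtended
#'   leaves and branch `length` in generations), `coal_times` (sorted merge
#'   times), `H1`, `H2` (whether the population-1 / population-2 sampled pair
#'   coalesced before the split), `tmrca`, and `t_split`.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  og <- config$outgroup
  has_out <- !is.null(og)
  t_out <- if (has_out) og$t_out else Inf

  anc_size <- function(s) {
    if (has_out && s >= t_out) return(og$N_root)
    if (s < config$t_split + config$phi) return(config$N_anc)
    if (s < config$t_split + config$phi + config$tau_b) {
      return(config$lambda * config$N_anc)
    }
    config$N_anc
  }
  pop_size <- function(pop, s) {
    if (pop == 1) {
      if (s < config$t_split) config$N1 else anc_size(s)
    } else if (pop == 2) {
      config$N2
    } else {
      og$N_out
    }
  }

  lin <- data.frame(d1 = c(1, 1, 0, 0), d2 = c(0, 0, 1, 1),
                    d_out = 0, pop = c(1, 1, 2, 2), birth = 0)
  if (has_out) {
    lin <- rbind(lin, data.frame(d1 = 0, d2 = 0, d_out = c(1, 1),
                                 pop = 3, birth = 0))
  }
  bnd <- config$t_split
  if (config$gamma > 0 && config$delta > 0) bnd <- c(bnd, config$delta)
  if (config$lambda != 1 && config$tau_b > 0) {
    bnd <- c(bnd, config$t_split + config$phi,
             config$t_split + config$phi + config$tau_b)
  }
  if (has_out) bnd <- c(bnd, t_out)
  bnd <- sort(bnd)

  mig_done <- config$gamma == 0
  rec <- config$recipient
  don <- config$donor
  if (!mig_done && config$delta <= 0) {
    move <- lin$pop == rec & stats::runif(nrow(lin)) < config$gamma
    lin$pop[move] <- don
    mig_done <- TRUE
  }

  segments <- list()
  coal_times <- numeric(0)
  t_pair1 <- t_pair2 <- NA_real_
  s <- 0
  bi <- 1L
  while (nrow(lin) > 1L) {
    nb <- if (bi <= length(bnd)) bnd[bi] else Inf
    rate <- vapply(1:3, function(p) {
      k <- sum(lin$pop == p)
      if (k >= 2) k * (k - 1) / (4 * pop_size(p, s)) else 0
    }, 0)
    total <- sum(rate)
    w <- if (total > 0) stats::rexp(1, total) else Inf
    if (s + w >= nb) {
      s <- nb
      bi <- bi + 1L
      if (!mig_done && nb == config$delta) {
        move <- lin$pop == rec & stats::runif(nrow(lin)) < config$gamma
        lin$pop[move] <- don
        mig_done <- TRUE
      }
      if (nb == config$t_split) lin$pop[lin$pop == 2] <- 1L
      if (has_out && nb == t_out) lin$pop[lin$pop == 3] <- 1L
      next
    }
    s <- s + w
    p <- sample.int(3, 1, prob = rate)
    members <- which(lin$pop == p)
    pair <- sample(members, 2)
    A <- lin[pair[1], ]
    B <- lin[pair[2], ]
    if (is.na(t_pair1) && A$d1 > 0 && B$d1 > 0) t_pair1 <- s
    if (is.na(t_pair2) && A$d2 > 0 && B$d2 > 0) t_pair2 <- s
    segments[[length(segments) + 1L]] <-
      data.frame(d1 = c(A$d1, B$d1), d2 = c(A$d2, B$d2),
                 d_out = c(A$d_out, B$d_out),
                 length = s - c(A$birth, B$birth))
    coal_times <- c(coal_times, s)
    merged <- data.frame(d1 = A$d1 + B$d1, d2 = A$d2 + B$d2,
                         d_out = A$d_out + B$d_out, pop = p, birth = s)
    lin <- rbind(lin[-pair, ], merged)
  }
  structure(list(
    segments = do.call(rbind, segments),
    coal_times = coal_times,
    H1 = !is.na(t_pair1) && t_pair1 < config$t_split,
    H2 = !is.na(t_pair2) && t_pair2 < config$t_split,
    tmrca = max(coal_times),
    t_split = config$t_split
  ), class = "genealogy4")
}

#' Configuration probabilities of a single genealogy
#'
#' A mutation falling on a branch that subtends `i` population-1 leaves and
#' `j` population-2 leaves produces sample configuration `(i, j)`, so in the
#' linear-in-mu regime `p[i,j] = mu * L[i,j]` with `L` the total branch
#' length by subtended leaf subset (outgroup leaves marginalized).
#'
#' @param g a `genealogy4` from [simulate_genealogy()].
#' @param mu mutation rate; `mu * total branch length` must be <= 0.1 for the
#'   linear approximation to hold.
#' @return a [config_probs] object.
#' @export
genealogy_config_probs <- function(g, mu) {
  stopifnot(inherits(g, "genealogy4"), mu >= 0)
  seg <- g$segments
  if (mu * sum(seg$length) > 0.1) {
    stop("mu * total branch length exceeds 0.1; linearity in the mutation ",
         "rate is violated for this genealogy")
  }
  p <- matrix(0, 3, 3)
  for (r in seq_len(nrow(seg))) {
    i <- seg$d1[r] + 1L
    j <- seg$d2[r] + 1L
    if (i == 3L && j == 3L) next  # all focal leaves derived: part of the lump
    p[i, j] <- p[i, j] + mu * seg$length[r]
  }
  config_probs(p)
}

#' Simulate a per-site genotype table
#'
#' Draws `m_tot` independent sites from the per-site configuration
#' distribution of `config` (always multinomial sampling) and writes them as
#' a site-record table suitable for [tally_counts()] /
#' [ascertained_tally()], with an outgroup derived-count column when the
#' configuration includes an outgroup.
#'
#' @param config a [demography_config].
#' @return data frame with columns `chrom`, `pos`, `ancestral`, `d1`, `d2`
#'   and, with an outgroup, `d_out`.
#' @export
simulate_site_table <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sp <- .sim_probs(config)
  n <- stats::rmultinom(1, config$m_tot, as.vector(sp$p))[, 1]
  idx <- rep.int(seq_len(27L), n)
  idx <- sample(idx)  # sites are exchangeable; shuffle configuration order
  k <- idx - 1L
  tab <- data.frame(
    chrom = "sim1",
    pos = seq_along(idx),
    ancestral = "A",
    d1 = k %% 3L,
    d2 = (k %/% 3L) %% 3L
  )
  if (!is.null(config$outgroup)) tab$d_out <- k %/% 9L
  tab
}
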