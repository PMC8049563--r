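test_that("demography configurations are validated", {
  expect_error(demography_config(N1 = -1), "N1")
  expect_error(demography_config(gamma = 1.5))
  expect_error(demography_config(delta = 20000, t_split = 10000))
  expect_error(demography_config(outgroup = list(t_out = 500),
                                 t_split = 10000))
  expect_error(demography_config(donor = 3),
               "requires an outgroup")
  expect_error(demography_config(t_split = 1000, lambda = 0.1, tau_b = 5000,
                                 outgroup = list(t_out = 3000)),
               "must end before")
  expect_error(simulate_counts(demography_config(R = 100)), "at least 1000")
})

test_that("identical seed and configuration reproduce output bit-for-bit", {
  cfg <- demography_config(t_split = 5000, m_tot = 1e5, R = 2000,
                           mode = "multinomial", seed = 99)
  s1 <- suppressWarnings(simulate_counts(cfg))
  s2 <- suppressWarnings(simulate_counts(cfg))
  expect_identical(s1$counts$m, s2$counts$m)
  expect_identical(s1$truth$tau2, s2$truth$tau2)
})

test_that("a zero split time gives a single-population coalescent", {
  set.seed(401)
  N <- 12000
  cfg <- demography_config(N1 = N, N2 = N, N_anc = N, t_split = 0, R = 1000)
  tm <- replicate(300, {
    g <- simulate_genealogy(cfg)
    g$tmrca - max(g$coal_times[-length(g$coal_times)]) # last waiting time
  })
  # the final pair coalesces at rate 1/(2N): mean waiting time 2N
  expect_equal(mean(tm), 2 * N, tolerance = 0.15)
  a <- true_alpha(cfg)
  expect_equal(as.numeric(a), c(1, 1))
})

test_that("drift parameters match the closed-form exponential survival", {
  set.seed(402)
  cfg <- demography_config(N1 = 17000, N2 = 8000, t_split = 10000, R = 2e5)
  sim <- suppressWarnings(simulate_counts(cfg))
  cf <- c(exp(-10000 / 34000), exp(-10000 / 16000))
  expect_equal(attr(true_alpha(cfg), "method"), "closed_form")
  expect_equal(as.numeric(true_alpha(cfg)), cf)
  # Monte-Carlo and closed form agree where both apply
  expect_equal(sim$truth$alpha_mc, cf, tolerance = 0.01)
})

test_that("full replacement moves the sampled pair into the donor population", {
  set.seed(403)
  cfg <- demography_config(t_split = 10000, gamma = 1, delta = 0,
                           recipient = 2, R = 5e4)
  a <- suppressWarnings(true_alpha(cfg))
  expect_equal(attr(a, "method"), "monte_carlo")
  # both pairs now live in population 1 (size 17000) for 10000 generations,
  # so each survives without coalescence with probability exp(-10000/34000)
  expect_equal(as.numeric(a), rep(exp(-10000 / 34000), 2), tolerance = 0.02)
})

test_that("the ancestral four-lineage process obeys the Kingman ratios", {
  set.seed(404)
  cfg <- demography_config(t_split = 1000, N_anc = 17000, R = 1000)
  tau <- ancestral_t4_moments(cfg, R = 2e5)
  expect_equal(tau$ET42, 34000, tolerance = 0.02)
  expect_equal(tau$ET43 / tau$ET42, 1 / 3, tolerance = 0.03)
  expect_equal(tau$ET44 / tau$ET43, 1 / 2, tolerance = 0.03)
})

test_that("simulated configuration probabilities match the analytic forward model", {
  set.seed(405)
  N <- 17000
  t <- 10000
  cfg <- demography_config(N1 = N, N2 = N, N_anc = N, t_split = t,
                           m_tot = 1, R = 3e5)
  sim <- simulate_counts(cfg)
  a <- exp(-t / (2 * N))
  # conditional coalescence time of an exponential truncated at t
  V_gen <- 2 * N - t * a / (1 - a)
  pars <- tt_params(a, a, theta = cfg$mu * 2 * N, T1 = cfg$mu * t,
                    T2 = cfg$mu * t, V1 = cfg$mu * V_gen, V2 = cfg$mu * V_gen)
  p_exact <- tt_forward_probs(pars)$p
  p_sim <- sim$counts$m / sim$counts$m_tot
  for (cell in list(c(2, 1), c(1, 2), c(3, 1), c(2, 2), c(3, 2), c(2, 3))) {
    expect_equal(p_sim[cell[1], cell[2]],
                 p_exact[cell[1], cell[2]], tolerance = 0.02)
  }
})

test_that("single-genealogy probabilities are consistent and guarded", {
  set.seed(406)
  cfg <- demography_config(t_split = 3000, R = 1000)
  g <- simulate_genealogy(cfg)
  expect_s3_class(g, "genealogy4")
  expect_equal(nrow(g$segments), 6)  # 3 merges, two children each
  expect_true(all(diff(g$coal_times) > 0))
  p <- genealogy_config_probs(g, 1e-8)
  expect_equal(sum(p$p, na.rm = TRUE) + p$p00_p22, 1)
  expect_equal(sum(p$p, na.rm = TRUE), 1e-8 * sum(g$segments$length),
               tolerance = 1e-9)
  p0 <- genealogy_config_probs(g, 0)
  expect_equal(sum(p0$p, na.rm = TRUE), 0)
  expect_error(genealogy_config_probs(g, 1), "linearity|exceeds 0.1")

  # a genealogy in which both pairs coalesce before the split cannot carry
  # shared polymorphism
  set.seed(11)
  cfg2 <- demography_config(N1 = 50, N2 = 50, t_split = 10000, R = 1000)
  g2 <- simulate_genealogy(cfg2)
  expect_true(g2$H1 && g2$H2)
  expect_equal(genealogy_config_probs(g2, 1e-8)$p["1", "1"], 0)
})

test_that("the R and compiled simulators agree on mean branch lengths", {
  set.seed(407)
  cfg <- demography_config(t_split = 6000, R = 5e4)
  tot_r <- mean(replicate(400, sum(simulate_genealogy(cfg)$segments$length)))
  sim <- suppressWarnings(simulate_counts(cfg))
  tot_cpp <- sum(sim$counts$m[-1] / sim$counts$m_tot) / cfg$mu +
    0 # polymorphic branch mass only
  # compare total tree length via the polymorphic probability mass
  expect_equal(tot_r, tot_cpp, tolerance = 0.1)
})

test_that("expected counts are exactly linear in the number of sites", {
  cfg1 <- demography_config(t_split = 5000, m_tot = 1e6, R = 2000, seed = 5)
  cfg2 <- demography_config(t_split = 5000, m_tot = 2e6, R = 2000, seed = 5)
  c1 <- suppressWarnings(simulate_counts(cfg1))$counts
  c2 <- suppressWarnings(simulate_counts(cfg2))$counts
  expect_equal(2 * c1$m, c2$m, tolerance = 1e-12)
})

test_that("TT underestimation grows with bottleneck duration", {
  set.seed(408)
  lam <- 1500 / 17000
  t_hat <- vapply(c(100, 500, 1000), function(tb) {
    cfg <- demography_config(t_split = 10000, lambda = lam, tau_b = tb,
                             phi = 0, R = 1e5)
    estimate_tt(suppressWarnings(simulate_counts(cfg))$counts)$t1_gen
  }, 0)
  expect_true(all(diff(t_hat) < 0))
  expect_true(all(t_hat < 10000))
})

test_that("multinomial blocks are integer-valued and sum to the expectation scale", {
  cfg <- demography_config(t_split = 5000, m_tot = 1e6, R = 2000,
                           mode = "multinomial", n_blocks = 8, seed = 6)
  sim <- suppressWarnings(simulate_counts(cfg))
  expect_s3_class(sim$counts, "blocked_counts")
  expect_length(sim$counts$blocks, 8L)
  expect_equal(sim$counts$total$m_tot, 1e6)
  expect_true(all(vapply(sim$counts$blocks,
                         function(b) all(b$m == round(b$m)), TRUE)))
})
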