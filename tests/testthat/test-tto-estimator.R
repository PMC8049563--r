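test_that("ascertained drift estimates recover alpha from exact model counts", {
  # oracle: exact ascertained probabilities from the conditional table
  for (pars in list(c(0.9, 0.9), c(0.45, 0.85), c(0.6, 0.3))) {
    b <- c(4e-4, 1.7e-4, 9e-5)  # an arbitrary non-constant spectrum
    cc <- ascertained_counts(pars[1], pars[2], b)
    a <- estimate_alpha_ascertained(cc)
    expect_equal(a$alpha1, pars[1], tolerance = 1e-10)
    expect_equal(a$alpha2, pars[2], tolerance = 1e-10)
    expect_length(a$flags, 0)
  }
})

test_that("no within-population coalescence drives the ascertained alpha to one", {
  cc <- ascertained_counts(1, 1, c(4e-4, 1.7e-4, 9e-5))
  a <- estimate_alpha_ascertained(cc)
  expect_equal(a$alpha1, 1, tolerance = 1e-12)
  expect_equal(a$alpha2, 1, tolerance = 1e-12)
  expect_error(estimate_alpha_ascertained(config_counts(c(m00 = 10))),
               "empty denominator")
})

test_that("tree-ness statistics vanish on symmetric counts and under the model", {
  cc <- config_counts(c(m10 = 50, m01 = 50, m20 = 20, m02 = 20,
                        m21 = 30, m12 = 30, m11 = 40), m_tot = 1e4)
  y <- treeness_tests(cc)
  expect_equal(unname(y), c(0, 0))

  # identically zero on exact ascertained-model probabilities even when the
  # two populations have very different drift
  cc2 <- ascertained_counts(0.3, 0.95, c(4e-4, 1.7e-4, 9e-5))
  y2 <- treeness_tests(cc2)
  expect_equal(unname(y2), c(0, 0), tolerance = 1e-10)
})

test_that("tree-ness statistics are invariant to rescaling all counts", {
  cc <- config_counts(c(m10 = 55, m01 = 48, m20 = 22, m02 = 19,
                        m21 = 33, m12 = 28, m11 = 40), m_tot = 1e4)
  sc <- config_counts(7 * cc$m, m_tot = 7 * cc$m_tot)
  expect_equal(treeness_tests(cc), treeness_tests(sc))
  expect_error(treeness_tests(config_counts(c(m10 = 5), m_tot = 10)),
               "Y1 undefined")
})

test_that("outgroup gene flow shifts Y2 with the sign tracking the recipient", {
  set.seed(301)
  base <- list(t_split = 10000, outgroup = list(t_out = 20000), R = 1e5)
  into2 <- do.call(demography_config,
                   c(base, list(gamma = 0.1, delta = 0, recipient = 2,
                                donor = 3)))
  into1 <- do.call(demography_config,
                   c(base, list(gamma = 0.1, delta = 0, recipient = 1,
                                donor = 3)))
  y2_into2 <- suppressWarnings(
    treeness_tests(simulate_counts(into2)$counts_ascertained)[["Y2"]])
  y2_into1 <- suppressWarnings(
    treeness_tests(simulate_counts(into1)$counts_ascertained)[["Y2"]])
  expect_lt(y2_into2, -0.01)
  expect_gt(y2_into1, 0.01)
})

test_that("TTo with true drift reproduces TT exactly under a constant ancestor", {
  pars <- tt_params(0.8, 0.5, theta = 1e-3, T1 = 1.25e-4, T2 = 6e-5,
                    V1 = 2.5e-5, V2 = 1e-5)
  cc <- expected_counts(tt_forward_probs(pars), 1e7)
  tto <- estimate_tto(cc, pars$alpha1, pars$alpha2)
  th <- pars$theta
  expect_equal(tto$tau2, th, tolerance = 1e-10)
  expect_equal(tto$tau3, th / 3, tolerance = 1e-10)
  # the tau4 approximation (3/2) tau3^2 / tau2 is exact in the constant case
  expect_equal(tto$tau4, th / 6, tolerance = 1e-10)
  expect_equal(tto$B1, pars$T1 + th / 6, tolerance = 1e-10)
  expect_equal(tto$T1, pars$T1, tolerance = 1e-10)
  expect_equal(tto$T2, pars$T2, tolerance = 1e-10)
  expect_equal(tto$V1, pars$V1, tolerance = 1e-10)
  expect_equal(tto$V2, pars$V2, tolerance = 1e-10)

  tt <- estimate_tt(cc)
  expect_equal(tto$T1, tt$T1, tolerance = 1e-10)
  expect_equal(tto$T2, tt$T2, tolerance = 1e-10)

  # under a symmetric model the two printed variants agree exactly
  sym <- tt_params(0.7, 0.7, theta = 1e-3, T1 = 1e-4, T2 = 1e-4,
                   V1 = 2e-5, V2 = 2e-5)
  ccs <- expected_counts(tt_forward_probs(sym), 1e7)
  ttos <- estimate_tto(ccs, 0.7, 0.7)
  expect_equal(ttos$tau2_variants[["m21"]], ttos$tau2_variants[["m12"]],
               tolerance = 1e-10)
  expect_equal(ttos$tau3_variants[["m21"]], ttos$tau3_variants[["m12"]],
               tolerance = 1e-10)
})

test_that("undrifted populations identify tau2 from the cross configurations", {
  th <- 1e-3
  # alpha1 = alpha2 = 1: expected (m11, m21, m12) proportional to
  # (2/3, 1/3, 1/3) * theta, and tau2-hat reduces to 3 * p21
  cc <- config_counts(c(m11 = 2e3 / 3, m21 = 1e3 / 3, m12 = 1e3 / 3),
                      m_tot = 1e6)
  tto <- estimate_tto(cc, 1, 1)
  expect_equal(tto$tau2, 3 * (1e3 / 3) / 1e6, tolerance = 1e-12)
  expect_equal(tto$tau2, th, tolerance = 1e-12)
  # V is unidentifiable at the alpha = 1 boundary
  expect_true(all(c("V1_undefined", "V2_undefined") %in% tto$flags))
  expect_true(is.na(tto$V1))
})

test_that("degenerate TTo inputs give structured errors and flags", {
  expect_error(estimate_tto(config_counts(c(m10 = 5), m_tot = 100), 0.8, 0.8),
               "insufficient shared polymorphism")
  cc <- config_counts(c(m11 = 400, m21 = 400, m12 = 400), m_tot = 1e6)
  expect_error(estimate_tto(cc, 1.2, 0.5), "must lie in")
  # overwhelming shared polymorphism makes tau2-hat negative
  cc2 <- config_counts(c(m11 = 4000, m21 = 10, m12 = 10, m10 = 100,
                         m01 = 100), m_tot = 1e6)
  expect_warning(tto <- estimate_tto(cc2, 0.9, 0.9), "nonpositive")
  expect_true("tau2_nonpositive" %in% tto$flags)
  expect_true(is.na(tto$T1))
  expect_false(is.na(tto$B1))
})

test_that("TTo with true drift beats TT under a severe ancestral bottleneck", {
  set.seed(302)
  cfg <- demography_config(t_split = 10000, lambda = 1500 / 17000,
                           tau_b = 1000, phi = 0, R = 2e5)
  sim <- simulate_counts(cfg)
  a <- true_alpha(cfg)
  t_true <- cfg$mu * cfg$t_split
  tt <- estimate_tt(sim$counts)
  tto <- estimate_tto(sim$counts, a[[1]], a[[2]])
  expect_lt(abs(tto$T1 - t_true), abs(tt$T1 - t_true))
  expect_lt(abs(tto$T2 - t_true), abs(tt$T2 - t_true))
})
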