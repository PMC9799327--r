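test_that("neutral diffusion limits are exact", {
  m0 <- underdominant_model(0, 0)
  for (sg in c(0, 0.5, 0.95))
    expect_equal(fixation_probability_underdominant(1000, sg, m0),
                 1 / 2000, tolerance = 1e-10)
  ft <- single_mutation_fixation_time(1000, 0, 0, 0.5, 1e-5)
  expect_equal(ft$T_wait, 1e5, tolerance = 1e-6)
  expect_equal(ft$T_fix, 4000, tolerance = 0.02)
  expect_equal(ft$T, ft$T_wait + ft$T_fix)
  # selfing shortens the neutral spread time through Ne
  ft_s <- single_mutation_fixation_time(1000, 0.9, 0, 0.5, 1e-5)
  expect_equal(ft_s$T_wait, 1e5, tolerance = 1e-6)
  expect_equal(ft_s$T_fix, 4 * effective_size(1000, 0.9), tolerance = 0.02)
})

test_that("diffusion fixation probabilities match the exact Markov chain", {
  # small-N spot checks; the full sigma x s_u x s grid runs in the
  # acceptance suite
  for (p in list(c(0, 0.01, 0), c(0.5, 0.01, 0.02), c(0.95, 0, 0.02))) {
    m <- underdominant_model(p[2], p[3])
    ch <- wf_exact_fixation_prob(40, p[1], m)$p_fix
    di <- fixation_probability_underdominant(40, p[1], m)
    expect_equal(di, ch, tolerance = 0.05)
  }
  # conditional spread time agrees with the chain at small N
  ch <- wf_exact_fixation_prob(30, 0.4, underdominant_model(0, 0),
                               with_time = TRUE)
  Fx <- wright_fixation_index(0.4)
  tf <- single_mutation_fixation_time(30, 0.4, 0, 0.5, 1e-4)$T_fix
  expect_equal(tf, ch$t_fix, tolerance = 0.12)
})

test_that("fixation probability of an advantaged valley allele rises with selfing", {
  m <- underdominant_model(0.01, 0.02)
  pf <- vapply(c(0, 0.3, 0.6, 0.9), function(sg)
    fixation_probability_underdominant(500, sg, m), 0)
  expect_true(all(diff(pf) > 0))
})

test_that("directional-selection fixation probability has the classical limits", {
  # codominant outcrossing: Kimura formula
  N <- 500; s <- 0.01
  kim <- (1 - exp(-2 * 0.5 * s)) / (1 - exp(-4 * N * 0.5 * s))
  expect_equal(fixation_probability_directional(N, 0, s, 0.5), kim,
               tolerance = 0.01)
  # recessive beneficial mutations fix more easily under selfing
  pr <- vapply(c(0, 0.5, 0.95), function(sg)
    fixation_probability_directional(500, sg, 0.01, 0.1), 0)
  expect_true(all(diff(pr) > 0))
  # dominant beneficial mutations fix less easily under selfing
  pd <- vapply(c(0, 0.5, 0.95), function(sg)
    fixation_probability_directional(500, sg, 0.01, 0.9), 0)
  expect_true(all(diff(pd) < 0))
  # full selfing: deleterious mutation, checked against the exact chain
  # (fitnesses (1, 1 + h s, 1 + s) written in the valley parametrisation)
  N <- 60; s <- -0.005; h <- 0.3
  ph <- fixation_probability_directional(N, 1, s, h)
  ch <- wf_exact_fixation_prob(N, 1, underdominant_model(-h * s, s))$p_fix
  expect_equal(ph, ch, tolerance = 0.05)
})

test_that("gamma-DFE rate and time ratios are reciprocal powers of 1 - sigma", {
  dfe <- gamma_dfe(100, 1)
  expect_equal(relative_rate_gamma_dfe(0, dfe), 1)
  expect_equal(relative_rate_gamma_dfe(0.5, dfe), 2)
  expect_equal(relative_time_gamma_dfe(0.99, gamma_dfe(10, 0.5)),
               0.01^0.5)
  expect_equal(relative_rate_gamma_dfe(0.9, gamma_dfe(5, 0.1)), 10^0.1)
  sg <- seq(0, 0.95, by = 0.05)
  for (beta in c(0.1, 0.5, 1))
    expect_equal(relative_rate_gamma_dfe(sg, gamma_dfe(50, beta)) *
                   relative_time_gamma_dfe(sg, gamma_dfe(50, beta)),
                 rep(1, length(sg)))
  expect_error(relative_rate_gamma_dfe(1, dfe), "diverges")
})

test_that("weak compensatory fixation is a reversed-dominance two-step process", {
  m <- compensatory_model(1e-4, 0.5)
  N <- 1000; mu <- 1e-5
  tw <- compensatory_time_weak(m, N, 0, mu)
  # h_c = 1/2 is self-symmetric: both steps see the same dominance
  expect_equal(tw$first$T_fix, tw$second$T_fix, tolerance = 0.01)
  # nearly neutral: close to two neutral fixations
  neutral <- single_mutation_fixation_time(N, 0, 0, 0.5, mu)$T
  expect_equal(tw$T, 2 * neutral, tolerance = 0.1)
  # dominant deleterious + recessive compensatory: faster under selfing
  md <- compensatory_model(2e-3, 0.8)
  t0 <- compensatory_time_weak(md, 1000, 0, mu)$T
  t9 <- compensatory_time_weak(md, 1000, 0.9, mu)$T
  expect_lt(t9, t0)
  expect_warning(compensatory_time_weak(compensatory_model(0.05, 0.5),
                                        1000, 0, mu), "validity")
})

test_that("strong-effect compensatory time: selfing limits and valley-widening factor", {
  m <- compensatory_model(0.01, 0.3, 0)
  mu <- 1e-5
  # F = 1 vs F = 0 endpoints differ by 1/h_c
  expect_equal(compensatory_time_strong_linked(m, 1000, 1, mu) /
                 compensatory_time_strong_linked(m, 1000, 0, mu), 1 / 0.3)
  expect_equal(compensatory_time_strong_linked(m, 1000, 0, mu),
               0.3 * 0.01 / (2 * mu^2))
  # monotone increase in sigma for all h_c < 1
  for (hc in c(0.1, 0.5, 0.9)) {
    mm <- compensatory_model(0.01, hc, 0)
    tt <- vapply(seq(0, 1, 0.1), function(sg)
      compensatory_time_strong_linked(mm, 1000, sg, mu), 0)
    expect_true(all(diff(tt) > 0))
  }
  # widening factor: 1 as R -> 0, strictly increasing, reduced by selfing
  expect_equal(compensatory_time_strong(m, 1000, 0, mu, r = 0) /
                 compensatory_time_strong_linked(m, 1000, 0, mu),
               1, tolerance = 1e-12)
  expect_equal(compensatory_time_strong(m, 1000, 0, mu, r = 1e-9) /
                 compensatory_time_strong_linked(m, 1000, 0, mu),
               1, tolerance = 1e-5)
  mk <- compensatory_model(0.01, 0.5, 1)
  f <- vapply(c(0.5, 1, 2, 5, 10), function(R)
    selfersim:::.valley_widening_factor(R), 0)
  expect_true(all(diff(f) > 0))
  expect_gt(f[5], 1e3)
  ratio <- function(sg) compensatory_time_strong(mk, 1000, sg, mu, r = 1e-3) /
    compensatory_time_strong_linked(mk, 1000, sg, mu)
  expect_gt(ratio(0), ratio(0.5))
  expect_gt(ratio(0.5), ratio(0.99))
})

test_that("neutral BDMi times: low-mu form, Kimura recurrent form, corrected form", {
  expect_equal(neutral_bdmi_time_low_mu(2.5e-7, 1e4), 1 / 5e-7 + 4e4)
  # waiting-dominated limit
  expect_equal(neutral_bdmi_time_low_mu(1e-6, 1), 1 / 2e-6 + 4,
               tolerance = 1e-10)
  # removable singularity at 4 Ne mu = 1
  expect_equal(kimura_recurrent_time(1e4, 2.5e-5), 4e4 * pi^2 / 6)
  expect_equal(neutral_bdmi_time(2.5e-5, 1e4), 4e4 * pi^2 / 6 - 2e4)
  # Kimura time decreases with mutation rate
  tk <- vapply(c(1e-6, 5e-6, 2.5e-5, 1e-4), function(mu)
    kimura_recurrent_time(1e4, mu), 0)
  expect_true(all(diff(tk) < 0))
  # converges to the low-mu expression when 4 Ne mu is small
  mu <- 2.5e-7; Ne <- 1e4 # 4 Ne mu = 0.01
  expect_equal(neutral_bdmi_time(mu, Ne), neutral_bdmi_time_low_mu(mu, Ne),
               tolerance = 0.2)
  # and the corrected time is independent of sigma given Ne
  expect_identical(neutral_bdmi_time(1e-5, 800), neutral_bdmi_time(1e-5, 800))
})
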