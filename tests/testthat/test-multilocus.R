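test_that("architecture draws follow the gamma spectrum and are reproducible", {
  dfe <- gamma_dfe(100, 1)
  set.seed(8)
  a <- draw_architecture("underdominant", L = 50, N = 1000, dfe = dfe)
  set.seed(8)
  b <- draw_architecture("underdominant", L = 50, N = 1000, dfe = dfe)
  expect_identical(a, b)
  # moment check on the scaled effects 4 N s_u
  set.seed(9)
  big <- draw_architecture("underdominant", L = 1e5, N = 1000,
                           dfe = gamma_dfe(100, 0.5))
  scaled <- big$s_u * 4000
  expect_equal(mean(scaled), 100, tolerance = 0.02)
  expect_equal(var(scaled), 100^2 / 0.5, tolerance = 0.05)
  # shape 1 is exponential: CV = 1
  set.seed(10)
  e <- draw_architecture("underdominant", L = 1e5, N = 1000,
                         dfe = gamma_dfe(100, 1))
  expect_equal(sd(e$s_u) / mean(e$s_u), 1, tolerance = 0.02)
  # pair architectures use disjoint adjacent pairs by default
  p <- draw_architecture("bdmi", L = 6, N = 100,
                         model = bdmi_model("neutral", s_b = 0.01))
  expect_equal(p$pairs, cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_error(draw_architecture("bdmi", L = 4, N = 100,
                                 model = bdmi_model("neutral", s_b = 0.01),
                                 pairs = rbind(c(1, 2), c(2, 3))),
               "disjoint")
})

test_that("without mutation nothing fixes and allele counts drift as a martingale", {
  arch <- draw_architecture("underdominant", L = 8, N = 200,
                            dfe = gamma_dfe(1e-9, 1)) # effectively neutral
  cfg <- sim_config("neutral", mating_system(200, 0.4), mu = 0, r = 0.1,
                    max_generations = 40, replicates = 1, seed = 5)
  rec <- run_multilocus(arch, cfg)
  expect_true(rec$censored)
  # neutral initial polymorphism: mean per-locus count change ~ 0
  cfg2 <- sim_config("neutral", mating_system(200, 0.4), mu = 0, r = 0.1,
                     max_generations = 25, replicates = 30, seed = 21)
  drift <- replicate(30, 0)
  for (i in 1:30) {
    cfg_i <- sim_config("neutral", mating_system(200, 0.4), mu = 0, r = 0.1,
                        max_generations = 26, replicates = 1, seed = 100 + i)
    rec_i <- run_multilocus(arch, cfg_i, init_freq = 0.5,
                            record_interval = 25)
    tr <- attr(rec_i, "trajectories")[[1]]
    drift[i] <- mean(tr$counts[2, ] - tr$counts[1, ]) / 400
  }
  expect_lt(abs(mean(drift)), 3 * sd(drift) / sqrt(30) + 1e-9)
})

test_that("full selfing erodes within-individual heterozygosity", {
  arch <- draw_architecture("underdominant", L = 32, N = 400,
                            dfe = gamma_dfe(1e-9, 1)) # effectively neutral
  cfg <- sim_config("neutral", mating_system(400, 1), mu = 0, r = 0.2,
                    max_generations = 13, replicates = 1, seed = 44)
  rec <- run_multilocus(arch, cfg, init_freq = 0.5, record_interval = 1)
  het <- attr(rec, "trajectories")[[1]]$mean_het_loci
  # starts near L/2 heterozygous loci per individual, then roughly
  # halves each generation of selfing
  expect_equal(het[1], 16, tolerance = 0.1)
  ratios <- het[3:8] / het[2:7]
  expect_equal(mean(ratios), 0.5, tolerance = 0.15)
  expect_lt(het[13], 1)
})

test_that("hand-built populations expose segregating incompatibilities", {
  m <- bdmi_model("neutral", s_b = 0.1, h_b = 0.5, k_b = 0.5)
  arch <- draw_architecture("bdmi", L = 4, N = 4, model = m)
  pop <- array(0L, dim = c(4, 2, 4))
  expect_equal(segregating_incompatibility_count(pop, arch), 0L)
  # one individual carries both derived alleles of pair (1,2) -> fitness
  # cell below 1 -> one segregating incompatibility
  pop[1, 1, 1] <- 1L
  pop[1, 2, 2] <- 1L
  expect_equal(segregating_incompatibility_count(pop, arch), 1L)
  # derived alleles in different individuals do not clash
  pop2 <- array(0L, dim = c(4, 2, 4))
  pop2[1, 1, 1] <- 1L
  pop2[2, 1, 2] <- 1L
  expect_equal(segregating_incompatibility_count(pop2, arch), 0L)
  # compensatory schemes flag lone derived alleles as deleterious:
  # both carriers hit pair (1,2); a third carrier hits pair (3,4)
  mc <- compensatory_model(0.1, 0.5, 0)
  archc <- draw_architecture("compensatory", L = 4, N = 4, model = mc)
  expect_equal(segregating_incompatibility_count(pop2, archc), 1L)
  pop2[3, 2, 3] <- 1L
  expect_equal(segregating_incompatibility_count(pop2, archc), 2L)
})

test_that("a mutation-free multilocus run censors; a mutating one eventually fixes", {
  arch <- draw_architecture("underdominant", L = 4, N = 50,
                            dfe = gamma_dfe(0.1, 1))
  cfg0 <- sim_config("neutral", mating_system(50, 0.5), mu = 0, r = 0.5,
                     max_generations = 100, replicates = 2, seed = 2)
  expect_true(all(run_multilocus(arch, cfg0)$censored))
  cfg1 <- sim_config("neutral", mating_system(50, 0.5), mu = 2e-3, r = 0.5,
                     max_generations = 1e5, replicates = 3, seed = 2)
  rec <- run_multilocus(arch, cfg1)
  expect_true(all(!rec$censored))
  expect_true(all(rec$fixed_locus %in% 1:4))
})

test_that("multilocus engine at L = 2 matches the two-locus frequency engine", {
  # compact cross-engine anchor; the full n = 300 KS comparison runs in
  # the acceptance suite
  m <- bdmi_model("neutral", s_b = 1e-3, h_b = 0.5, k_b = 0.5)
  cfg <- sim_config(m, mating_system(100, 0.3), mu = 1e-3, r = 0.1,
                    max_generations = 1e6, replicates = 150, seed = 61)
  a <- run_two_locus(cfg)
  arch <- draw_architecture("bdmi", L = 2, N = 100, model = m)
  b <- run_multilocus(arch, cfg)
  ks <- suppressWarnings(stats::ks.test(a$generations, b$generations))
  expect_gt(ks$p.value, 0.01)
})
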