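# Desk-scale validation experiments: compact, fully parameterised
# versions of the headline simulation designs, shared by the test suite
# and the acceptance script. Each function reruns the relevant engine
# from scratch and returns plain summaries.

#' Gamma-DFE selfing law at desk scale
#'
#' Multilocus underdominant runs (L = 100 loci, N = 1000, mean scaled
#' effect 100) across selfing rates and DFE shapes, comparing the
#' fixation-time ratio T(sigma)/T(0) with the prediction
#' `(1 - sigma)^beta`. Each replicate draws a fresh architecture
#' (quenched effects). The mutation rate is chosen so that the waiting
#' time for the destined mutation dominates the conditional spread
#' time, the regime in which the law is derived, while keeping runs
#' tractable; see the vignette.
#'
#' @param seed Base seed.
#' @param betas DFE shape parameters.
#' @param sigmas Selfing rates (must include 0, the reference).
#' @param mu Per-locus mutation rate.
#' @param reps Replicates per cell.
#' @param boot Bootstrap resamples for the ratio CIs.
#' @return List with `means` (per-cell mean fixation times) and
#'   `ratios` (data frame: beta, sigma, obs, lo, hi, pred, n).
#' @export
dfe_ratio_experiment <- function(seed = 1, betas = c(0.5, 1),
                                 sigmas = c(0, 0.5, 0.9), mu = 4e-6,
                                 reps = 100, boot = 2000) {
  gamma_mean <- 100; L <- 100; N <- 1000
  cells <- list()
  for (bi in seq_along(betas)) {
    dfe <- gamma_dfe(gamma_mean, betas[bi])
    for (si in seq_along(sigmas)) {
      base <- seed + 10000 * (bi * 10 + si)
      g <- vapply(seq_len(reps), function(i) {
        set.seed(base + i)
        arch <- draw_architecture("underdominant", L = L, N = N, dfe = dfe)
        cfg <- sim_config("neutral", mating_system(N, sigmas[si]),
                          mu = mu, r = 0.01, max_generations = 2e6,
                          replicates = 1, seed = base + 5000 + i)
        run_multilocus(arch, cfg)$generations
      }, 0)
      cells[[sprintf("beta%g_sigma%g", betas[bi], sigmas[si])]] <- g
    }
  }
  means <- vapply(cells, mean, 0)
  ratios <- NULL
  set.seed(seed)
  for (b in betas) {
    g0 <- cells[[sprintf("beta%g_sigma0", b)]]
    for (sg in setdiff(sigmas, 0)) {
      g1 <- cells[[sprintf("beta%g_sigma%g", b, sg)]]
      bs <- replicate(boot, mean(sample(g1, replace = TRUE)) /
                        mean(sample(g0, replace = TRUE)))
      ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
      ratios <- rbind(ratios, data.frame(
        beta = b, sigma = sg, obs = mean(g1) / mean(g0),
        lo = ci[1], hi = ci[2], pred = (1 - sg)^b, n = length(g1)))
    }
  }
  list(means = means, ratios = ratios, cells = cells)
}

#' Compensatory fixation-time orderings at desk scale
#'
#' Two-locus compensatory runs in the strong-effect regime
#' (N = 200, s_c = 0.05, h_c = 0.5, mu = 1e-3, so Ne s_c = 10 and the
#' single-mutant balance frequency stays low). Cells that barely ever
#' fix within the threshold enter the comparison at their censored
#' values, which only strengthens the reported orderings.
#'
#' @param seed Base seed.
#' @param reps Replicates per cell.
#' @param N,s_c,h_c,mu,max_gen Desk-scale run parameters.
#' @return List of mean fixation times (censored entries at the
#'   threshold): `k0_r0`, `k1_r0`, `k0_r01`, `k0_r0_selfing`, plus the
#'   per-cell censoring counts in `censored`.
#' @export
compensatory_ordering_experiment <- function(seed = 1, reps = 80,
                                             N = 200, s_c = 0.05,
                                             h_c = 0.5, mu = 1e-3,
                                             max_gen = 4e4) {
  run_cell <- function(sigma, k_c, r, off) {
    cfg <- sim_config(compensatory_model(s_c, h_c, k_c),
                      mating_system(N, sigma), mu = mu, r = r,
                      max_generations = max_gen, replicates = reps,
                      seed = seed + off)
    run_two_locus(cfg)
  }
  a <- run_cell(0, 0, 0, 0)
  b <- run_cell(0, 1, 0, 1000)
  d <- run_cell(0, 0, 0.1, 2000)
  e <- run_cell(0.99, 0, 0, 3000)
  list(k0_r0 = mean(a$generations), k1_r0 = mean(b$generations),
       k0_r01 = mean(d$generations), k0_r0_selfing = mean(e$generations),
       censored = c(k0_r0 = sum(a$censored), k1_r0 = sum(b$censored),
                    k0_r01 = sum(d$censored),
                    k0_r0_selfing = sum(e$censored)),
       predicted_T00 = c(
         sigma0 = compensatory_time_strong_linked(
           compensatory_model(s_c, h_c, 0), N, 0, mu),
         sigma099 = compensatory_time_strong_linked(
           compensatory_model(s_c, h_c, 0), N, 0.99, mu)))
}

#' Conflict-selection reversal at desk scale
#'
#' BDMi runs at high mutation rate (4 N mu = 1) with selection that
#' decays with selfing, `s = s0 (1 - sigma)`. With `N s0` well above 4
#' the beneficial sweep at low selfing outruns the drift-dominated
#' dynamics of selfers; without conflict selection the segregating
#' incompatibilities penalise outcrossers instead.
#'
#' @param seed Base seed.
#' @param reps Replicates per cell.
#' @param N Census size.
#' @param s0 Baseline conflict selection (`N * s0` = 8 by default).
#' @return List of mean fixation times: `strong_outcross`,
#'   `strong_selfing` (s0 as given), `neutral_outcross`,
#'   `neutral_selfing` (s0 = 0).
#' @export
conflict_experiment <- function(seed = 1, reps = 200, N = 1000,
                                s0 = 8e-3) {
  run_cell <- function(sigma, s0v, off) {
    m <- if (s0v > 0)
      bdmi_model("local_adaptation", s_b = 1e-3, h_b = 0.5, k_b = 0.5,
                 h = 0.5, s0 = s0v)
    else bdmi_model("neutral", s_b = 1e-3, h_b = 0.5, k_b = 0.5)
    cfg <- sim_config(m, mating_system(N, sigma), mu = 2.5e-4, r = 0.5,
                      max_generations = 1e6, replicates = reps,
                      seed = seed + off)
    mean(run_two_locus(cfg)$generations)
  }
  list(strong_outcross = run_cell(0, s0, 0),
       strong_selfing = run_cell(0.99, s0, 1000),
       neutral_outcross = run_cell(0, 0, 2000),
       neutral_selfing = run_cell(0.99, 0, 3000))
}
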