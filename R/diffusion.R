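# Diffusion-approximation predictions: fixation probabilities under
# partial selfing, conditional sojourn times, and the closed-form
# fixation-time approximations for compensatory and neutral BDMi
# mutations.
#
# All fixation probabilities share the Green-function form
#   P_fix(p) = int_0^p G(x) dx / int_0^1 G(x) dx,
#   G(x) = exp(-int_0^x 2 M(y)/V(y) dy),
# with M(y) = y(1-y) f(y) the expected per-generation change and
# V(y) = y(1-y)/(2 Ne), so the inner integral is 4 Ne int f, which is
# polynomial for every selection scheme used here.

# cumulative integral of f for the underdominant scheme (1, 1-su, 1+s)
.H_underdominant <- function(x, su, s, F) {
  (1 - F) * ((2 * su + s) * x^2 / 2 - su * x) + F * s * x
}

# cumulative integral of f for directional selection (1, 1+hs, 1+s):
# f(y) = s (F + h(1-F) + y (1 - F)(1 - 2h))
.H_directional <- function(x, s, h, F) {
  s * ((F + h * (1 - F)) * x + (1 - F) * (1 - 2 * h) * x^2 / 2)
}

.pfix_from_H <- function(N, Ne, H, p = 1 / (2 * N), rel.tol = 1e-8) {
  G <- function(x) exp(-4 * Ne * H(x))
  num <- stats::integrate(G, 0, p, rel.tol = rel.tol)
  den <- stats::integrate(G, 0, 1, rel.tol = rel.tol)
  if (num$message != "OK" || den$message != "OK")
    stop("quadrature failed: ", num$message, " / ", den$message)
  num$value / den$value
}

#' Diffusion fixation probability of a single underdominant mutant
#'
#' Probability that a single copy of the derived allele (initial
#' frequency `1/2N`) ultimately fixes, for genotype fitnesses
#' `(1, 1 - s_u, 1 + s)` in a population selfing at rate `sigma`.
#' Selfing enters twice: through the drift variance (`Ne = N/(1+F)`)
#' and through the exposure of the allele in homozygotes (the `F` terms
#' of [delta_x_underdominant()]).
#'
#' @param N Census population size.
#' @param sigma Selfing rate in `[0, 1]`.
#' @param model An [underdominant_model()].
#' @param p Initial frequency (default a single copy, `1/(2N)`).
#' @return Fixation probability.
#' @export
fixation_probability_underdominant <- function(N, sigma, model,
                                               p = 1 / (2 * N)) {
  stopifnot(inherits(model, "underdominant_model"))
  Fx <- wright_fixation_index(sigma)
  Ne <- effective_size(N, sigma)
  .pfix_from_H(N, Ne, function(x) .H_underdominant(x, model$s_u, model$s, Fx),
               p = p)
}

#' Diffusion fixation probability under directional selection
#'
#' Same machinery for an allele with genotype fitnesses
#' `(1, 1 + h s, 1 + s)` under partial selfing.
#'
#' @inheritParams fixation_probability_underdominant
#' @param s_sel Selection coefficient of the derived homozygote.
#' @param h_sel Dominance coefficient.
#' @return Fixation probability of a single copy.
#' @export
fixation_probability_directional <- function(N, sigma, s_sel, h_sel,
                                             p = 1 / (2 * N)) {
  Fx <- wright_fixation_index(sigma)
  Ne <- effective_size(N, sigma)
  .pfix_from_H(N, Ne, function(x) .H_directional(x, s_sel, h_sel, Fx), p = p)
}

# Conditional sojourn-time integral (Kimura-Ohta): mean time to fixation
# given fixation, from initial frequency p, on a clamped grid.
.tfix_conditional <- function(N, Ne, H, p = 1 / (2 * N), ngrid = 4001) {
  eps <- 1 / (4 * N)
  xs <- seq(eps, 1 - eps, length.out = ngrid)
  Gx <- exp(-4 * Ne * H(xs))
  dx <- xs[2] - xs[1]
  # cumulative scale integral and fixation probability u(x)
  cum <- c(0, cumsum((Gx[-1] + Gx[-length(Gx)]) / 2 * dx))
  C <- cum[length(cum)]
  u <- cum / C
  up <- stats::approx(xs, u, xout = min(max(p, eps), 1 - eps), rule = 2)$y
  V <- xs * (1 - xs) / (2 * Ne)
  t_upper <- 2 * C * u * (1 - u) / (V * Gx)            # x >= p branch
  t_lower <- 2 * C * u^2 * (1 - up) / (up * V * Gx)    # x <  p branch
  w_upper <- as.numeric(xs >= p)
  integrand <- w_upper * t_upper + (1 - w_upper) * t_lower
  sum((integrand[-1] + integrand[-length(integrand)]) / 2 * dx)
}

#' Fixation-time decomposition for a single recurrent mutation
#'
#' Mean number of generations until the first allele destined to fix at
#' a locus mutating at rate `mu` has fixed, split into the waiting time
#' for that allele to arise, `T_wait = 1/(2 N mu P_fix)`, and the mean
#' conditional spread time `T_fix` (Kimura-Ohta sojourn integral). Both
#' the effective-size and the homozygosity effects of selfing are
#' included.
#'
#' @param N Census population size.
#' @param sigma Selfing rate.
#' @param s_sel Selection coefficient of the derived homozygote (may be
#'   negative for a deleterious mutation).
#' @param h_sel Dominance coefficient.
#' @param mu Per-allele mutation rate.
#' @return An object of class `fixation_time` with fields `T_wait`,
#'   `T_fix`, `T` (their sum) and `P_fix`.
#' @examples
#' # neutral: T_wait = 1/mu, T_fix ~ 4 Ne
#' single_mutation_fixation_time(1000, 0, 0, 0.5, 1e-5)
#' @export
single_mutation_fixation_time <- function(N, sigma, s_sel, h_sel, mu) {
  if (abs(2 * N * s_sel) > 100)
    warning("|2 N s| > 100: outside the weak-selection validity range")
  Fx <- wright_fixation_index(sigma)
  Ne <- effective_size(N, sigma)
  H <- function(x) .H_directional(x, s_sel, h_sel, Fx)
  pfix <- .pfix_from_H(N, Ne, H)
  if (pfix < 1e-300) stop("fixation probability underflows: effectively never fixes")
  tw <- 1 / (2 * N * mu * pfix)
  tf <- .tfix_conditional(N, Ne, H)
  structure(list(T_wait = tw, T_fix = tf, T = tw + tf, P_fix = pfix),
            class = "fixation_time")
}

#' @export
print.fixation_time <- function(x, ...) {
  cat(sprintf("T = %.6g generations (T_wait = %.6g, T_fix = %.6g; P_fix = %.3g)\n",
              x$T, x$T_wait, x$T_fix, x$P_fix))
  invisible(x)
}

#' Relative fixation rate under a gamma spectrum of underdominant effects
#'
#' When `4 N s_u` of incoming underdominant mutations follows a Gamma
#' distribution with shape `beta`, the fixation rate in a population
#' selfing at rate `sigma`, relative to an outcrossing population, is
#' approximately `(1 - sigma)^(-beta)`, independent of the mean.
#'
#' @param sigma Selfing rate, < 1.
#' @param dfe A [gamma_dfe()].
#' @return The rate ratio (>= 1).
#' @export
relative_rate_gamma_dfe <- function(sigma, dfe) {
  stopifnot(inherits(dfe, "gamma_dfe"))
  if (any(sigma >= 1)) stop("the rate ratio diverges at sigma = 1")
  (1 - sigma)^(-dfe$beta)
}

#' Relative fixation time under a gamma spectrum of underdominant effects
#'
#' Reciprocal of [relative_rate_gamma_dfe()]: the waiting-time-dominated
#' fixation time scales as `(1 - sigma)^beta`.
#'
#' @inheritParams relative_rate_gamma_dfe
#' @return The time ratio (<= 1).
#' @export
relative_time_gamma_dfe <- function(sigma, dfe) {
  stopifnot(inherits(dfe, "gamma_dfe"))
  (1 - sigma)^dfe$beta
}

#' Two-step fixation time of weak compensatory mutations
#'
#' In the weak-selection regime (`Ne s_c` of order one or below) the
#' pair fixes sequentially: a mildly deleterious mutation (effect
#' `-s_c`, dominance `h_c`) fixes first, then the compensating mutation
#' spreads as beneficial with *reversed* dominance (`+s_c`, dominance
#' `1 - h_c`) in the rescaled background. Returns the sum of the two
#' single-mutation decompositions.
#'
#' @param model A [compensatory_model()].
#' @param N Census population size.
#' @param sigma Selfing rate.
#' @param mu Per-allele mutation rate.
#' @return List with `T`, the two `fixation_time` components
#'   (`first`, `second`), and the validity flag `weak_regime`.
#' @export
compensatory_time_weak <- function(model, N, sigma, mu) {
  stopifnot(inherits(model, "compensatory_model"))
  Ne <- effective_size(N, sigma)
  weak <- Ne * model$s_c <= 5
  if (!weak)
    warning("Ne * s_c > 5: two-step approximation outside its validity range")
  t1 <- single_mutation_fixation_time(N, sigma, -model$s_c, model$h_c, mu)
  t2 <- single_mutation_fixation_time(N, sigma, +model$s_c, 1 - model$h_c, mu)
  list(T = t1$T + t2$T, first = t1, second = t2, weak_regime = weak)
}

#' Joint fixation time of strong, fully linked compensatory mutations
#'
#' With fully linked loci (recombination 0), `k_c = 0` and a deep
#' valley (`Ne s_c >> 1`) the pair
#' crosses jointly: single mutants are held at mutation-selection
#' balance with effective dominance `h_c (1 - F) + F`, a second mutation
#' on such a haplotype creates the neutral double-mutant A2B2 which
#' fixes by drift, giving
#' `T_00 = (h_c (1 - F) + F) s_c / (2 mu^2)`.
#' Monotonically increasing in the selfing rate: selfing always slows
#' this path.
#'
#' @inheritParams compensatory_time_weak
#' @return Predicted mean fixation time (generations).
#' @export
compensatory_time_strong_linked <- function(model, N, sigma, mu) {
  stopifnot(inherits(model, "compensatory_model"))
  Fx <- wright_fixation_index(sigma)
  (model$h_c * (1 - Fx) + Fx) * model$s_c / (2 * mu^2)
}

# sqrt(pi) e^R erf(sqrt(R)) / (2 sqrt(R)); -> 1 as R -> 0
.valley_widening_factor <- function(R) {
  ifelse(R < 1e-10, 1,
         sqrt(pi) * exp(R) * .erf(sqrt(R)) / (2 * sqrt(R)))
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Joint fixation time of strong compensatory mutations
#'
#' Extends [compensatory_time_strong_linked()] to small recombination
#' rates and selected double heterozygotes: with
#' `R = N (1 - sigma)(r + h_c k_c s_c)`, the time is inflated by
#' `sqrt(pi) exp(R) erf(sqrt(R)) / (2 sqrt(R))`, which tends to 1 as
#' `R -> 0` and increases very rapidly with `R`. Both recombination and
#' selection against double heterozygotes impede the joint crossing,
#' and both effects shrink with selfing.
#'
#' @inheritParams compensatory_time_weak
#' @param r Recombination rate between the two loci (small).
#' @return Predicted mean fixation time (generations).
#' @export
compensatory_time_strong <- function(model, N, sigma, mu, r = 0) {
  stopifnot(inherits(model, "compensatory_model"))
  T00 <- compensatory_time_strong_linked(model, N, sigma, mu)
  R <- N * (1 - sigma) * (r + model$h_c * model$k_c * model$s_c)
  T00 * .valley_widening_factor(R)
}

#' Neutral BDMi fixation time at low mutation rate
#'
#' With `4 Ne mu < 1` the two loci rarely segregate simultaneously and
#' the first derived allele fixes as an isolated neutral mutation:
#' `T = 1/(2 mu) + 4 Ne` (mutation can strike either locus, hence the
#' `2 mu`).
#'
#' @param mu Per-allele mutation rate.
#' @param Ne Effective population size.
#' @return Mean fixation time (generations).
#' @export
neutral_bdmi_time_low_mu <- function(mu, Ne) {
  if (4 * Ne * mu >= 1)
    warning("4 Ne mu >= 1: low-mutation approximation outside validity range")
  1 / (2 * mu) + 4 * Ne
}

#' Mean single-locus fixation time under recurrent mutation pressure
#'
#' Kimura's result: `T = 4 Ne (gamma + psi(4 Ne mu)) / (4 Ne mu - 1)`,
#' with `gamma` Euler's constant and `psi` the digamma function. The
#' removable singularity at `4 Ne mu = 1` is `4 Ne pi^2 / 6`.
#'
#' @param Ne Effective population size.
#' @param mu Per-allele mutation rate.
#' @return Mean fixation time (generations).
#' @export
kimura_recurrent_time <- function(Ne, mu) {
  theta <- 4 * Ne * mu
  if (abs(theta - 1) < 1e-8) return(4 * Ne * pi^2 / 6)
  4 * Ne * (-digamma(1) + digamma(theta)) / (theta - 1)
}

#' Neutral BDMi fixation time under recurrent mutation
#'
#' High-mutation-rate refinement of [neutral_bdmi_time_low_mu()]:
#' decomposing Kimura's recurrent-mutation time as waiting plus spread
#' and re-attaching the two-locus waiting time gives
#' `T = T_Kimura - 1/(2 mu)`. This is the neutral reference against
#' which incompatibility effects on fixation time are judged.
#'
#' @inheritParams neutral_bdmi_time_low_mu
#' @param Ne Effective population size.
#' @return Mean fixation time (generations), floored at 0.
#' @export
neutral_bdmi_time <- function(mu, Ne) {
  out <- kimura_recurrent_time(Ne, mu) - 1 / (2 * mu)
  if (out < 0) {
    warning("negative corrected time; floored at 0")
    out <- 0
  }
  out
}
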