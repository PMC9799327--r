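#' Wright's fixation index under partial selfing
#'
#' Equilibrium excess homozygosity of a population reproducing by
#' self-fertilisation at rate `sigma`: `F = sigma / (2 - sigma)`.
#'
#' @param sigma Selfing rate, in `[0, 1]`.
#' @return The fixation index, a number in `[0, 1]`.
#' @examples
#' wright_fixation_index(0)    # outcrossing: 0
#' wright_fixation_index(0.5)  # 1/3
#' wright_fixation_index(1)    # full selfing: 1
#' @export
wright_fixation_index <- function(sigma) {
  if (!is.numeric(sigma) || any(sigma < 0 | sigma > 1 | is.na(sigma)))
    stop("`sigma` must lie in [0, 1]")
  sigma / (2 - sigma)
}

#' Effective population size under partial selfing
#'
#' Pollak's effective size `Ne = N / (1 + F)` with `F = sigma/(2 - sigma)`.
#' Ranges from `N` at full outcrossing down to `N/2` at full selfing.
#'
#' @param N Census population size (diploid individuals), at least 2.
#' @param sigma Selfing rate, in `[0, 1]`.
#' @return Effective population size (not necessarily an integer).
#' @export
effective_size <- function(N, sigma) {
  if (!is.numeric(N) || any(N < 2)) stop("`N` must be >= 2")
  N / (1 + wright_fixation_index(sigma))
}

#' Mating-system descriptor
#'
#' Bundles the census size and selfing rate with the derived fixation
#' index and effective size.
#'
#' @param N Census population size, >= 2.
#' @param sigma Selfing rate in `[0, 1]`.
#' @return An object of class `mating_system` with fields `N`, `sigma`,
#'   `F` and `Ne`.
#' @examples
#' mating_system(1000, 0.5)  # F = 1/3, Ne = 750
#' @export
mating_system <- function(N, sigma) {
  Fx <- wright_fixation_index(sigma)
  structure(
    list(N = N, sigma = sigma, F = Fx, Ne = effective_size(N, sigma)),
    class = "mating_system"
  )
}

#' @export
print.mating_system <- function(x, ...) {
  cat(sprintf("Mating system: N = %g, sigma = %.4g (F = %.4g, Ne = %.6g)\n",
              x$N, x$sigma, x$F, x$Ne))
  invisible(x)
}

#' Dirichlet concentration matching a target effective size
#'
#' A Dirichlet-multinomial resampling step inflates the variance of
#' one-generation genotype-frequency changes by `(N + alpha)/(1 + alpha)`
#' relative to plain multinomial sampling, so that the realised effective
#' size is `Ne = N (1 + alpha)/(N + alpha)`. This inverts that relation
#' to find the concentration `alpha` delivering `Ne_target`.
#'
#' @param N Census population size.
#' @param Ne_target Desired effective size, in `(1, N]`.
#' @return The concentration `alpha` (positive number), or `Inf` when
#'   `Ne_target == N` (no inflation: use plain multinomial drift).
#' @examples
#' a <- dirichlet_alpha_for_Ne(1000, 500.5)  # 1000
#' @export
dirichlet_alpha_for_Ne <- function(N, Ne_target) {
  if (Ne_target <= 1) stop("`Ne_target` must exceed 1")
  if (Ne_target > N) stop("`Ne_target` cannot exceed the census size N")
  if (Ne_target == N) return(Inf)
  N * (Ne_target - 1) / (N - Ne_target)
}

#' Effective size implied by a Dirichlet concentration
#'
#' @param N Census population size.
#' @param alpha Dirichlet concentration; `Inf` means plain multinomial.
#' @return `Ne = N (1 + alpha)/(N + alpha)`.
#' @export
dirichlet_effective_size <- function(N, alpha) {
  if (is.infinite(alpha)) return(N)
  if (alpha <= 0) stop("`alpha` must be positive")
  N * (1 + alpha) / (N + alpha)
}

#' Drift model specification
#'
#' @param kind `"multinomial"` or `"dirichlet_multinomial"`.
#' @param alpha Dirichlet concentration (required for
#'   `"dirichlet_multinomial"`; `Inf` degrades to plain multinomial).
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(kind = c("multinomial", "dirichlet_multinomial"),
                        alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "dirichlet_multinomial") {
    if (is.null(alpha) || !is.numeric(alpha) || alpha <= 0)
      stop("`alpha` must be a positive number for Dirichlet-multinomial drift")
    if (is.infinite(alpha)) kind <- "multinomial"
  } else {
    alpha <- Inf
  }
  structure(list(kind = kind, alpha = alpha), class = "drift_model")
}

#' Background-selection profiles for the effective size
#'
#' Linked selection against recurrent deleterious mutations reduces the
#' effective size at a focal locus, increasingly so at high selfing
#' rates. Rather than a mechanistic model, three parametric profiles
#' return a multiplier in `(0, 1]` applied to Pollak's `Ne`:
#' \describe{
#'   \item{linear}{`1 - c * sigma`, the low-genomic-recombination regime
#'     where the reduction grows steadily with selfing.}
#'   \item{curved}{`1 - c * sigma^kappa` with `kappa > 1`, the
#'     high-genomic-recombination regime where only highly selfing
#'     populations are affected.}
#'   \item{table}{monotone linear interpolation of user-supplied
#'     `(sigma, multiplier)` nodes.}
#' }
#' Defaults `c = 0.6`, `kappa = 6` put the full-selfing multiplier at
#' 0.4, the order of magnitude of strong background selection.
#'
#' @param scenario One of `"linear"`, `"curved"`, `"table"`.
#' @param sigma Selfing rate(s) in `[0, 1]`.
#' @param c Maximum proportional reduction reached at `sigma = 1`.
#' @param kappa Curvature exponent (curved profile only), > 1.
#' @param table Data frame or list with components `sigma` and
#'   `multiplier` (table profile only).
#' @return Multiplier(s) in `(0, 1]`.
#' @export
bgs_ne_profile <- function(scenario = c("linear", "curved", "table"),
                           sigma, c = 0.6, kappa = 6, table = NULL) {
  scenario <- match.arg(scenario)
  if (any(sigma < 0 | sigma > 1)) stop("`sigma` must lie in [0, 1]")
  mult <- switch(scenario,
    linear = 1 - c * sigma,
    curved = 1 - c * sigma^kappa,
    table = {
      if (is.null(table) || is.null(table$sigma) || is.null(table$multiplier))
        stop("table profile needs `table$sigma` and `table$multiplier`")
      if (is.unsorted(table$sigma))
        stop("table nodes must be ordered by sigma")
      stats::approx(table$sigma, table$multiplier, xout = sigma,
                    rule = 2)$y
    }
  )
  if (any(mult <= 0 | mult > 1))
    stop("background-selection multiplier must lie in (0, 1]")
  mult
}

#' Dirichlet concentration emulating background selection
#'
#' Combines a background-selection profile with the mating system to get
#' the Dirichlet concentration for the drift step. By default the
#' multinomial mating scheme is taken to produce the organic `1/(1 + F)`
#' reduction on its own, so `alpha` only encodes the *extra* reduction
#' (`convention = "extra"`). With `convention = "total"` the profile is
#' interpreted as the total `Ne/N` and `alpha` absorbs the selfing
#' reduction as well.
#'
#' @param N Census size.
#' @param sigma Selfing rate.
#' @param scenario,c,kappa,table Passed to [bgs_ne_profile()].
#' @param convention `"extra"` (default) or `"total"`.
#' @return A [drift_model()] object.
#' @export
bgs_drift_model <- function(N, sigma, scenario = "linear", c = 0.6,
                            kappa = 6, table = NULL,
                            convention = c("extra", "total")) {
  convention <- match.arg(convention)
  mult <- bgs_ne_profile(scenario, sigma, c = c, kappa = kappa, table = table)
  target <- if (convention == "extra") N * mult
            else N * mult * (1 + wright_fixation_index(sigma))
  target <- min(target, N)
  alpha <- dirichlet_alpha_for_Ne(N, target)
  if (is.infinite(alpha)) drift_model("multinomial")
  else drift_model("dirichlet_multinomial", alpha = alpha)
}

#' Selection reduced by selfing ("conflict" selection)
#'
#' Mimics genomic or sexual conflicts whose intensity vanishes as
#' outcrossing disappears: `s = s0 (1 - sigma)`.
#'
#' @param s0 Baseline selection coefficient at full outcrossing, >= 0.
#' @param sigma Selfing rate in `[0, 1]`.
#' @return The realised selection coefficient.
#' @export
conflict_selection <- function(s0, sigma) {
  if (any(s0 < 0)) stop("`s0` must be non-negative")
  if (any(sigma < 0 | sigma > 1)) stop("`sigma` must lie in [0, 1]")
  s0 * (1 - sigma)
}
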