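# Two biallelic loci A and B with ancestral alleles A1, B1 and derived
# alleles A2, B2. Haplotypes X1 = A1B1, X2 = A1B2, X3 = A2B1, X4 = A2B2.
# Genotypes Gij pair haplotypes i <= j; G14 (cis) and G23 (trans) are the
# two double heterozygotes, identical in fitness but not in gamete output.

#' Genotype class labels of the two-locus system
#'
#' The ten unordered haplotype pairs, in the fixed order used by every
#' frequency vector and fitness matrix in the package.
#' @return Character vector `c("G11","G12","G13","G14","G22","G23","G24","G33","G34","G44")`.
#' @export
genotype_labels <- function() {
  c("G11", "G12", "G13", "G14", "G22", "G23", "G24", "G33", "G34", "G44")
}

#' Haplotype labels of the two-locus system
#' @return `c("X1","X2","X3","X4")` for A1B1, A1B2, A2B1, A2B2.
#' @export
haplotype_labels <- function() c("X1", "X2", "X3", "X4")

#' Free-form two-locus fitness matrix
#'
#' Wraps ten positive genotype fitnesses as a `fitness_matrix`. Any
#' epistatic two-locus scheme can be entered cell by cell; the built-in
#' constructors ([fitness_underdominant()], [fitness_compensatory()],
#' [fitness_bdmi()]) cover the standard incompatibility models and all
#' satisfy `w14 == w23` (no cis/trans fitness distinction).
#'
#' @param w Numeric vector of 10 positive fitnesses, in
#'   [genotype_labels()] order (names, if present, are checked).
#' @return A named numeric vector of class `fitness_matrix`.
#' @export
fitness_matrix <- function(w) {
  lab <- genotype_labels()
  if (length(w) != 10) stop("a fitness matrix has exactly 10 genotype cells")
  if (!is.null(names(w))) {
    if (!setequal(names(w), lab)) stop("fitness names must be the genotype labels")
    w <- w[lab]
  } else names(w) <- lab
  if (any(!is.finite(w)) || any(w <= 0)) stop("all fitnesses must be positive")
  structure(as.numeric(stats::setNames(w, lab)), names = lab,
            class = "fitness_matrix")
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat("Two-locus fitness matrix (w_ij):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Single-locus underdominant model
#'
#' Genotype fitnesses `1`, `1 - s_u`, `1 + s` for A1A1, A1A2, A2A2: the
#' heterozygote sits in a fitness valley of depth `s_u` and the derived
#' homozygote may carry an advantage `s`.
#'
#' @param s_u Heterozygote disadvantage, >= 0 and < 1.
#' @param s Derived-homozygote advantage (>= -1; usually 0 or small positive).
#' @return An object of class `underdominant_model`.
#' @export
underdominant_model <- function(s_u, s = 0) {
  if (s_u < 0) stop("`s_u` must be non-negative")
  if (1 - s_u <= 0 || 1 + s <= 0) stop("all genotype fitnesses must be positive")
  structure(list(s_u = s_u, s = s), class = "underdominant_model")
}

#' Fitness triple of the underdominant model
#' @param model An [underdominant_model()].
#' @return Named numeric `c(w11 = 1, w12 = 1 - s_u, w22 = 1 + s)`.
#' @export
fitness_underdominant <- function(model) {
  stopifnot(inherits(model, "underdominant_model"))
  c(w11 = 1, w12 = 1 - model$s_u, w22 = 1 + model$s)
}

#' Compensatory-mutation model
#'
#' Each derived allele is deleterious alone (effect `s_c`, dominance
#' `h_c`) but the double-mutant haplotype A2B2 restores full fitness.
#' `k_c` scales the dominance in the double heterozygote: with
#' `k_c = 0` the diagonal path through A1A2;B1B2 is neutral.
#'
#' @param s_c Deleterious effect of a lone derived allele, >= 0.
#' @param h_c Dominance coefficient in single heterozygotes, in `[0, 1]`.
#' @param k_c Dominance factor in double heterozygotes, >= 0.
#' @return An object of class `compensatory_model`.
#' @export
compensatory_model <- function(s_c, h_c = 0.5, k_c = 0) {
  if (s_c < 0) stop("`s_c` must be non-negative")
  if (h_c < 0 || h_c > 1) stop("`h_c` must lie in [0, 1]")
  if (k_c < 0) stop("`k_c` must be non-negative")
  structure(list(s_c = s_c, h_c = h_c, k_c = k_c), class = "compensatory_model")
}

#' Fitness matrix of the compensatory model
#'
#' `w11 = w44 = 1`, `w22 = w33 = 1 - s_c`, single heterozygotes
#' `1 - h_c s_c`, double heterozygotes `1 - h_c k_c s_c`.
#'
#' @param model A [compensatory_model()].
#' @return A [fitness_matrix()].
#' @export
fitness_compensatory <- function(model) {
  stopifnot(inherits(model, "compensatory_model"))
  sc <- model$s_c; hc <- model$h_c; kc <- model$k_c
  fitness_matrix(c(
    G11 = 1,
    G12 = 1 - hc * sc,
    G13 = 1 - hc * sc,
    G14 = 1 - hc * kc * sc,
    G22 = 1 - sc,
    G23 = 1 - hc * kc * sc,
    G24 = 1 - hc * sc,
    G33 = 1 - sc,
    G34 = 1 - hc * sc,
    G44 = 1
  ))
}

#' Bateson-Dobzhansky-Muller incompatibility model
#'
#' Derived alleles A2 and B2 are harmless alone but deleterious when
#' combined in one genome (strength `s_b`, dominance `h_b` when one
#' derived allele is heterozygous, `h_b k_b` in double heterozygotes).
#' Three selective regimes for the derived alleles themselves:
#' \describe{
#'   \item{neutral}{`s = 0`; fixation is driven by drift and mutation.}
#'   \item{local_adaptation}{locus A is under directional selection
#'     (`s > 0`, dominance `h`) in the focal population.}
#'   \item{convergent}{both loci under the same directional selection.}
#' }
#'
#' @param mode One of `"neutral"`, `"local_adaptation"`, `"convergent"`.
#' @param s_b Incompatibility strength, in `[0, 1)`.
#' @param h_b Incompatibility dominance, in `[0, 1]`.
#' @param k_b Extra dominance factor for double heterozygotes, >= 0.
#' @param s Directional selection coefficient (must be 0 in neutral mode).
#' @param h Dominance of the directional selection.
#' @param s0 Optional baseline for selfing-dependent "conflict"
#'   selection; when supplied, `s` is derived as `s0 (1 - sigma)` at
#'   simulation time.
#' @return An object of class `bdmi_model`.
#' @export
bdmi_model <- function(mode = c("neutral", "local_adaptation", "convergent"),
                       s_b = 0, h_b = 0.5, k_b = 0.5, s = 0, h = 0.5,
                       s0 = NULL) {
  mode <- match.arg(mode)
  if (mode == "neutral" && s != 0)
    stop("neutral mode requires s = 0; use local_adaptation or convergent")
  if (s_b < 0 || s_b >= 1) stop("`s_b` must lie in [0, 1)")
  if (h_b < 0 || h_b > 1) stop("`h_b` must lie in [0, 1]")
  if (k_b < 0) stop("`k_b` must be non-negative")
  if (!is.null(s0) && s0 < 0) stop("`s0` must be non-negative")
  structure(list(mode = mode, s_b = s_b, h_b = h_b, k_b = k_b,
                 s = s, h = h, s0 = s0),
            class = "bdmi_model")
}

#' Fitness matrix of the BDMi model
#'
#' Local adaptation: `w11 = w12 = w22 = 1`, `w13 = 1 + h s`,
#' `w33 = 1 + s`, `w24 = (1 + h s)(1 - h_b s_b)`,
#' `w34 = (1 + s)(1 - h_b s_b)`, `w14 = w23 = (1 + h s)(1 - h_b k_b s_b)`,
#' `w44 = (1 + s)(1 - s_b)`. Convergent selection squares the
#' directional terms symmetrically; neutral sets `s = 0`.
#'
#' @param model A [bdmi_model()].
#' @param sigma Selfing rate, used only when the model carries a
#'   conflict baseline `s0` (then `s = s0 (1 - sigma)`).
#' @return A [fitness_matrix()].
#' @export
fitness_bdmi <- function(model, sigma = NULL) {
  stopifnot(inherits(model, "bdmi_model"))
  s <- model$s
  if (!is.null(model$s0)) {
    if (is.null(sigma))
      stop("a conflict-selection model needs `sigma` to resolve s = s0(1 - sigma)")
    s <- conflict_selection(model$s0, sigma)
  }
  h <- model$h; sb <- model$s_b; hb <- model$h_b; kb <- model$k_b
  w <- switch(model$mode,
    neutral = ,
    local_adaptation = c(
      G11 = 1, G12 = 1, G22 = 1,
      G13 = 1 + h * s,
      G33 = 1 + s,
      G24 = (1 + h * s) * (1 - hb * sb),
      G34 = (1 + s) * (1 - hb * sb),
      G14 = (1 + h * s) * (1 - hb * kb * sb),
      G23 = (1 + h * s) * (1 - hb * kb * sb),
      G44 = (1 + s) * (1 - sb)
    ),
    convergent = c(
      G11 = 1,
      G12 = 1 + h * s, G13 = 1 + h * s,
      G22 = 1 + s, G33 = 1 + s,
      G24 = (1 + h * s) * (1 + s) * (1 - hb * sb),
      G34 = (1 + h * s) * (1 + s) * (1 - hb * sb),
      G14 = (1 + h * s)^2 * (1 - hb * kb * sb),
      G23 = (1 + h * s)^2 * (1 - hb * kb * sb),
      G44 = (1 + s)^2 * (1 - sb)
    )
  )
  fitness_matrix(w[genotype_labels()])
}

#' Neutral two-locus fitness matrix
#' @return A [fitness_matrix()] with every cell equal to 1.
#' @export
fitness_neutral <- function() fitness_matrix(rep(1, 10))

#' Gamma distribution of scaled underdominant effects
#'
#' Describes a flow of underdominant mutations whose scaled effects
#' `4 N s_u` follow a Gamma distribution with mean `gamma_mean` and
#' shape `beta`. Small shapes give strongly leptokurtic spectra in which
#' most valleys are shallow.
#'
#' @param gamma_mean Mean of `4 N s_u`, > 0.
#' @param beta Shape parameter, > 0.
#' @return An object of class `gamma_dfe`.
#' @export
gamma_dfe <- function(gamma_mean, beta) {
  if (gamma_mean <= 0) stop("`gamma_mean` must be positive")
  if (beta <= 0) stop("`beta` must be positive")
  structure(list(gamma_mean = gamma_mean, beta = beta), class = "gamma_dfe")
}
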