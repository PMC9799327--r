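# Exact one-generation deterministic recursions for the ten two-locus
# genotype classes, life cycle: meiosis -> syngamy (partial selfing) ->
# mutation -> selection. Drift is added only in the stochastic engines.

.check_simplex <- function(p, what, tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > 1e-8)
    stop(sprintf("%s must be non-negative frequencies summing to 1", what))
}

#' Genotype frequency vector
#'
#' @param ... Named frequencies among [genotype_labels()] (missing
#'   classes are 0), or a single numeric vector of length 10.
#' @return Named numeric vector over the 10 genotype classes.
#' @examples
#' genotype_freqs(G11 = 1)                 # monomorphic ancestral
#' genotype_freqs(G14 = 0.5, G23 = 0.5)    # cis and trans double hets
#' @export
genotype_freqs <- function(...) {
  lab <- genotype_labels()
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && length(args[[1]]) == 10) {
    G <- as.numeric(args[[1]])
    names(G) <- lab
  } else {
    G <- stats::setNames(numeric(10), lab)
    vals <- unlist(args)
    if (is.null(names(vals)) || !all(names(vals) %in% lab))
      stop("arguments must be named with genotype labels G11..G44")
    G[names(vals)] <- vals
  }
  .check_simplex(G, "genotype frequencies")
  G
}

#' Allele frequencies implied by genotype frequencies
#'
#' @param G Genotype frequency vector (see [genotype_freqs()]).
#' @return `c(x = , y = )`: frequencies of the derived alleles A2 and B2.
#' @export
allele_freqs <- function(G) {
  x <- G["G33"] + G["G34"] + G["G44"] +
    (G["G13"] + G["G14"] + G["G23"] + G["G24"]) / 2
  y <- G["G22"] + G["G24"] + G["G44"] +
    (G["G12"] + G["G14"] + G["G23"] + G["G34"]) / 2
  c(x = unname(x), y = unname(y))
}

#' Haplotype frequencies after meiosis
#'
#' Gamete pool produced by the current genotype pool, with recombination
#' at rate `r` between the loci. Only the double heterozygotes are
#' sensitive to `r`: the cis class G14 emits recombinant X2/X3 gametes
#' and the trans class G23 recombinant X1/X4 gametes.
#'
#' @param G Genotype frequency vector.
#' @param r Recombination rate in `[0, 0.5]`.
#' @return Named haplotype frequency vector `X1..X4` summing to 1.
#' @export
meiosis <- function(G, r) {
  if (r < 0 || r > 0.5) stop("`r` must lie in [0, 0.5]")
  .check_simplex(G, "genotype frequencies")
  X <- c(
    X1 = G[["G11"]] + (G[["G12"]] + G[["G13"]] + (1 - r) * G[["G14"]] + r * G[["G23"]]) / 2,
    X2 = G[["G22"]] + (G[["G12"]] + G[["G24"]] + (1 - r) * G[["G23"]] + r * G[["G14"]]) / 2,
    X3 = G[["G33"]] + (G[["G13"]] + G[["G34"]] + (1 - r) * G[["G23"]] + r * G[["G14"]]) / 2,
    X4 = G[["G44"]] + (G[["G24"]] + G[["G34"]] + (1 - r) * G[["G14"]] + r * G[["G23"]]) / 2
  )
  X
}

# Mendelian selfed-offspring transition: each selfed offspring is the
# union of two independent gametes of one parent, derived from gamete
# segregation per parental genotype; column-stochastic by construction.
.syngamy_selfed <- function(G, r) {
  q <- (1 - r)^2; p <- r^2; m <- r * (1 - r)
  c(
    G11 = G[["G11"]] + (G[["G12"]] + G[["G13"]] + p * G[["G23"]] + q * G[["G14"]]) / 4,
    G12 = G[["G12"]] / 2 + m * (G[["G14"]] + G[["G23"]]) / 2,
    G13 = G[["G13"]] / 2 + m * (G[["G14"]] + G[["G23"]]) / 2,
    G14 = (p * G[["G23"]] + q * G[["G14"]]) / 2,
    G22 = G[["G22"]] + (G[["G12"]] + G[["G24"]] + p * G[["G14"]] + q * G[["G23"]]) / 4,
    G23 = (p * G[["G14"]] + q * G[["G23"]]) / 2,
    G24 = G[["G24"]] / 2 + m * (G[["G14"]] + G[["G23"]]) / 2,
    G33 = G[["G33"]] + (G[["G13"]] + G[["G34"]] + p * G[["G14"]] + q * G[["G23"]]) / 4,
    G34 = G[["G34"]] / 2 + m * (G[["G14"]] + G[["G23"]]) / 2,
    G44 = G[["G44"]] + (G[["G24"]] + G[["G34"]] + p * G[["G23"]] + q * G[["G14"]]) / 4
  )
}

#' Genotype frequencies after syngamy under partial selfing
#'
#' An offspring is selfed with probability `sigma` (two independent
#' gametes of one random parent, genotype drawn from `G`) and outcrossed
#' otherwise (random union of two gametes from the pool `Xp`).
#'
#' @param Xp Haplotype frequencies of the gamete pool, normally
#'   `meiosis(G, r)`.
#' @param G Parental genotype frequencies.
#' @param sigma Selfing rate in `[0, 1]`.
#' @param r Recombination rate in `[0, 0.5]`.
#' @return Offspring genotype frequency vector.
#' @export
syngamy <- function(Xp, G, sigma, r) {
  if (sigma < 0 || sigma > 1) stop("`sigma` must lie in [0, 1]")
  .check_simplex(Xp, "haplotype frequencies")
  .check_simplex(G, "genotype frequencies")
  x1 <- Xp[["X1"]]; x2 <- Xp[["X2"]]; x3 <- Xp[["X3"]]; x4 <- Xp[["X4"]]
  outcross <- c(
    G11 = x1 * x1, G12 = 2 * x1 * x2, G13 = 2 * x1 * x3, G14 = 2 * x1 * x4,
    G22 = x2 * x2, G23 = 2 * x2 * x3, G24 = 2 * x2 * x4,
    G33 = x3 * x3, G34 = 2 * x3 * x4, G44 = x4 * x4
  )
  (1 - sigma) * outcross + sigma * .syngamy_selfed(G, r)
}

# 4x4 haplotype mutation kernel: irreversible per-allele mutation
# A1->A2 and B1->B2, each at rate mu, acting independently on the two
# alleles carried by a haplotype.
.hap_mutation_kernel <- function(mu) {
  q <- 1 - mu
  matrix(c(
    q * q, q * mu, mu * q, mu * mu,
    0,     q,      0,      mu,
    0,     0,      q,      mu,
    0,     0,      0,      1
  ), nrow = 4, byrow = TRUE,
  dimnames = list(haplotype_labels(), haplotype_labels()))
}

# index helpers for unordered haplotype pairs
.pair_index <- matrix(0L, 4, 4)
.pair_index[1, ] <- c(1L, 2L, 3L, 4L)
.pair_index[2, ] <- c(2L, 5L, 6L, 7L)
.pair_index[3, ] <- c(3L, 6L, 8L, 9L)
.pair_index[4, ] <- c(4L, 7L, 9L, 10L)
.pair_i <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L)
.pair_j <- c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)

#' Genotype frequencies after mutation
#'
#' Applies irreversible per-allele mutation (A1 to A2 and B1 to B2, each
#' at rate `mu`) to both haplotypes of every genotype class. The
#' treatment is exact at the haplotype level (double mutation of one
#' gamete carries its natural `mu^2` weight), preserves total frequency,
#' and keeps the cis/trans bookkeeping.
#'
#' @param G Genotype frequency vector.
#' @param mu Per-allele mutation rate, `>= 0`; a warning is emitted for
#'   `mu >= 0.1`, far outside the weak-mutation regime the models assume.
#' @return Mutated genotype frequency vector.
#' @export
mutate_genotypes <- function(G, mu) {
  if (mu < 0) stop("`mu` must be non-negative")
  if (mu >= 0.1) warning("mu >= 0.1 is far outside the weak-mutation regime")
  if (mu == 0) return(G)
  .check_simplex(G, "genotype frequencies")
  K <- .hap_mutation_kernel(mu)
  out <- numeric(10)
  for (g in which(G > 0)) {
    i <- .pair_i[g]; j <- .pair_j[g] # unordered pair {i,j}: two haplotypes
    w <- G[g]
    for (a in 1:4) {
      ka <- K[i, a]
      if (ka == 0) next
      for (b in 1:4) {
        kb <- K[j, b]
        if (kb == 0) next
        out[.pair_index[a, b]] <- out[.pair_index[a, b]] + w * ka * kb
      }
    }
  }
  stats::setNames(out, genotype_labels())
}

#' Genotype frequencies after selection
#'
#' Weighted renormalisation `G_ij w_ij / sum(G w)`.
#'
#' @param G Genotype frequency vector.
#' @param W A [fitness_matrix()] (or numeric vector of 10 fitnesses).
#' @return Post-selection genotype frequency vector.
#' @export
select_genotypes <- function(G, W) {
  .check_simplex(G, "genotype frequencies")
  w <- as.numeric(W)
  wbar <- sum(w * G)
  if (wbar <= 0) stop("mean fitness is zero; cannot normalise")
  stats::setNames(w * G / wbar, genotype_labels())
}

#' Mean fitness of a genotype pool
#' @param G Genotype frequency vector.
#' @param W Fitness matrix.
#' @return `sum(G * w)`.
#' @export
mean_fitness <- function(G, W) sum(as.numeric(W) * G)

#' One deterministic generation
#'
#' Composition meiosis -> syngamy -> mutation -> selection (drift-free).
#'
#' @param G Genotype frequency vector.
#' @param W Fitness matrix.
#' @param mating A [mating_system()] (only `sigma` is used here).
#' @param r Recombination rate.
#' @param mu Per-allele mutation rate.
#' @return Next-generation genotype frequency vector.
#' @export
generation_step <- function(G, W, mating, r, mu) {
  sigma <- if (inherits(mating, "mating_system")) mating$sigma else mating
  Xp <- meiosis(G, r)
  Gp <- syngamy(Xp, G, sigma, r)
  Gm <- mutate_genotypes(Gp, mu)
  select_genotypes(Gm, W)
}

#' Deterministic allele-frequency change at an underdominant locus
#'
#' One-generation change of the derived-allele frequency `x` for
#' genotype fitnesses `(1, 1 - s_u, 1 + s)` with genotypes at
#' inbreeding equilibrium (fixation index `F`), to first order in the
#' selection coefficients:
#' `dx = x (1 - x) ((1 - F)((2 s_u + s) x - s_u) + F s)`.
#' At `F = 1` this is `s x (1 - x)`; at `F = 0` it is the classical
#' `x(1-x)((2 s_u + s) x - s_u)`.
#'
#' @param x Derived-allele frequency, in `[0, 1]` (vectorised).
#' @param model An [underdominant_model()].
#' @param F Wright's fixation index in `[0, 1]`.
#' @return The expected change `dx`.
#' @export
delta_x_underdominant <- function(x, model, F) {
  stopifnot(inherits(model, "underdominant_model"))
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]")
  su <- model$s_u; s <- model$s
  x * (1 - x) * ((1 - F) * ((2 * su + s) * x - su) + F * s)
}

#' Interior equilibrium of the underdominant dynamics
#'
#' The unstable equilibrium separating loss from fixation:
#' `x_eq = (s_u - F (s_u + s)) / ((1 - F)(2 s_u + s))`. It is a valid
#' interior equilibrium only when it falls in `(0, 1)`; it reaches 0
#' exactly when the selfing rate hits the threshold of
#' [sigma_threshold()].
#'
#' @param model An [underdominant_model()].
#' @param F Wright's fixation index, < 1.
#' @return The equilibrium frequency (possibly outside `(0,1)`, meaning
#'   no interior equilibrium).
#' @export
unstable_equilibrium <- function(model, F) {
  stopifnot(inherits(model, "underdominant_model"))
  su <- model$s_u; s <- model$s
  if (F >= 1) stop("no interior equilibrium at full selfing (F = 1)")
  if (2 * su + s <= 0) stop("requires 2*s_u + s > 0")
  (su - F * (su + s)) / ((1 - F) * (2 * su + s))
}

#' Selfing threshold above which a rare underdominant mutant is favoured
#'
#' `sigma_lim = 2 s_u / (s + 2 s_u)`: above this selfing rate the
#' marginal fitness of a rare A2 lineage exceeds 1 and the fitness
#' valley disappears.
#'
#' @param model An [underdominant_model()].
#' @return The threshold selfing rate in `[0, 1]`.
#' @export
sigma_threshold <- function(model) {
  stopifnot(inherits(model, "underdominant_model"))
  su <- model$s_u; s <- model$s
  if (2 * su + s <= 0) stop("requires 2*s_u + s > 0")
  2 * su / (s + 2 * su)
}

#' Expected allele-frequency change field of a two-locus model
#'
#' For each grid point `(x, y)` builds genotype frequencies at
#' inbreeding-adjusted Hardy-Weinberg and linkage equilibrium
#' (`G_ii = (1-F) X_i^2 + F X_i`, `G_ij = (1-F) 2 X_i X_j`), applies one
#' deterministic generation (mutation plus selection; meiosis/syngamy
#' leave this construction invariant up to the recursion itself) and
#' records the expected per-generation change of the two derived-allele
#' frequencies together with the population mean fitness. This is the
#' phase-portrait arrow field of the two-locus dynamics.
#'
#' @param W Fitness matrix (or a model object accepted by
#'   [fitness_bdmi()] / [fitness_compensatory()]).
#' @param mating A [mating_system()] or a selfing rate.
#' @param mu Per-allele mutation rate.
#' @param x,y Grid coordinates in `[0, 1]` (all combinations are used).
#' @param r Recombination rate.
#' @return A data frame with columns `x, y, dx, dy, wbar`.
#' @export
expected_change_field <- function(W, mating, mu, x, y, r = 0.5) {
  if (inherits(W, "bdmi_model")) {
    sig <- if (inherits(mating, "mating_system")) mating$sigma else mating
    W <- fitness_bdmi(W, sigma = sig)
  }
  if (inherits(W, "compensatory_model")) W <- fitness_compensatory(W)
  sigma <- if (inherits(mating, "mating_system")) mating$sigma else mating
  Fx <- wright_fixation_index(sigma)
  grid <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1, function(p) {
    X <- c((1 - p[1]) * (1 - p[2]), (1 - p[1]) * p[2],
           p[1] * (1 - p[2]), p[1] * p[2])
    G <- numeric(10)
    for (g in 1:10) {
      i <- .pair_i[g]; j <- .pair_j[g]
      G[g] <- if (i == j) (1 - Fx) * X[i]^2 + Fx * X[i]
              else (1 - Fx) * 2 * X[i] * X[j]
    }
    G <- stats::setNames(G, genotype_labels())
    G2 <- generation_step(G, W, sigma, r, mu)
    af0 <- allele_freqs(G)
    af1 <- allele_freqs(G2)
    c(af1 - af0, mean_fitness(G, W))
  }))
  data.frame(x = grid$x, y = grid$y,
             dx = res[, 1], dy = res[, 2], wbar = res[, 3])
}
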