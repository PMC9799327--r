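test_that("meiosis produces the expected gamete pool, tracking cis and trans classes", {
  expect_equal(unname(meiosis(genotype_freqs(G11 = 1), 0.2)), c(1, 0, 0, 0))
  # cis double heterozygote: no recombinant gametes at r = 0
  X <- meiosis(genotype_freqs(G14 = 1), 0)
  expect_equal(unname(X), c(0.5, 0, 0, 0.5))
  # trans double heterozygote mirrors it
  X <- meiosis(genotype_freqs(G23 = 1), 0)
  expect_equal(unname(X), c(0, 0.5, 0.5, 0))
  # free recombination randomises the double heterozygote
  X <- meiosis(genotype_freqs(G14 = 1), 0.5)
  expect_equal(unname(X), rep(0.25, 4))
  expect_error(meiosis(genotype_freqs(G11 = 1), 0.6), "r")
})

test_that("syngamy matches Mendelian selfing and reduces to random union at sigma 0", {
  # full selfing of a one-locus heterozygote: 1/4, 1/2, 1/4
  G <- genotype_freqs(G12 = 1)
  Gp <- syngamy(meiosis(G, 0.3), G, 1, 0.3)
  expect_equal(unname(Gp[c("G11", "G12", "G22")]), c(0.25, 0.5, 0.25))
  # full selfing of the cis double heterozygote at r = 0
  G <- genotype_freqs(G14 = 1)
  Gp <- syngamy(meiosis(G, 0), G, 1, 0)
  expect_equal(unname(Gp[c("G11", "G14", "G44")]), c(0.25, 0.5, 0.25))
  # outcrossing is random union of gametes
  G <- genotype_freqs(G11 = 1)
  expect_equal(unname(syngamy(meiosis(G, 0.1), G, 0, 0.1)["G11"]), 1)
  set.seed(42)
  for (G in random_genotype_freqs(3)) {
    X <- meiosis(G, 0.23)
    G0 <- syngamy(X, G, 0, 0.23)
    expect_equal(unname(G0["G13"]), 2 * X[["X1"]] * X[["X3"]])
    expect_equal(unname(G0["G22"]), X[["X2"]]^2)
  }
})

test_that("every life-cycle operation maps the simplex to the simplex", {
  set.seed(7)
  for (G in random_genotype_freqs(8)) {
    r <- runif(1, 0, 0.5); sg <- runif(1); mu <- runif(1, 0, 0.01)
    X <- meiosis(G, r)
    expect_equal(sum(X), 1, tolerance = 1e-12)
    Gp <- syngamy(X, G, sg, r)
    expect_equal(sum(Gp), 1, tolerance = 1e-12)
    expect_true(all(Gp >= -1e-15))
    Gm <- mutate_genotypes(Gp, mu)
    expect_equal(sum(Gm), 1, tolerance = 1e-12)
    W <- fitness_compensatory(compensatory_model(0.3, 0.4, 0.5))
    Gs <- select_genotypes(Gm, W)
    expect_equal(sum(Gs), 1, tolerance = 1e-12)
  }
})

test_that("mutation is irreversible, exact in total mass, and O(mu) in allele frequency", {
  G <- genotype_freqs(G11 = 1)
  expect_identical(mutate_genotypes(G, 0), G)
  mu <- 1e-4
  Gm <- mutate_genotypes(G, mu)
  af <- allele_freqs(Gm)
  # per-allele mutation moves each derived frequency to exactly mu
  expect_equal(unname(af["x"]), mu, tolerance = 1e-12)
  expect_equal(unname(af["y"]), mu, tolerance = 1e-12)
  # monomorphic derived state is left untouched
  G44 <- genotype_freqs(G44 = 1)
  expect_equal(mutate_genotypes(G44, 0.01), G44)
  expect_warning(mutate_genotypes(G, 0.2), "weak-mutation")
})

test_that("selection is fitness-weighted renormalisation, invariant to fitness scale", {
  G <- genotype_freqs(G11 = 0.5, G22 = 0.5)
  W <- fitness_matrix(stats::setNames(c(1, rep(1, 3), 0.5, rep(1, 5)),
                                      genotype_labels()))
  Gs <- select_genotypes(G, W)
  expect_equal(unname(Gs["G11"]), 2 / 3)
  expect_equal(unname(Gs["G22"]), 1 / 3)
  expect_equal(select_genotypes(G, fitness_matrix(as.numeric(W) * 10)), Gs)
  expect_equal(select_genotypes(G, fitness_neutral()), G)
})

test_that("allele frequencies are conserved by the neutral drift-free step", {
  set.seed(13)
  W <- fitness_neutral()
  for (G in random_genotype_freqs(5)) {
    sg <- runif(1); r <- runif(1, 0, 0.5)
    G2 <- generation_step(G, W, mating_system(100, sg), r, 0)
    expect_equal(allele_freqs(G2), allele_freqs(G), tolerance = 1e-12)
  }
})

test_that("full selfing halves heterozygosity each generation", {
  W <- fitness_neutral()
  m <- mating_system(100, 1)
  # per-locus heterozygosity halves for any r
  G <- genotype_freqs(G14 = 0.4, G23 = 0.4, G12 = 0.2)
  for (r in c(0, 0.2, 0.5)) {
    h0 <- locus_het(G)
    G1 <- generation_step(G, W, m, r, 0)
    expect_equal(locus_het(G1), h0 / 2, tolerance = 1e-12)
  }
  # joint (any-locus) heterozygosity halves when loci are fully linked
  G <- genotype_freqs(G14 = 0.5, G23 = 0.5)
  het <- function(G) sum(G[c("G12", "G13", "G14", "G23", "G24", "G34")])
  h <- het(G)
  for (i in 1:4) {
    G <- generation_step(G, W, m, 0, 0)
    h <- h / 2
    expect_equal(het(G), h, tolerance = 1e-12)
  }
})

test_that("relabelling the loci commutes with the step for symmetric fitness", {
  # A <-> B exchange permutes haplotypes X2 <-> X3, hence genotypes:
  swap <- c(G11 = "G11", G12 = "G13", G13 = "G12", G14 = "G14",
            G22 = "G33", G23 = "G23", G24 = "G34", G33 = "G22",
            G34 = "G24", G44 = "G44")
  relabel <- function(G) stats::setNames(G[swap], names(swap))
  set.seed(99)
  Ws <- list(fitness_compensatory(compensatory_model(0.02, 0.3, 0.5)),
             fitness_bdmi(bdmi_model("convergent", s = 1e-3, h = 0.3,
                                     s_b = 0.01, h_b = 0.4, k_b = 0.5)))
  for (W in Ws) {
    for (G in random_genotype_freqs(3)) {
      a <- relabel(generation_step(G, W, mating_system(50, 0.4), 0.1, 1e-4))
      b <- generation_step(relabel(G), W, mating_system(50, 0.4), 0.1, 1e-4)
      expect_equal(unname(a), unname(b), tolerance = 1e-12)
    }
  }
})

test_that("underdominant deterministic dynamics: boundaries, equilibrium, threshold", {
  m <- underdominant_model(0.01, 0.02)
  expect_equal(delta_x_underdominant(c(0, 1), m, 0.3), c(0, 0))
  # interior equilibrium is a root of the change (F below the threshold
  # value s_u/(s_u + s) = 1/3, where the equilibrium is interior)
  for (F in c(0, 0.15, 0.3)) {
    xeq <- unstable_equilibrium(m, F)
    expect_equal(delta_x_underdominant(xeq, m, F), 0, tolerance = 1e-15)
  }
  # symmetric valley without homozygote advantage sits at 1/2
  expect_equal(unstable_equilibrium(underdominant_model(0.01, 0), 0), 0.5)
  expect_equal(unstable_equilibrium(m, 0), 0.01 / 0.04)
  # full selfing limit: dx = s x(1-x)
  expect_equal(delta_x_underdominant(0.5, underdominant_model(0.3, 0.01), 1),
               0.0025)
  expect_error(unstable_equilibrium(m, 1), "full selfing")
  # threshold values
  expect_equal(sigma_threshold(underdominant_model(0.01, 0)), 1)
  expect_equal(sigma_threshold(underdominant_model(0, 0.02)), 0)
  expect_equal(sigma_threshold(underdominant_model(0.01, 0.01)), 2 / 3)
  # the equilibrium leaves (0,1) exactly at the threshold selfing rate
  xeq_at <- function(sg, m) unstable_equilibrium(m, wright_fixation_index(sg))
  m2 <- underdominant_model(0.005, 0.015)
  expect_equal(xeq_at(sigma_threshold(m2), m2), 0, tolerance = 1e-12)
})

test_that("rare-mutant selection changes sign exactly at the selfing threshold", {
  eps <- 1e-12 # rare-mutant limit: the O(x) term must dominate
  grid <- expand.grid(su = c(0.001, 0.01, 0.05), s = c(0.001, 0.01, 0.1))
  for (i in seq_len(nrow(grid))) {
    m <- underdominant_model(grid$su[i], grid$s[i])
    sl <- sigma_threshold(m)
    Fb <- wright_fixation_index(sl - 1e-4)
    Fa <- wright_fixation_index(sl + 1e-4)
    expect_lt(delta_x_underdominant(eps, m, Fb), 0)
    expect_gt(delta_x_underdominant(eps, m, Fa), 0)
    expect_equal(delta_x_underdominant(eps, m, wright_fixation_index(sl)) /
                   (eps * (1 - eps)), 0, tolerance = 1e-10)
  }
})

test_that("expected-change field: zero under neutrality, mutation pressure at the origin", {
  f0 <- expected_change_field(fitness_neutral(), mating_system(100, 0.3),
                              0, x = c(0.2, 0.6), y = c(0.1, 0.8))
  expect_true(all(abs(f0$dx) < 1e-12 & abs(f0$dy) < 1e-12))
  expect_true(all(abs(f0$wbar - 1) < 1e-12))
  mu <- 1e-4
  f1 <- expected_change_field(fitness_neutral(), mating_system(100, 0),
                              mu, x = 0, y = 0)
  expect_equal(f1$dx, mu, tolerance = 1e-10)
  expect_equal(f1$dy, mu, tolerance = 1e-10)
  # one-locus degeneration matches the single-locus selection term:
  # restrict to y = 0 so only the A locus segregates
  m <- underdominant_model(0.01, 0.02)
  W <- fitness_matrix(stats::setNames(
    c(1, 1, 1 - m$s_u, 1 - m$s_u, 1, 1 - m$s_u, 1 - m$s_u,
      1 + m$s, 1 + m$s, 1 + m$s), genotype_labels()))
  for (sg in c(0, 0.6)) {
    Fx <- wright_fixation_index(sg)
    fld <- expected_change_field(W, mating_system(100, sg), 0,
                                 x = c(0.1, 0.45, 0.9), y = 0)
    pred <- delta_x_underdominant(c(0.1, 0.45, 0.9), m, Fx)
    expect_equal(sign(fld$dx), sign(pred))
    expect_equal(fld$dx, pred, tolerance = 0.05)
  }
})
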