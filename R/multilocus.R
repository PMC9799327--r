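# Individual-based multilocus simulation: diploid genomes of L loci,
# recurrent irreversible mutation, crossovers between adjacent loci,
# partial selfing, viability selection, constant census size.

#' Draw a multilocus genetic architecture
#'
#' For the underdominant architecture each locus gets its own
#' heterozygote disadvantage, drawn so that `4 N s_u` follows the
#' [gamma_dfe()] (mean `gamma_mean`, shape `beta`); effects are frozen
#' at draw time (quenched). Pairwise architectures (compensatory, BDMi)
#' share one fitness scheme across disjoint locus pairs
#' `(1,2), (3,4), ...` unless `pairs` is supplied.
#'
#' @param type `"underdominant"`, `"compensatory"` or `"bdmi"`.
#' @param L Number of loci.
#' @param N Census size (used to unscale the DFE draws).
#' @param dfe A [gamma_dfe()] (underdominant type only).
#' @param model A [compensatory_model()] or [bdmi_model()] (pair types).
#' @param s_hom Optional per-locus derived-homozygote advantage
#'   (underdominant type; recycled; default 0).
#' @param pairs Optional two-column matrix of 1-based interacting locus
#'   pairs (pair types); pairs must be disjoint.
#' @param sigma Selfing rate, needed only to resolve a conflict-selection
#'   BDMi model into a fitness matrix.
#' @return An object of class `architecture`.
#' @export
draw_architecture <- function(type = c("underdominant", "compensatory", "bdmi"),
                              L, N, dfe = NULL, model = NULL, s_hom = 0,
                              pairs = NULL, sigma = NULL) {
  type <- match.arg(type)
  if (L < 1) stop("`L` must be at least 1")
  arch <- list(type = type, L = as.integer(L))
  if (type == "underdominant") {
    stopifnot(inherits(dfe, "gamma_dfe"))
    scaled <- stats::rgamma(L, shape = dfe$beta,
                            rate = dfe$beta / dfe$gamma_mean)
    arch$s_u <- scaled / (4 * N)
    arch$s_hom <- rep_len(s_hom, L)
    arch$pairs <- matrix(integer(0), 0, 2)
    arch$w10 <- rep(1, 10)
  } else {
    if (is.null(pairs)) {
      np <- L %/% 2
      pairs <- cbind(2 * seq_len(np) - 1, 2 * seq_len(np))
    }
    pairs <- as.matrix(pairs)
    if (anyDuplicated(as.vector(pairs)))
      stop("interacting pairs must be disjoint")
    if (any(pairs < 1 | pairs > L)) stop("pair indices out of range")
    W <- if (type == "compensatory") {
      stopifnot(inherits(model, "compensatory_model"))
      fitness_compensatory(model)
    } else {
      stopifnot(inherits(model, "bdmi_model"))
      fitness_bdmi(model, sigma = sigma)
    }
    arch$pairs <- pairs
    arch$w10 <- as.numeric(W)
    arch$s_u <- numeric(L)
    arch$s_hom <- numeric(L)
  }
  structure(arch, class = "architecture")
}

.arch_wmax <- function(arch) {
  if (arch$type == "underdominant")
    prod(pmax(1, 1 + arch$s_hom, 1 - arch$s_u))
  else max(1, max(arch$w10))^nrow(arch$pairs)
}

#' Multilocus forward simulation
#'
#' Runs the individual-based engine for each replicate: every offspring
#' is selfed with probability `sigma` or formed from two random
#' parents; gametes recombine between adjacent loci at rate `r` and
#' mutate (ancestral to derived) at rate `mu` per locus; offspring
#' survive viability selection with multiplicative fitness across loci
#' (underdominant) or interacting pairs (compensatory, BDMi). A
#' replicate stops at the first fixation of a derived state: any locus
#' (underdominant), either member of any pair (BDMi), or both members
#' of a pair (compensatory); otherwise it censors at `max_generations`.
#'
#' @param arch An [draw_architecture()] object (reused across
#'   replicates; redraw per replicate yourself for a quenched-random
#'   design).
#' @param config A [sim_config()]; its `r` is the between-adjacent-loci
#'   recombination rate and its drift model must be multinomial (the
#'   engine is individual-based).
#' @param init_freq Initial derived-allele frequency applied
#'   independently to every allele copy (default 0: all ancestral).
#' @param record_interval If positive, record per-locus derived-allele
#'   counts (and, for pair types, the number of pairs with an
#'   incompatible genotype present) every this many generations.
#' @return A `fixation_records` data frame with an extra `fixed_locus`
#'   column; recorded trajectories are attached as the
#'   `"trajectories"` attribute (one list element per replicate).
#' @export
run_multilocus <- function(arch, config, init_freq = 0,
                           record_interval = 0) {
  stopifnot(inherits(arch, "architecture"), inherits(config, "sim_config"))
  if (!is.null(config$drift) && config$drift$kind != "multinomial")
    stop("the multilocus engine supports multinomial drift only")
  N <- config$mating$N
  type_i <- if (arch$type == "underdominant") 0L else 1L
  stop_i <- if (arch$type == "compensatory") 1L else 0L
  pairs0 <- if (nrow(arch$pairs)) arch$pairs - 1L else arch$pairs
  storage.mode(pairs0) <- "integer"
  wmax <- .arch_wmax(arch)
  rows <- vector("list", config$replicates)
  traj <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    sd_i <- config$seed + i - 1
    set.seed(sd_i)
    res <- cpp_run_multilocus(N, arch$L, config$mating$sigma, config$r,
                              config$mu, config$max_generations, type_i,
                              arch$s_u, arch$s_hom, pairs0, arch$w10,
                              wmax, stop_i, init_freq,
                              as.integer(record_interval),
                              type_i == 1L)
    rows[[i]] <- data.frame(replicate = i, seed = sd_i,
                            generations = res$generations,
                            outcome = .outcome_labels[as.character(res$outcome)],
                            censored = res$censored,
                            fixed_locus = res$fixed_locus)
    if (record_interval > 0) {
      tr <- list(generation = res$trajectory_generations,
                 counts = matrix(res$trajectory_counts, ncol = arch$L,
                                 byrow = TRUE),
                 mean_het_loci = res$trajectory_het)
      if (!is.null(res$segregating_incompatibilities))
        tr$segregating <- res$segregating_incompatibilities
      traj[[i]] <- tr
    }
  }
  out <- .records_df(rows)
  out$fixed_locus <- as.integer(out$fixed_locus)
  if (record_interval > 0) attr(out, "trajectories") <- traj
  out
}

#' Count locus pairs with segregating incompatibilities
#'
#' For a hand-specified population (a 0/1 array `N x 2 x L` of derived
#' alleles), counts the interacting pairs for which at least one
#' individual carries a genotype whose pair fitness falls below 1,
#' i.e. an incompatible (or, for compensatory schemes, deleterious
#' intermediate) genotype is actually present.
#'
#' @param haplotypes Integer/logical array of dimension `c(N, 2, L)`.
#' @param arch An [draw_architecture()] object of a pair type.
#' @return Integer count of affected pairs.
#' @export
segregating_incompatibility_count <- function(haplotypes, arch) {
  stopifnot(inherits(arch, "architecture"), arch$type != "underdominant")
  d <- dim(haplotypes)
  if (length(d) != 3 || d[2] != 2) stop("`haplotypes` must be N x 2 x L")
  pairs <- arch$pairs
  w10 <- arch$w10
  pair_index <- matrix(c(1, 2, 3, 4, 2, 5, 6, 7, 3, 6, 8, 9, 4, 7, 9, 10), 4, 4)
  nseg <- 0L
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    c1 <- haplotypes[, 1, a] * 2 + haplotypes[, 1, b] + 1
    c2 <- haplotypes[, 2, a] * 2 + haplotypes[, 2, b] + 1
    cells <- pair_index[cbind(c1, c2)]
    if (any(w10[cells] < 1)) nseg <- nseg + 1L
  }
  nseg
}
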