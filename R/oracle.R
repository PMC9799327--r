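# Exact single-locus Wright-Fisher computation by absorbing Markov
# chain. The state is the genotype composition (number of heterozygotes,
# number of derived homozygotes) of N diploid individuals; one step is
# the same life cycle as the stochastic engine (meiosis, partial
# selfing, selection, multinomial resampling), so absorption
# probabilities and times are exact for the finite population. Used as
# an independent check of the diffusion approximations; O(N^4) work and
# O(N^4) memory, intended for N up to ~60.

.wf_states <- function(N) {
  # all (n12, n22) with n12 + n22 <= N
  n12 <- unlist(lapply(0:N, function(i) rep(i, N - i + 1)))
  n22 <- unlist(lapply(0:N, function(i) 0:(N - i)))
  cbind(n12 = n12, n22 = n22)
}

.wf_offspring_probs <- function(n12, n22, N, sigma, w) {
  g11 <- (N - n12 - n22) / N; g12 <- n12 / N; g22 <- n22 / N
  xg <- g12 / 2 + g22                       # gamete frequency of A2
  p11 <- (1 - sigma) * (1 - xg)^2 + sigma * (g11 + g12 / 4)
  p12 <- (1 - sigma) * 2 * xg * (1 - xg) + sigma * g12 / 2
  p22 <- (1 - sigma) * xg^2 + sigma * (g22 + g12 / 4)
  p <- c(p11, p12, p22) * w
  p / sum(p)
}

#' Exact fixation probability of a single underdominant mutant
#'
#' Builds the full transition matrix of the genotype-composition Markov
#' chain for `N` diploids under partial selfing and selection
#' `(1, 1 - s_u, 1 + s)`, and solves the absorption problem starting
#' from one heterozygous carrier. No diffusion or weak-selection
#' approximation is involved.
#'
#' @param N Census population size (kept small; cost grows as `N^4`).
#' @param sigma Selfing rate.
#' @param model An [underdominant_model()].
#' @param with_time If `TRUE`, also return the mean absorption time
#'   conditional on fixation.
#' @return A list with `p_fix` (and `t_fix` when requested).
#' @export
wf_exact_fixation_prob <- function(N, sigma, model, with_time = FALSE) {
  stopifnot(inherits(model, "underdominant_model"))
  w <- c(1, 1 - model$s_u, 1 + model$s)
  st <- .wf_states(N)
  M <- nrow(st)
  loss <- which(st[, 1] == 0 & st[, 2] == 0)
  fixd <- which(st[, 1] == 0 & st[, 2] == N)
  # row-wise multinomial transition probabilities
  P <- matrix(0, M, M)
  k12 <- st[, 1]; k22 <- st[, 2]
  for (i in seq_len(M)) {
    if (i == loss || i == fixd) { P[i, i] <- 1; next }
    p <- .wf_offspring_probs(st[i, 1], st[i, 2], N, sigma, w)
    # P(k12) * P(k22 | k12)
    pr12 <- stats::dbinom(k12, N, p[2])
    p22c <- if (p[2] >= 1) 0 else p[3] / (1 - p[2])
    pr22 <- stats::dbinom(k22, N - k12, min(p22c, 1))
    P[i, ] <- pr12 * pr22
  }
  trans <- setdiff(seq_len(M), c(loss, fixd))
  Q <- P[trans, trans, drop = FALSE]
  b <- P[trans, fixd]
  IQ <- diag(length(trans)) - Q
  u <- solve(IQ, b)
  start <- which(st[, 1] == 1 & st[, 2] == 0)
  ustart <- u[match(start, trans)]
  out <- list(p_fix = ustart)
  if (with_time) {
    h <- solve(IQ, u)                 # E[T * 1{fix}]
    out$t_fix <- h[match(start, trans)] / ustart
  }
  out
}
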