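# R-level interface to the stochastic engines.

#' Simulation configuration
#'
#' @param model An [underdominant_model()], [compensatory_model()],
#'   [bdmi_model()], the string `"neutral"`, or a raw
#'   [fitness_matrix()].
#' @param mating A [mating_system()].
#' @param mu Per-allele mutation rate.
#' @param r Recombination rate (two-locus engines).
#' @param drift A [drift_model()]; default plain multinomial.
#' @param max_generations Censoring threshold (replicates still running
#'   at this generation are recorded as censored).
#' @param replicates Number of independent replicates.
#' @param seed Base RNG seed; replicate `i` runs under
#'   `set.seed(seed + i - 1)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model, mating, mu, r = 0.5,
                       drift = drift_model("multinomial"),
                       max_generations = 1e9, replicates = 1, seed = 1) {
  stopifnot(inherits(mating, "mating_system"),
            max_generations >= 1, replicates >= 1)
  if (mu < 0) stop("`mu` must be non-negative")
  structure(list(model = model, mating = mating, mu = mu, r = r,
                 drift = drift, max_generations = max_generations,
                 replicates = replicates, seed = seed),
            class = "sim_config")
}

.drift_alpha <- function(drift) {
  if (is.null(drift) || drift$kind == "multinomial" ||
      is.infinite(drift$alpha)) -1 else drift$alpha
}

.outcome_labels <- c(`0` = "A2 fixed", `1` = "B2 fixed", `2` = "A2B2 fixed",
                     `3` = "censored", `4` = "lost")

.records_df <- function(rows) {
  df <- do.call(rbind, rows)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$replicate <- as.integer(df$replicate)
  df$seed <- as.numeric(df$seed)
  df$generations <- as.numeric(df$generations)
  df$outcome <- as.character(df$outcome)
  df$censored <- as.logical(df$censored)
  class(df) <- c("fixation_records", "data.frame")
  df
}

#' Single-locus Wright-Fisher simulation
#'
#' Simulates `N` hermaphrodites at one biallelic locus under the life
#' cycle meiosis, partial selfing, irreversible mutation, selection
#' `(1, 1 - s_u, 1 + s)` and multinomial (or Dirichlet-multinomial)
#' resampling, until the derived allele fixes or `max_generations` is
#' reached. Starts monomorphic ancestral unless `init` is given.
#'
#' @param config A [sim_config()] whose model is an
#'   [underdominant_model()] or `"neutral"`.
#' @param init Optional initial genotype counts
#'   `c(A1A1, A1A2, A2A2)` summing to `N` (e.g. a single introduced
#'   heterozygote with `mu = 0` for fixation-probability experiments).
#' @return A `fixation_records` data frame with one row per replicate:
#'   `replicate, seed, generations, outcome, censored`.
#' @export
run_single_locus <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$model
  w <- if (identical(m, "neutral")) c(1, 1, 1)
       else if (inherits(m, "underdominant_model")) unname(fitness_underdominant(m))
       else stop("single-locus engine needs an underdominant model or \"neutral\"")
  N <- config$mating$N
  if (is.null(init)) init <- c(N, 0, 0)
  if (sum(init) != N) stop("`init` must sum to N")
  alpha <- .drift_alpha(config$drift)
  rows <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    sd_i <- config$seed + i - 1
    set.seed(sd_i)
    res <- cpp_run_single_locus(as.integer(init), w, N,
                                config$mating$sigma, config$mu, alpha,
                                config$max_generations)
    rows[[i]] <- data.frame(replicate = i, seed = sd_i,
                            generations = res$generations,
                            outcome = .outcome_labels[as.character(res$outcome)],
                            censored = res$censored)
  }
  .records_df(rows)
}

.two_locus_fitness <- function(model, sigma) {
  if (identical(model, "neutral")) return(fitness_neutral())
  if (inherits(model, "compensatory_model")) return(fitness_compensatory(model))
  if (inherits(model, "bdmi_model")) return(fitness_bdmi(model, sigma = sigma))
  if (inherits(model, "fitness_matrix")) return(model)
  stop("unsupported model for the two-locus engine")
}

#' Two-locus Wright-Fisher simulation
#'
#' Simulates the ten genotype classes of the two-locus system under the
#' full life cycle, starting from the monomorphic ancestral state
#' (`G11 = 1`). Stops when the A2B2 haplotype is fixed homozygous
#' (compensatory stopping rule) or when either derived allele is fixed
#' (BDMi rule), or censors at `max_generations`.
#'
#' @param config A [sim_config()] with a [compensatory_model()],
#'   [bdmi_model()], `"neutral"`, or a raw [fitness_matrix()].
#' @param stop_rule `"pair"` (fixation of A2B2/A2B2) or `"either"`
#'   (fixation of either derived allele); defaults to the convention of
#'   the model class (pair for compensatory, either otherwise).
#' @param init Optional initial genotype counts over the 10 classes.
#' @param mu_b Optional mutation rate of the B locus when it differs
#'   from `config$mu` (e.g. 0 to freeze the B locus and reduce the
#'   engine to a single segregating locus).
#' @return A `fixation_records` data frame.
#' @export
run_two_locus <- function(config, stop_rule = NULL, init = NULL,
                          mu_b = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sigma <- config$mating$sigma
  W <- .two_locus_fitness(config$model, sigma)
  if (is.null(stop_rule))
    stop_rule <- if (inherits(config$model, "compensatory_model")) "pair" else "either"
  rule <- match.arg(stop_rule, c("pair", "either"))
  rule_i <- if (rule == "pair") 0L else 1L
  N <- config$mating$N
  if (is.null(init)) init <- c(N, rep(0, 9))
  if (sum(init) != N) stop("`init` must sum to N")
  alpha <- .drift_alpha(config$drift)
  rows <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    sd_i <- config$seed + i - 1
    set.seed(sd_i)
    res <- cpp_run_two_locus(as.integer(init), as.numeric(W), N, sigma,
                             config$r, config$mu,
                             if (is.null(mu_b)) config$mu else mu_b,
                             alpha, config$max_generations, rule_i)
    rows[[i]] <- data.frame(replicate = i, seed = sd_i,
                            generations = res$generations,
                            outcome = .outcome_labels[as.character(res$outcome)],
                            censored = res$censored)
  }
  .records_df(rows)
}

#' One-generation drift draws
#'
#' Samples offspring counts from a frequency vector, either
#' multinomially or by the Dirichlet-multinomial scheme in which the
#' probability vector is first perturbed by a Dirichlet draw with
#' concentration `alpha * p`, inflating the variance of frequency
#' changes by `(N + alpha)/(1 + alpha)`.
#'
#' @param p Frequency vector (any number of classes).
#' @param N Number of individuals to sample.
#' @param drift A [drift_model()].
#' @param ndraws Number of independent one-generation draws.
#' @return Integer matrix, `length(p)` rows by `ndraws` columns.
#' @export
drift_sample <- function(p, N, drift = drift_model("multinomial"),
                         ndraws = 1) {
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("`p` must be a frequency vector")
  cpp_drift_draws(as.numeric(p), as.integer(N), .drift_alpha(drift),
                  as.integer(ndraws))
}

#' @export
print.fixation_records <- function(x, ...) {
  cat(sprintf("%d replicate(s); %d censored; mean generations (uncensored) = %.6g\n",
              nrow(x), sum(x$censored),
              mean(x$generations[!x$censored])))
  NextMethod()
}

#' Summarise fixation records
#'
#' @param records A `fixation_records` data frame (or any data frame
#'   with `generations` and `censored` columns).
#' @param censor_limit Censoring threshold used in the runs (needed for
#'   the corrected mean; defaults to the maximum censored value).
#' @param boot Number of bootstrap resamples for the 95% CI of the mean.
#' @return List with `n`, `n_censored`, `mean`, `median`, `mean_all`
#'   (censored entries counted at the threshold), `ci` (bootstrap 95%
#'   CI of the uncensored mean), and `corrected_mean` (censored-gamma
#'   estimate, `NA` when unavailable).
#' @export
replicate_summary <- function(records, censor_limit = NULL, boot = 1000) {
  g <- records$generations
  cens <- records$censored
  n <- length(g)
  if (n < 1) stop("need at least one record")
  unc <- g[!cens]
  out <- list(n = n, n_censored = sum(cens),
              mean = if (length(unc)) mean(unc) else NA_real_,
              median = if (length(unc)) stats::median(unc) else NA_real_,
              mean_all = mean(g))
  if (length(unc) >= 2 && boot > 0) {
    bm <- replicate(boot, mean(sample(unc, replace = TRUE)))
    out$ci <- unname(stats::quantile(bm, c(0.025, 0.975)))
  } else out$ci <- c(NA_real_, NA_real_)
  out$corrected_mean <- NA_real_
  if (any(cens) && length(unc) >= 2) {
    lim <- if (is.null(censor_limit)) max(g[cens]) else censor_limit
    fit <- try(censored_gamma_mean(censored_sample(g, lim)), silent = TRUE)
    if (!inherits(fit, "try-error")) out$corrected_mean <- fit$mean
  } else if (!any(cens)) {
    out$corrected_mean <- out$mean
  }
  out
}
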