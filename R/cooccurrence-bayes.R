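#' Beta posterior for a Bernoulli marker frequency
#'
#' Conjugate update for the unknown fraction `f` of positive synaptosomes:
#' with a Beta(a_prior, b_prior) prior and `n` positives out of `N`
#' synaptosomes, the posterior is `Beta(a_prior + n, b_prior + N - n)`.
#'
#' @param n number of positive synaptosomes (successes).
#' @param N total number of synaptosomes (trials).
#' @param a_prior,b_prior positive prior shape parameters (default uniform).
#' @return object of class `beta_posterior` with shapes `a`, `b`, the
#'   prior, `mean`, `mode` (NA when undefined) and a `credible_interval`
#'   function of the level.
#' @export
beta_posterior <- function(n, N, a_prior = 1, b_prior = 1) {
  if (a_prior <= 0 || b_prior <= 0) stop("prior shapes must be positive")
  if (n < 0 || N < 0 || n > N) stop("need 0 <= n <= N")
  a <- a_prior + n
  b <- b_prior + N - n
  structure(list(
    a = a, b = b, prior = c(a_prior = a_prior, b_prior = b_prior),
    n = n, N = N,
    mean = a / (a + b),
    mode = if (a > 1 && b > 1) (a - 1) / (a + b - 2) else NA_real_,
    credible_interval = function(level = 0.95) {
      p <- (1 - level) / 2
      stats::qbeta(c(p, 1 - p), a, b)
    }
  ), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  ci <- x$credible_interval(0.95)
  cat(sprintf("Beta(%g, %g) posterior: mean %.4f, 95%% CI [%.4f, %.4f] (n = %d / N = %d)\n",
              x$a, x$b, x$mean, ci[1], ci[2], x$n, x$N))
  invisible(x)
}

#' Bayes factor: shared versus independent Bernoulli frequencies
#'
#' Compares M1, "both datasets share one frequency f", against M2, "each
#' dataset has its own independent frequency", for two Bernoulli count
#' pairs. With the Bernoulli-sequence likelihood, marginal likelihoods have
#' closed Beta-function forms and combinatorial factors cancel:
#' \deqn{\log P(data|M_1) = \log B(a + n_1 + n_2, b + (N_1-n_1) + (N_2-n_2)) - \log B(a, b)}
#' \deqn{\log P(data|M_2) = \sum_i \log B(a + n_i, b + N_i - n_i) - \log B(a, b).}
#' The Bayes factor `B = P(data|M1) / P(data|M2)` is reported with the
#' probability of the shared model `B / (1 + B)`.
#'
#' @param counts_1,counts_2 length-2 vectors `c(n, N)`.
#' @param a_prior,b_prior positive prior shapes (default uniform).
#' @return object of class `bayes_factor_result` with `log_B`, `B`,
#'   `prob_M1` and `prob_M2`.
#' @export
bayes_factor_shared_vs_independent <- function(counts_1, counts_2,
                                               a_prior = 1, b_prior = 1) {
  check_counts <- function(c2) {
    if (length(c2) != 2L || any(c2 < 0) || c2[1] > c2[2])
      stop("counts must be c(n, N) with 0 <= n <= N")
  }
  check_counts(counts_1); check_counts(counts_2)
  if (a_prior <= 0 || b_prior <= 0) stop("prior shapes must be positive")
  n1 <- counts_1[1]; N1 <- counts_1[2]
  n2 <- counts_2[1]; N2 <- counts_2[2]
  lb0 <- lbeta(a_prior, b_prior)
  log_m1 <- lbeta(a_prior + n1 + n2, b_prior + (N1 - n1) + (N2 - n2)) - lb0
  log_m2 <- (lbeta(a_prior + n1, b_prior + N1 - n1) - lb0) +
    (lbeta(a_prior + n2, b_prior + N2 - n2) - lb0)
  log_B <- log_m1 - log_m2
  B <- exp(log_B)
  prob_M1 <- 1 / (1 + exp(-log_B))     # B / (1 + B), stable for large |log_B|
  structure(list(log_B = log_B, B = B, prob_M1 = prob_M1,
                 prob_M2 = 1 - prob_M1,
                 counts_1 = c(n = n1, N = N1), counts_2 = c(n = n2, N = N2),
                 prior = c(a_prior = a_prior, b_prior = b_prior)),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("Bayes factor (shared vs independent f): B = %.4g (log B = %.4f)\n",
              x$B, x$log_B))
  cat(sprintf("  P(shared) = %.4f, P(independent) = %.4f\n",
              x$prob_M1, x$prob_M2))
  invisible(x)
}

#' Derive the two count pairs for the shared-frequency comparison
#'
#' Builds `(n, N)` count pairs from a per-synaptosome flag table for
#' [bayes_factor_shared_vs_independent()]. In `"as_stated"` mode the first
#' pair counts the signal over all synaptosomes and the second the signal
#' over the AT8-positive subset (the literal comparison of the marginal
#' and conditional frequencies, with overlapping data); in `"disjoint"`
#' mode the table is partitioned into the AT8-negative and AT8-positive
#' subsets, which makes the two datasets independent.
#'
#' @param table data frame with logical columns `at8` and `signal`.
#' @param mode `"as_stated"` or `"disjoint"`.
#' @return list with `counts_1` and `counts_2`, each `c(n, N)`.
#' @export
derive_count_pairs <- function(table, mode = c("as_stated", "disjoint")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) stop("`table` must be non-empty")
  n_at8 <- sum(table$at8)
  if (n_at8 == 0L)
    stop("no AT8-positive synaptosomes; conditional comparison undefined")
  at8 <- table$at8; sig <- table$signal
  if (mode == "as_stated") {
    list(counts_1 = c(sum(sig), nrow(table)),
         counts_2 = c(sum(sig & at8), n_at8))
  } else {
    list(counts_1 = c(sum(sig & !at8), sum(!at8)),
         counts_2 = c(sum(sig & at8), n_at8))
  }
}
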