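# Analytic companions to the simulator: the stationary endo-pair count of
# the fusion/fission queueing process, and the exact replication mean used
# as an oracle for the Dirichlet-multinomial resampler.

#' Stationary endo-pair expectation under the fusion/fission queue
#'
#' Cellularization (rate `alpha` per encounter) and decellularization (rate
#' `beta` per endo-pair) act as a birth-death queue on the endo-pair count.
#' With `n_E` endo-pairs out of `N` total agents and an (approximately)
#' even sender/receiver split, there are about `(N - 2 n_E) / 2`
#' extracellular encounters, so flow balance
#' `alpha (N - 2 n_E) / 2 = beta n_E` gives the stationary point
#' `n_E* = alpha N / (2 (alpha + beta))`.  This derivation assumes
#' `min(n_S, n_R) = (N - 2 n_E) / 2` exactly; in a finite run the split is
#' binomial, so `min(n_S, n_R)` falls short by half the (fixed) absolute
#' sender/receiver imbalance, typically of order `sqrt(N)`.
#'
#' @param alpha cellularization probability per encounter.
#' @param beta decellularization probability per endo-pair.
#' @param n_agents total (conserved) number of agents `N`.
#' @return An object of class `stationary_prediction`: list with `n_E`,
#'   `n_S`, `n_R` (expected counts) and `cellularized_fraction`
#'   (`2 n_E / N`).
#' @examples
#' stationary_endo_expectation(0.0001, 0.01, 10000)  # n_E ~ 49.5
#' @export
stationary_endo_expectation <- function(alpha, beta, n_agents) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1, n_agents > 0)
  if (alpha + beta == 0)
    stop("alpha + beta must be positive: with no transitions the chain ",
         "has no unique stationary point")
  n_e <- alpha * n_agents / (2 * (alpha + beta))
  n_ind <- (n_agents - 2 * n_e) / 2
  structure(list(n_E = n_e, n_S = n_ind, n_R = n_ind,
                 cellularized_fraction = 2 * n_e / n_agents),
            class = "stationary_prediction")
}

#' @export
print.stationary_prediction <- function(x, digits = 4, ...) {
  cat("Stationary agent-type prediction\n")
  cat("  n(E)* = ", format(x$n_E, digits = digits),
      "   n(S)* = n(R)* = ", format(x$n_S, digits = digits), "\n", sep = "")
  cat("  cellularized fraction 2 n(E)*/N = ",
      format(x$cellularized_fraction, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Exact replication mean
#'
#' The marginal expectation of the Dirichlet-multinomial replication draw:
#' with per-type aggregate rewards `U` and class total `n`, type `v` is
#' expected to hold `n U_v / sum(U)` agents next generation.  Serves as the
#' independent oracle for [rdirmnom()] and [replicate_population()].
#'
#' @param U non-negative reward vector with positive sum.
#' @param n class total.
#' @return Numeric vector of expected counts, summing to `n`.
#' @examples
#' replication_mean(c(8, 2), 50)  # 40 10
#' @export
replication_mean <- function(U, n) {
  stopifnot(all(U >= 0), n >= 0)
  if (sum(U) <= 0) stop("sum(U) must be positive")
  n * U / sum(U)
}
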