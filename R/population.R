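# Population state and the within-generation mechanics: random pairing of
# independent senders and receivers into encounters, game play, and the
# cellularization (fusion) / decellularization (fission) transitions.
# State is held as per-location integer count matrices, one column per
# strategic type: S and R are L x 4, E is L x 8 (endo types are indexed by
# the outcome they deterministically play).

# outcome played when sender strategic type h encounters receiver type g
.ENC_OUT <- local({
  snd <- cbind(type = c(1L, 1L, 2L, 2L), message = c(1L, 2L, 1L, 2L))
  rcv <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))  # action on M1, on M2
  out <- matrix(NA_integer_, 4L, 4L)
  for (h in 1:4) for (g in 1:4) {
    m <- snd[h, "message"]
    out[h, g] <- .OUT_IDX[snd[h, "type"], m, rcv[g, m]]
  }
  out
})

# decellularization maps: endo type o splits into one sender of type
# .E2S-column and one receiver whose action on the played message is fixed
# (two receiver types are consistent; the unobserved-message action is
# redrawn uniformly between them)
.E2S  <- matrix(0, 8L, 4L)   # endo -> sender strategic type indicator
.E2R1 <- matrix(0, 8L, 4L)   # endo -> first consistent receiver type
.E2R2 <- matrix(0, 8L, 4L)   # endo -> second consistent receiver type
local({
  rcv_on <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  for (o in 1:8) {
    t <- .TRIPLE[o, "type"]; m <- .TRIPLE[o, "message"]; a <- .TRIPLE[o, "action"]
    h <- (t - 1L) * 2L + m                    # sender_strategies() ordering
    g <- which(rcv_on[, m] == a)              # exactly two receiver types
    .E2S[o, h]      <<- 1
    .E2R1[o, g[1L]] <<- 1
    .E2R2[o, g[2L]] <<- 1
  }
})

.new_state <- function(nrows, ncols) {
  L <- nrows * ncols
  structure(list(S = matrix(0L, L, 4L), R = matrix(0L, L, 4L),
                 E = matrix(0L, L, 8L), generation = 0L,
                 dims = c(nrows, ncols)),
            class = "endo_state")
}

#' Conserved population total
#'
#' The quantity `n(S) + n(R) + 2 n(E)` summed over the whole domain.  Each
#' endo-pair holds one sender and one receiver, so this total is invariant
#' under every phase of the simulation (fixed population size assumption).
#'
#' @param state a population state.
#' @return A single number.
#' @export
total_population <- function(state) {
  sum(state$S) + sum(state$R) + 2 * sum(state$E)
}

#' @export
print.endo_state <- function(x, ...) {
  cat("Population state (generation ", x$generation, ")\n", sep = "")
  cat("  domain: ", x$dims[1], " x ", x$dims[2], "\n", sep = "")
  cat("  n(S) = ", sum(x$S), ", n(R) = ", sum(x$R), ", n(E) = ", sum(x$E),
      "  [conserved total ", total_population(x), "]\n", sep = "")
  invisible(x)
}

#' Initialize a population
#'
#' Creates the generation-0 population: each of `total_agents` agents is
#' independently a sender or a receiver with probability 1/2, receives a
#' strategic type drawn uniformly over its class's four types, and a domain
#' location drawn uniformly.  No endo-pairs exist at initialization.
#'
#' Uses the current R random number stream; seed it (or call through
#' [run_simulation()], which seeds from the config) for reproducibility.
#'
#' @param config a simulation configuration, see [sim_config()].
#' @return An object of class `endo_state`.
#' @examples
#' set.seed(1)
#' init_population(sim_config(total_agents = 100))
#' @export
init_population <- function(config) {
  N <- config$total_agents
  if (!is.numeric(N) || N <= 0) stop("total_agents must be positive")
  nrows <- config$domain_shape[1]; ncols <- config$domain_shape[2]
  L <- nrows * ncols
  state <- .new_state(nrows, ncols)
  n_s <- stats::rbinom(1L, N, 0.5)
  # uniform over (location, type) cells == independent uniform draws
  state$S[] <- stats::rmultinom(1L, n_s, rep(1, L * 4L))
  state$R[] <- stats::rmultinom(1L, N - n_s, rep(1, L * 4L))
  state
}

# multivariate hypergeometric: draw k agents without replacement from a
# population with per-type counts `counts`
.rmvhyper <- function(counts, k) {
  n <- length(counts)
  total <- sum(counts)
  stopifnot(k >= 0, k <= total)
  out <- integer(n)
  for (i in seq_len(n - 1L)) {
    out[i] <- stats::rhyper(1L, counts[i], total - counts[i], k)
    k <- k - out[i]
    total <- total - counts[i]
  }
  out[n] <- k
  out
}

#' Pair agents into encounters at one location
#'
#' Independent senders and receivers at a location are randomly paired; the
#' number of extracellular encounters equals the smaller of the two
#' populations, and surplus agents of the larger class sit out.  The
#' count-level procedure (multivariate hypergeometric draw of which agents
#' participate, then a uniform random assortment of participants via
#' [stats::r2dtable()]) is distributionally identical to matching
#' individually labelled agents uniformly at random without replacement.
#' Every endo-pair is in a protracted encounter with itself and contributes
#' one intracellular encounter.
#'
#' @param state a population state.
#' @param location location index (row of the count matrices).
#' @return An object of class `encounter_tally`: list with `extracellular`
#'   (4 x 4 matrix of sender-type x receiver-type pair counts),
#'   `intracellular` (8 endo-type counts), `unpaired` (surplus S and R),
#'   and `location`.
#' @export
pair_encounters <- function(state, location = 1L) {
  s <- state$S[location, ]
  r <- state$R[location, ]
  m <- min(sum(s), sum(r))
  if (m > 0L) {
    a <- .rmvhyper(s, m)
    b <- .rmvhyper(r, m)
    ex <- stats::r2dtable(1L, a, b)[[1L]]
  } else {
    ex <- matrix(0L, 4L, 4L)
  }
  structure(list(extracellular = ex,
                 intracellular = state$E[location, ],
                 unpaired = c(S = sum(s) - m, R = sum(r) - m),
                 location = location),
            class = "encounter_tally")
}

#' Play one generation of signaling games
#'
#' Resolves every encounter in a tally.  Each extracellular pairing of
#' sender type `h` and receiver type `g` plays the outcome determined by
#' the sender's nature type and message and the receiver's action on that
#' message; `U_S` accrues to the sender's strategic type and `U_R` to the
#' receiver's.  Each endo-pair of type `o` deterministically plays outcome
#' `o` and is credited the inclusive utility `U_S + U_R`.  Outcome tallies
#' are kept separately per compartment.
#'
#' @param tally an `encounter_tally` from [pair_encounters()].
#' @param table a payoff table.
#' @return List with `rewards` (list of aggregate reward vectors `S` (4),
#'   `R` (4), `E` (8)) and `outcomes` (list of 8-count outcome tallies
#'   `extracellular`, `intracellular`).
#' @export
play_generation <- function(tally, table) {
  table <- .as_payoff_matrix(table)
  us <- table[, "US"]; ur <- table[, "UR"]
  ex <- tally$extracellular
  us_mat <- matrix(us[.ENC_OUT], 4L, 4L)
  ur_mat <- matrix(ur[.ENC_OUT], 4L, 4L)
  ex_out <- vapply(1:8, function(o) sum(ex[.ENC_OUT == o]), numeric(1))
  e_cnt <- as.numeric(tally$intracellular)
  list(rewards = list(S = rowSums(ex * us_mat),
                      R = colSums(ex * ur_mat),
                      E = e_cnt * unname(us + ur)),
       outcomes = list(extracellular = ex_out,
                       intracellular = e_cnt))
}

#' Cellularization: fuse encountering pairs into endo-pairs
#'
#' Each extracellular encounter in the tally independently fuses with
#' probability `alpha` (a Bernoulli trial per encounter).  A fused pair is
#' removed from the independent sender and receiver populations and becomes
#' one endo agent, at the same location, whose type is the outcome the pair
#' plays together.  The conserved total is unchanged.
#'
#' @param state a population state.
#' @param tally the location's `encounter_tally` for this generation.
#' @param alpha fusion probability per encounter, in \[0, 1\].
#' @return The updated state.
#' @export
cellularize <- function(state, tally, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) return(state)
  l <- tally$location
  ex <- tally$extracellular
  fused <- matrix(stats::rbinom(16L, as.vector(ex), alpha), 4L, 4L)
  if (sum(fused) == 0L) return(state)
  state$S[l, ] <- state$S[l, ] - as.integer(rowSums(fused))
  state$R[l, ] <- state$R[l, ] - as.integer(colSums(fused))
  add_e <- vapply(1:8, function(o) sum(fused[.ENC_OUT == o]), integer(1))
  state$E[l, ] <- state$E[l, ] + add_e
  state
}

#' Decellularization: split endo-pairs back into independent agents
#'
#' Each endo-pair independently splits with probability `beta`.  The pair's
#' (type, message, action) triple determines the released sender's strategic
#' type exactly; the released receiver's action on the message the pair was
#' playing is the triple's action, while its action on the other message --
#' information destroyed at fusion -- is redrawn uniformly between the two
#' consistent receiver types.  Re-fusing the same pair therefore reproduces
#' the original endo type.
#'
#' @param state a population state.
#' @param beta fission probability per endo-pair, in \[0, 1\].
#' @param census optional L x 8 matrix of endo counts to draw the Bernoulli
#'   trials from (defaults to `state$E`); the engine passes the
#'   pre-cellularization census so that pairs fused this generation cannot
#'   split in the same generation.
#' @return The updated state.
#' @export
decellularize <- function(state, beta, census = NULL) {
  stopifnot(beta >= 0, beta <= 1)
  if (beta == 0) return(state)
  E <- if (is.null(census)) state$E else census
  split <- matrix(stats::rbinom(length(E), as.vector(E), beta),
                  nrow(E), 8L)
  if (sum(split) == 0L) return(state)
  half <- matrix(stats::rbinom(length(split), as.vector(split), 0.5),
                 nrow(E), 8L)
  as_int <- function(m) { storage.mode(m) <- "integer"; m }
  state$E <- as_int(state$E - split)
  state$S <- as_int(state$S + split %*% .E2S)
  state$R <- as_int(state$R + half %*% .E2R1 + (split - half) %*% .E2R2)
  state
}
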