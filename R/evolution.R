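# Evolutionary operators: reward-proportional Dirichlet-multinomial
# replication, uniform mutation of strategic types, and spatial dispersion
# on the domain lattice.  All operators act on count matrices and consume
# the single global RNG stream in a fixed order.

#' Dirichlet-multinomial sampler
#'
#' Draws counts from the compound distribution: proportions `p` are drawn
#' from Dirichlet(`alpha`), then counts from Multinomial(`size`, `p`).  The
#' marginal mean of category `v` is `size * alpha[v] / sum(alpha)`, and the
#' counts are overdispersed relative to a plain multinomial with the same
#' mean.  This is the replication kernel: with `alpha` set to per-type
#' aggregate rewards, types that earned more than average tend to be
#' amplified and the rest attenuated.
#'
#' Concentrations may be zero (those categories almost surely receive no
#' counts); at least one must be positive.  Rows whose Gamma draws all
#' underflow to zero (possible for uniformly tiny concentrations) fall back
#' to a Dirichlet(1, ..., 1) redraw.
#'
#' @param n number of independent draws.
#' @param size total count per draw (non-negative integer).
#' @param alpha vector of non-negative concentration parameters, at least
#'   one positive.
#' @return An `n` x `length(alpha)` integer matrix; rows sum to `size`.
#' @examples
#' set.seed(1)
#' rdirmnom(5, 10, c(1, 1))          # overdispersed splits of 10
#' colMeans(rdirmnom(1e4, 100, c(3, 1)))  # close to (75, 25)
#' @export
rdirmnom <- function(n, size, alpha) {
  k <- length(alpha)
  stopifnot(n >= 1, size >= 0, k >= 1, all(alpha >= 0), any(alpha > 0))
  size <- as.integer(size)
  counts <- matrix(0L, n, k)
  if (size == 0L) return(counts)
  if (k == 1L) {
    counts[, 1L] <- size
    return(counts)
  }
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  zero <- rowSums(g) == 0
  if (any(zero))
    g[zero, ] <- stats::rgamma(sum(zero) * k, shape = 1)
  # conditional binomial decomposition of the multinomial, vectorized over
  # the n draws
  rem <- rep.int(size, n)
  g_left <- rowSums(g)
  for (j in seq_len(k - 1L)) {
    p <- ifelse(g_left > 0, pmin(g[, j] / g_left, 1), 1 / (k - j + 1))
    counts[, j] <- stats::rbinom(n, rem, p)
    rem <- rem - counts[, j]
    g_left <- pmax(g_left - g[, j], 0)
  }
  counts[, k] <- rem
  counts
}

.reward_matrix <- function(u, L, k, what) {
  if (is.null(dim(u))) u <- matrix(u, nrow = L, ncol = k, byrow = L == 1L)
  if (!all(dim(u) == c(L, k)))
    stop("rewards for class ", what, " must be a ", L, " x ", k, " matrix")
  if (any(u < 0)) stop("rewards must be non-negative")
  u
}

#' Reward-proportional replication
#'
#' Resamples each (location, class) population independently by a
#' Dirichlet-multinomial draw whose size is the class's current total at
#' that location and whose concentrations are the per-type aggregate
#' rewards earned this generation, floored by a smoothing constant
#' `epsilon` so the Dirichlet stays proper and unrewarded types remain
#' resurrectable at negligible probability.  If every type's reward at a
#' location is exactly zero (e.g. a freshly fused endo population that has
#' not yet played), the draw falls back to uniform concentrations; the
#' number of such fallbacks is recorded in the `"uniform_fallbacks"`
#' attribute of the returned state.  Class totals per location are
#' preserved exactly.
#'
#' @param state a population state.
#' @param rewards list with elements `S`, `R`, `E`: per-type aggregate
#'   reward matrices (L x 4, L x 4, L x 8), or plain vectors on a
#'   single-location domain.
#' @param epsilon smoothing floor added to every concentration.
#' @return The replicated state.
#' @export
replicate_population <- function(state, rewards, epsilon = 1e-6) {
  L <- nrow(state$S)
  fallbacks <- 0L
  for (cls in c("S", "R", "E")) {
    cnt <- state[[cls]]
    k <- ncol(cnt)
    u <- .reward_matrix(rewards[[cls]], L, k, cls)
    for (l in seq_len(L)) {
      n <- sum(cnt[l, ])
      if (n == 0L) next
      if (all(u[l, ] == 0)) {
        conc <- rep(1, k)
        fallbacks <- fallbacks + 1L
      } else {
        conc <- u[l, ] + epsilon
      }
      cnt[l, ] <- rdirmnom(1L, n, conc)[1L, ]
    }
    state[[cls]] <- cnt
  }
  attr(state, "uniform_fallbacks") <- fallbacks
  state
}

#' Mutation of strategic types
#'
#' Each agent, independently and with probability `mu`, has its strategic
#' type redrawn uniformly over its own class's strategy space (4 sender, 4
#' receiver, 8 endo types).  Class membership and location never change.
#' Implemented on counts as binomial thinning followed by uniform
#' multinomial reallocation.
#'
#' @param state a population state.
#' @param mu mutation probability per agent, in \[0, 1\].
#' @return The mutated state.
#' @export
mutate_population <- function(state, mu) {
  stopifnot(mu >= 0, mu <= 1)
  if (mu == 0) return(state)
  for (cls in c("S", "R", "E")) {
    cnt <- state[[cls]]
    k <- ncol(cnt)
    mut <- matrix(stats::rbinom(length(cnt), as.vector(cnt), mu),
                  nrow(cnt), k)
    keep <- cnt - mut
    tot <- rowSums(mut)
    for (l in which(tot > 0L))
      keep[l, ] <- keep[l, ] + as.vector(stats::rmultinom(1L, tot[l], rep(1, k)))
    state[[cls]] <- keep
  }
  state
}

# neighbor location indices (L x n_directions); torus wraps, reflect
# bounces a move off the edge back in the opposite direction
.neighbor_index <- function(nrows, ncols,
                            neighborhood = c("von_neumann", "moore"),
                            boundary = c("torus", "reflect")) {
  neighborhood <- match.arg(neighborhood)
  boundary <- match.arg(boundary)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (neighborhood == "moore")
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  L <- nrows * ncols
  nb <- matrix(NA_integer_, L, length(offs))
  wrap <- function(x, n) ((x - 1L) %% n) + 1L
  for (l in seq_len(L)) {
    i <- ((l - 1L) %% nrows) + 1L
    j <- ((l - 1L) %/% nrows) + 1L
    for (d in seq_along(offs)) {
      ti <- i + offs[[d]][1L]; tj <- j + offs[[d]][2L]
      if (boundary == "torus") {
        ti <- wrap(ti, nrows); tj <- wrap(tj, ncols)
      } else {
        if (ti < 1L || ti > nrows) ti <- i - offs[[d]][1L]
        if (tj < 1L || tj > ncols) tj <- j - offs[[d]][2L]
        ti <- min(max(ti, 1L), nrows); tj <- min(max(tj, 1L), ncols)
      }
      nb[l, d] <- (tj - 1L) * nrows + ti
    }
  }
  nb
}

#' Spatial dispersion
#'
#' Each agent, independently and with probability `gamma`, takes a random
#' walk step to a uniformly chosen neighboring location.  On a 1 x 1 domain
#' dispersion is a no-op for any `gamma` (all moves return to the single
#' location).
#'
#' @param state a population state.
#' @param gamma move probability per agent, in \[0, 1\].
#' @param neighborhood `"von_neumann"` (4 neighbors) or `"moore"` (8).
#' @param boundary `"torus"` (wrap) or `"reflect"` (a move off the edge is
#'   redirected to the opposite direction).
#' @return The dispersed state.
#' @export
disperse_population <- function(state, gamma,
                                neighborhood = c("von_neumann", "moore"),
                                boundary = c("torus", "reflect")) {
  stopifnot(gamma >= 0, gamma <= 1)
  L <- nrow(state$S)
  if (gamma == 0 || L == 1L) return(state)
  nb <- .neighbor_index(state$dims[1], state$dims[2], neighborhood, boundary)
  nd <- ncol(nb)
  for (cls in c("S", "R", "E")) {
    cnt <- state[[cls]]
    k <- ncol(cnt)
    movers <- matrix(stats::rbinom(length(cnt), as.vector(cnt), gamma),
                     L, k)
    new <- cnt - movers
    for (l in seq_len(L)) for (v in which(movers[l, ] > 0L)) {
      d <- as.vector(stats::rmultinom(1L, movers[l, v], rep(1, nd)))
      for (dd in which(d > 0L))
        new[nb[l, dd], v] <- new[nb[l, dd], v] + d[dd]
    }
    state[[cls]] <- new
  }
  state
}
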