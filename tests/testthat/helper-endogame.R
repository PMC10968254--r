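# Shared test fixtures, all built in code.

# a small, fast configuration for engine-level tests
tiny_config <- function(...) {
  args <- list(total_agents = 200L, generations = 40L, seed = 101L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# construct a population state with explicit counts (vectors recycle over a
# single location; matrices give multi-location states)
make_state <- function(S = 0, R = 0, E = 0, dims = c(1L, 1L)) {
  st <- endogame:::.new_state(dims[1], dims[2])
  fill <- function(m, x) {
    if (is.matrix(x)) m[] <- x else m[] <- matrix(x, nrow(m), ncol(m), byrow = TRUE)
    storage.mode(m) <- "integer"
    m
  }
  st$S <- fill(st$S, S)
  st$R <- fill(st$R, R)
  st$E <- fill(st$E, E)
  st
}

# brute-force weak-domination scan, written independently of pareto_front
pareto_oracle <- function(table) {
  us <- table[, 1]; ur <- table[, 2]
  keep <- character(0)
  for (j in 1:8) {
    dominated <- FALSE
    for (i in 1:8) {
      if (i == j) next
      if (us[i] >= us[j] && ur[i] >= ur[j] && (us[i] > us[j] || ur[i] > ur[j]))
        dominated <- TRUE
    }
    if (!dominated) keep <- c(keep, rownames(table)[j])
  }
  keep
}

# agent-level uniform matching oracle: expand counts to labelled agents,
# draw the participants and a uniform assortment, tally pair types
match_agents_oracle <- function(s_counts, r_counts) {
  senders <- rep(seq_along(s_counts), s_counts)
  receivers <- rep(seq_along(r_counts), r_counts)
  m <- min(length(senders), length(receivers))
  sp <- sample(senders)[seq_len(m)]
  rp <- sample(receivers)[seq_len(m)]
  tab <- matrix(0L, length(s_counts), length(r_counts))
  for (i in seq_len(m)) tab[sp[i], rp[i]] <- tab[sp[i], rp[i]] + 1L
  tab
}
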