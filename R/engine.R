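# Simulation configuration, the per-generation phase loop, and orchestration.
# Phase order within a generation: pair encounters -> play games ->
# cellularize (alpha trial on this generation's encounters) -> decellularize
# (beta trial on the pre-fusion endo census) -> replicate -> mutate ->
# disperse.  A single seeded RNG stream is consumed in exactly this order.

.REC_NAMES <- c("generation", "n_S", "n_R", "n_E",
                paste0("ex_O", 1:8), paste0("in_O", 1:8),
                "ex_mode", "in_mode",
                paste0("rew_S", 1:4), paste0("rew_R", 1:4),
                paste0("rew_E", 1:8))

#' Simulation configuration
#'
#' Assembles and validates the full parameter set of a run.  Defaults are
#' the reference configuration: 10,000 agents for 3,000 generations on a
#' single-location domain, cellularization rate `alpha` = 1e-4 per
#' encounter, decellularization rate `beta` = 0.01 per endo-pair, mutation
#' rate `mu` = 0.01 and dispersion rate `gamma` = 0.01 per agent.
#'
#' @param total_agents fixed population size (senders + receivers +
#'   2 x endo-pairs).
#' @param generations number of generations to simulate.
#' @param alpha per-encounter Bernoulli probability of fusing into an
#'   endo-pair.
#' @param beta per-endo-pair Bernoulli probability of splitting back into
#'   independent agents.
#' @param mu per-agent Bernoulli probability of uniform strategy
#'   re-selection.
#' @param gamma per-agent Bernoulli probability of a random-walk move.
#' @param domain_shape integer pair (rows, cols) of the spatial lattice.
#' @param payoff_table payoff table; must pass [validate_payoff_table()].
#' @param seed integer RNG seed for [run_simulation()].
#' @param neighborhood,boundary lattice topology for dispersion, see
#'   [disperse_population()].
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(total_agents = 500, generations = 100, seed = 7)
#' @export
sim_config <- function(total_agents = 10000L,
                       generations = 3000L,
                       alpha = 0.0001,
                       beta = 0.01,
                       mu = 0.01,
                       gamma = 0.01,
                       domain_shape = c(1L, 1L),
                       payoff_table = default_payoff_table(),
                       seed = 1L,
                       neighborhood = c("von_neumann", "moore"),
                       boundary = c("torus", "reflect")) {
  config <- structure(list(total_agents = as.integer(total_agents),
                           generations = as.integer(generations),
                           alpha = alpha, beta = beta, mu = mu, gamma = gamma,
                           domain_shape = as.integer(domain_shape),
                           payoff_table = .as_payoff_matrix(payoff_table),
                           seed = as.integer(seed),
                           neighborhood = match.arg(neighborhood),
                           boundary = match.arg(boundary)),
                      class = "sim_config")
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  config
}

#' Validate a simulation configuration
#'
#' @param config a `sim_config` or a bare list with the same fields.
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(config$total_agents) && length(config$total_agents) == 1 &&
        config$total_agents >= 1, "total_agents must be a positive integer")
  chk(is.numeric(config$generations) && length(config$generations) == 1 &&
        config$generations >= 0, "generations must be a non-negative integer")
  for (p in c("alpha", "beta", "mu", "gamma"))
    chk(is.numeric(config[[p]]) && length(config[[p]]) == 1 &&
          config[[p]] >= 0 && config[[p]] <= 1,
        paste0(p, " must be a probability in [0, 1]"))
  chk(is.numeric(config$domain_shape) && length(config$domain_shape) == 2 &&
        all(config$domain_shape >= 1),
      "domain_shape must be two positive integers (rows, cols)")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  chk(config$neighborhood %in% c("von_neumann", "moore"),
      "neighborhood must be 'von_neumann' or 'moore'")
  chk(config$boundary %in% c("torus", "reflect"),
      "boundary must be 'torus' or 'reflect'")
  pv <- tryCatch(validate_payoff_table(config$payoff_table),
                 error = function(e) list(valid = FALSE,
                                          violations = conditionMessage(e)))
  if (!pv$valid)
    problems <- c(problems, paste0("payoff table: ", pv$violations))
  problems
}

#' Read a configuration file
#'
#' Reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) run configuration.  All
#' fields of [sim_config()] are accepted by the same names; the payoff
#' table is a mapping from outcome label to a `[U_S, U_R]` pair.  Missing
#' fields take the defaults; unknown fields are an error.
#'
#' @param path path to the configuration file.
#' @return A validated `sim_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml  = yaml::read_yaml(path),
                stop("unsupported config format '", ext,
                     "'; use .json, .yaml or .yml"))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$payoff_table) && !is.matrix(raw$payoff_table)) {
    tab <- do.call(rbind, lapply(raw$payoff_table, as.numeric))
    raw$payoff_table <- tab
  }
  if (!is.null(raw$domain_shape))
    raw$domain_shape <- as.integer(unlist(raw$domain_shape))
  do.call(sim_config, raw)
}

#' Advance the simulation by one generation
#'
#' Applies, in order: [pair_encounters()] and [play_generation()] at every
#' location, [cellularize()] on this generation's encounter tallies,
#' [decellularize()] on the pre-fusion endo census, then
#' [replicate_population()], [mutate_population()] and
#' [disperse_population()].  The generation record (class counts, outcome
#' tallies and modal outcomes per compartment, per-type rewards) is taken
#' at play time, i.e. on the pre-transition census.
#'
#' @param state a population state.
#' @param config a `sim_config`.
#' @return List with elements `state` (the advanced state) and `record`
#'   (named numeric vector for this generation).
#' @export
run_generation <- function(state, config) {
  L <- nrow(state$S)
  table <- config$payoff_table
  tallies <- vector("list", L)
  ex_tot <- numeric(8); in_tot <- numeric(8)
  rew_s <- matrix(0, L, 4L); rew_r <- matrix(0, L, 4L); rew_e <- matrix(0, L, 8L)
  for (l in seq_len(L)) {
    tallies[[l]] <- pair_encounters(state, l)
    played <- play_generation(tallies[[l]], table)
    ex_tot <- ex_tot + played$outcomes$extracellular
    in_tot <- in_tot + played$outcomes$intracellular
    rew_s[l, ] <- played$rewards$S
    rew_r[l, ] <- played$rewards$R
    rew_e[l, ] <- played$rewards$E
  }
  record <- c(state$generation + 1L, sum(state$S), sum(state$R), sum(state$E),
              ex_tot, in_tot,
              .modal_index(ex_tot), .modal_index(in_tot),
              colSums(rew_s), colSums(rew_r), colSums(rew_e))
  names(record) <- .REC_NAMES

  e_census <- state$E
  for (l in seq_len(L))
    state <- cellularize(state, tallies[[l]], config$alpha)
  state <- decellularize(state, config$beta, census = e_census)
  state <- replicate_population(state,
                                list(S = rew_s, R = rew_r, E = rew_e))
  fallbacks <- attr(state, "uniform_fallbacks")
  attr(state, "uniform_fallbacks") <- NULL
  state <- mutate_population(state, config$mu)
  state <- disperse_population(state, config$gamma,
                               config$neighborhood, config$boundary)
  state$generation <- state$generation + 1L
  list(state = state, record = record, uniform_fallbacks = fallbacks)
}

#' Run a full simulation
#'
#' Validates the configuration, seeds the RNG with `config$seed`,
#' initializes the population ([init_population()]) and advances it
#' `config$generations` times with [run_generation()].  Output is
#' deterministic given (config, seed): two runs with the same configuration
#' produce identical records.
#'
#' @param config a `sim_config`.
#' @param verbose if `TRUE`, progress is reported to standard error every
#'   500 generations.
#' @return An object of class `endogame_sim`: list with `config`, `records`
#'   (data frame, one row per generation: class counts, per-compartment
#'   outcome tallies `ex_O*`/`in_O*`, modal outcome indices
#'   `ex_mode`/`in_mode` (`NA` when a compartment had no plays), per-type
#'   aggregate rewards), `state` (final state) and `uniform_fallbacks`
#'   (number of zero-reward replication fallbacks, see
#'   [replicate_population()]).
#' @examples
#' sim <- run_simulation(sim_config(total_agents = 200, generations = 50,
#'                                  seed = 42))
#' head(sim$records[, 1:12])
#' @export
run_simulation <- function(config, verbose = FALSE) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  set.seed(config$seed)
  state <- init_population(config)
  G <- config$generations
  rec <- matrix(NA_real_, G, length(.REC_NAMES),
                dimnames = list(NULL, .REC_NAMES))
  fallbacks <- 0L
  for (g in seq_len(G)) {
    step <- run_generation(state, config)
    state <- step$state
    rec[g, ] <- step$record
    fallbacks <- fallbacks + step$uniform_fallbacks
    if (verbose && g %% 500L == 0L)
      message("generation ", g, "/", G, "  n(E) = ", sum(state$E))
  }
  structure(list(config = config,
                 records = as.data.frame(rec),
                 state = state,
                 uniform_fallbacks = fallbacks),
            class = "endogame_sim")
}

#' @export
print.endogame_sim <- function(x, ...) {
  cfg <- x$config
  cat("Endosymbiosis signaling game simulation\n")
  cat("  ", cfg$total_agents, " agents, ", cfg$generations,
      " generations, domain ", cfg$domain_shape[1], " x ",
      cfg$domain_shape[2], ", seed ", cfg$seed, "\n", sep = "")
  cat("  alpha = ", cfg$alpha, ", beta = ", cfg$beta, ", mu = ", cfg$mu,
      ", gamma = ", cfg$gamma, "\n", sep = "")
  cat("  final census: n(S) = ", sum(x$state$S), ", n(R) = ", sum(x$state$R),
      ", n(E) = ", sum(x$state$E), "\n", sep = "")
  if (nrow(x$records)) {
    modes <- x$records$in_mode
    modes <- modes[!is.na(modes)]
    if (length(modes))
      cat("  intracellular modal outcome O1 in ",
          round(100 * mean(modes == 1), 1),
          "% of generations with endo plays\n", sep = "")
  }
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes `generations.csv` (the per-generation records) and `summary.json`
#' (configuration echo including the payoff table, time-averaged expression
#' profiles, modal-outcome fractions, equilibrium classification fractions
#' and the queueing stationarity comparison; see [summarize_simulation()]).
#'
#' @param sim an `endogame_sim`.
#' @param dir output directory (created if needed).
#' @param ... passed to [summarize_simulation()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(sim, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "generations.csv")
  utils::write.csv(sim$records, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summarize_simulation(sim, ...), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(csv, js))
}
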