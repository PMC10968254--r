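# Outcome expression metrics: per-generation modal outcomes, fractional
# expression profiles over time, and classification of the signaling regime
# (separating / partial pooling / pooling / babbling) from windows of play
# tallies.

.modal_index <- function(tally) {
  if (sum(tally) == 0) return(NA_real_)
  which.max(tally)  # ties broken by lowest index
}

#' Modal outcome of a tally
#'
#' The maximally expressed outcome among the 8 counts; ties are broken by
#' the lowest outcome index, and `NA` is returned when no game was played.
#'
#' @param tally numeric vector of 8 outcome counts.
#' @return Outcome label (`"O1"`..`"O8"`) or `NA`.
#' @examples
#' modal_outcome(c(10, 3, 0, 0, 0, 0, 0, 2))  # "O1"
#' @export
modal_outcome <- function(tally) {
  stopifnot(length(tally) == 8L, all(tally >= 0))
  idx <- .modal_index(tally)
  if (is.na(idx)) NA_character_ else OUTCOMES[idx]
}

.records_of <- function(x) {
  if (inherits(x, "endogame_sim")) x$records
  else if (is.data.frame(x)) x
  else stop("expected an 'endogame_sim' or its records data frame")
}

.compartment_cols <- function(compartment) {
  prefix <- switch(compartment, extracellular = "ex_O", intracellular = "in_O")
  paste0(prefix, 1:8)
}

#' Outcome expression profile
#'
#' For each compartment (extracellular and intracellular), computes every
#' generation's fractional outcome volume (outcome count divided by total
#' plays in that compartment that generation) and the time average over
#' generations.  Generations in which a compartment had no plays are
#' excluded from the averages and counted in `n_undefined`.
#'
#' @param x an `endogame_sim` or its `records` data frame.
#' @param burn_in number of leading generations to discard (0 keeps all).
#' @return An object of class `expression_profile`: per compartment a list
#'   with `fractions` (generations x 8 matrix, `NA` rows when undefined),
#'   `time_average` (length-8, fractions renormalized over defined
#'   generations) and `n_undefined`.
#' @export
expression_profile <- function(x, burn_in = 0) {
  records <- .records_of(x)
  if (!nrow(records)) stop("no generation records")
  records <- records[records$generation > burn_in, , drop = FALSE]
  if (!nrow(records)) stop("burn_in leaves no generations")
  out <- lapply(c(extracellular = "extracellular",
                  intracellular = "intracellular"), function(cp) {
    counts <- as.matrix(records[, .compartment_cols(cp)])
    tot <- rowSums(counts)
    frac <- counts / ifelse(tot > 0, tot, NA_real_)
    defined <- tot > 0
    ta <- if (any(defined)) colMeans(frac[defined, , drop = FALSE])
          else rep(NA_real_, 8L)
    names(ta) <- OUTCOMES
    list(fractions = frac, time_average = ta,
         n_undefined = sum(!defined))
  })
  structure(out, class = "expression_profile", burn_in = burn_in)
}

#' @export
print.expression_profile <- function(x, digits = 3, ...) {
  cat("Outcome expression profile (time-averaged fractional volume",
      if (attr(x, "burn_in") > 0)
        paste0(", burn-in ", attr(x, "burn_in"), " generations"),
      ")\n", sep = "")
  ta <- rbind(extracellular = x$extracellular$time_average,
              intracellular = x$intracellular$time_average)
  print(round(ta, digits))
  for (cp in c("extracellular", "intracellular"))
    if (x[[cp]]$n_undefined > 0)
      cat("  ", cp, ": ", x[[cp]]$n_undefined,
          " generation(s) with no plays excluded\n", sep = "")
  invisible(x)
}

#' Classify the signaling regime of a window of plays
#'
#' From an aggregated 8-outcome play tally, computes two total-variation
#' diagnostics: `d_msg`, the distance between the empirical message
#' distributions of honest and deceptive senders (how informative the
#' signal is about the type), and `d_act`, the distance between the
#' empirical action distributions after `M1` and after `M2` (how responsive
#' the receiver is to the signal).  Labels: `SEPARATING` when both
#' diagnostics are at least `theta_sep`; `POOLING` when `d_msg` is at most
#' `theta_pool`; `BABBLING` when `d_act` is at most `theta_pool` (the
#' receiver ignores the signal); otherwise `PARTIAL_POOLING`.  A diagnostic
#' whose conditioning event has zero support (e.g. no deceptive play in the
#' window) is `NA`; any label decision that would need it is skipped and
#' the window falls back to `PARTIAL_POOLING` with `undefined = TRUE`.
#'
#' The thresholds are an operational choice, not part of the game
#' definition; the raw diagnostics are always returned so windows can be
#' re-thresholded.
#'
#' @param tally numeric vector of 8 outcome counts (a window aggregate).
#' @param theta_sep separating threshold on both diagnostics.
#' @param theta_pool pooling/babbling threshold.
#' @return An object of class `equilibrium_label`: list with `label`,
#'   `d_msg`, `d_act`, `undefined`.
#' @examples
#' # honest -> M1 -> A1 and deceptive -> M2 -> A2: fully informative
#' classify_equilibrium(c(60, 0, 0, 0, 0, 40, 0, 0))  # SEPARATING
#' @export
classify_equilibrium <- function(tally, theta_sep = 0.8, theta_pool = 0.2) {
  stopifnot(length(tally) == 8L, all(tally >= 0))
  if (sum(tally) == 0) stop("window contains no plays")
  h <- sum(tally[1:4]); d <- sum(tally[5:8])
  p_m1_h <- if (h > 0) (tally[1] + tally[2]) / h else NA_real_
  p_m1_d <- if (d > 0) (tally[7] + tally[8]) / d else NA_real_
  d_msg <- abs(p_m1_h - p_m1_d)
  m1 <- sum(tally[c(1, 2, 7, 8)]); m2 <- sum(tally[3:6])
  p_a1_m1 <- if (m1 > 0) (tally[1] + tally[8]) / m1 else NA_real_
  p_a1_m2 <- if (m2 > 0) (tally[4] + tally[5]) / m2 else NA_real_
  d_act <- abs(p_a1_m1 - p_a1_m2)
  label <- if (!is.na(d_msg) && d_msg <= theta_pool) "POOLING"
    else if (!is.na(d_act) && d_act <= theta_pool) "BABBLING"
    else if (!is.na(d_msg) && !is.na(d_act) &&
             d_msg >= theta_sep && d_act >= theta_sep) "SEPARATING"
    else "PARTIAL_POOLING"
  structure(list(label = label, d_msg = unname(d_msg), d_act = unname(d_act),
                 undefined = is.na(d_msg) || is.na(d_act)),
            class = "equilibrium_label")
}

#' @export
print.equilibrium_label <- function(x, ...) {
  cat(x$label, "  (d_msg = ", format(x$d_msg, digits = 3),
      ", d_act = ", format(x$d_act, digits = 3),
      if (x$undefined) ", some diagnostics undefined", ")\n", sep = "")
  invisible(x)
}

#' Classify consecutive windows of a run
#'
#' Splits the post-burn-in generations of a compartment into consecutive
#' non-overlapping windows, aggregates each window's play tally and applies
#' [classify_equilibrium()].
#'
#' @param x an `endogame_sim` or its records data frame.
#' @param compartment `"intracellular"` or `"extracellular"`.
#' @param window window length in generations.
#' @param burn_in generations discarded before windowing.
#' @inheritParams classify_equilibrium
#' @return Data frame with one row per window: `start`, `end` (generation
#'   indices), `label`, `d_msg`, `d_act`, `undefined`.  Windows with no
#'   plays get label `NA`.
#' @export
classify_windows <- function(x, compartment = c("intracellular",
                                                "extracellular"),
                             window = 100, burn_in = 500,
                             theta_sep = 0.8, theta_pool = 0.2) {
  compartment <- match.arg(compartment)
  records <- .records_of(x)
  records <- records[records$generation > burn_in, , drop = FALSE]
  nw <- nrow(records) %/% window
  if (nw < 1) stop("fewer than one window after burn-in")
  counts <- as.matrix(records[, .compartment_cols(compartment)])
  res <- lapply(seq_len(nw), function(w) {
    rows <- ((w - 1L) * window + 1L):(w * window)
    tal <- colSums(counts[rows, , drop = FALSE])
    gen <- records$generation[rows]
    if (sum(tal) == 0)
      return(data.frame(start = gen[1], end = gen[length(gen)],
                        label = NA_character_, d_msg = NA_real_,
                        d_act = NA_real_, undefined = TRUE))
    cl <- classify_equilibrium(tal, theta_sep, theta_pool)
    data.frame(start = gen[1], end = gen[length(gen)], label = cl$label,
               d_msg = cl$d_msg, d_act = cl$d_act, undefined = cl$undefined)
  })
  do.call(rbind, res)
}

#' Summarize a run
#'
#' Collects the headline quantities of a finished run: post-burn-in
#' modal-outcome fractions and time-averaged expression profiles per
#' compartment, equilibrium-label fractions over windows, the observed
#' mean endo-pair count against the analytic stationarity prediction
#' ([stationary_endo_expectation()]), and a verbatim echo of the
#' configuration (including the payoff table) for provenance.
#'
#' @param sim an `endogame_sim`.
#' @param burn_in generations discarded from all summary statistics; the
#'   default is 500, capped at half the run for short runs.
#' @param window window length for equilibrium classification; the default
#'   is 100, capped at the post-burn-in span.
#' @param theta_sep,theta_pool classification thresholds, see
#'   [classify_equilibrium()].
#' @return A nested list, suitable for JSON serialization.
#' @export
summarize_simulation <- function(sim, burn_in = NULL, window = NULL,
                                 theta_sep = 0.8, theta_pool = 0.2) {
  stopifnot(inherits(sim, "endogame_sim"))
  records <- sim$records
  if (is.null(burn_in)) burn_in <- min(500L, nrow(records) %/% 2L)
  if (is.null(window)) window <- max(1L, min(100L, nrow(records) - burn_in))
  if (burn_in >= nrow(records))
    stop("burn_in must be smaller than the number of generations")
  post <- records[records$generation > burn_in, , drop = FALSE]
  prof <- expression_profile(records, burn_in = burn_in)

  modal_fractions <- lapply(c(extracellular = "ex_mode",
                              intracellular = "in_mode"), function(col) {
    m <- post[[col]]
    defined <- !is.na(m)
    frac <- vapply(1:8, function(o) mean(m[defined] == o), numeric(1))
    names(frac) <- OUTCOMES
    list(fraction_of_defined_generations = as.list(frac),
         n_undefined = sum(!defined))
  })

  equilibrium <- lapply(c(extracellular = "extracellular",
                          intracellular = "intracellular"), function(cp) {
    w <- classify_windows(records, cp, window = window, burn_in = burn_in,
                          theta_sep = theta_sep, theta_pool = theta_pool)
    lab <- w$label[!is.na(w$label)]
    tab <- table(factor(lab, levels = c("SEPARATING", "PARTIAL_POOLING",
                                        "POOLING", "BABBLING")))
    list(n_windows = nrow(w),
         fractions = as.list(prop.table(tab)),
         mean_d_msg = mean(w$d_msg, na.rm = TRUE),
         mean_d_act = mean(w$d_act, na.rm = TRUE))
  })

  cfg <- sim$config
  pred <- stationary_endo_expectation(cfg$alpha, cfg$beta, cfg$total_agents)
  obs_mean_e <- mean(post$n_E)
  payoff_echo <- apply(cfg$payoff_table, 1L, as.list, simplify = FALSE)

  list(config = list(total_agents = cfg$total_agents,
                     generations = cfg$generations,
                     alpha = cfg$alpha, beta = cfg$beta,
                     mu = cfg$mu, gamma = cfg$gamma,
                     domain_shape = cfg$domain_shape,
                     neighborhood = cfg$neighborhood,
                     boundary = cfg$boundary,
                     payoff_table = payoff_echo),
       seed = cfg$seed,
       burn_in = burn_in,
       window = window,
       expression_profile = list(
         extracellular = as.list(prof$extracellular$time_average),
         intracellular = as.list(prof$intracellular$time_average)),
       modal_outcome_fractions = modal_fractions,
       equilibrium_fractions = equilibrium,
       stationarity = list(observed_mean_n_E = obs_mean_e,
                           predicted_n_E = pred$n_E,
                           ratio = obs_mean_e / pred$n_E),
       uniform_replication_fallbacks = sim$uniform_fallbacks)
}
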