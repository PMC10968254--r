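# Extensive-form signaling game: an informed sender (honest or deceptive
# nature type) emits one of two messages; an uninformed receiver, who observes
# only the message, picks one of two actions.  The eight (type, message,
# action) triples are labelled O1..O8 and carry configurable (U_S, U_R)
# payoffs.

SENDER_TYPES <- c("HONEST", "DECEPTIVE")
MESSAGES     <- c("M1", "M2")
ACTIONS      <- c("A1", "A2")
OUTCOMES     <- paste0("O", 1:8)

# outcome index by (type, message, action); the layout follows the game
# tree's three partitions: honest -> O1..O4, message one -> {O1,O2,O7,O8},
# action one -> {O1,O4,O5,O8}
.OUT_IDX <- array(NA_integer_, dim = c(2L, 2L, 2L),
                  dimnames = list(SENDER_TYPES, MESSAGES, ACTIONS))
.OUT_IDX["HONEST",    "M1", "A1"] <- 1L
.OUT_IDX["HONEST",    "M1", "A2"] <- 2L
.OUT_IDX["HONEST",    "M2", "A2"] <- 3L
.OUT_IDX["HONEST",    "M2", "A1"] <- 4L
.OUT_IDX["DECEPTIVE", "M2", "A1"] <- 5L
.OUT_IDX["DECEPTIVE", "M2", "A2"] <- 6L
.OUT_IDX["DECEPTIVE", "M1", "A2"] <- 7L
.OUT_IDX["DECEPTIVE", "M1", "A1"] <- 8L

# inverse map: row o gives the (type, message, action) indices of outcome o
.TRIPLE <- matrix(NA_integer_, nrow = 8L, ncol = 3L,
                  dimnames = list(OUTCOMES, c("type", "message", "action")))
for (.t in 1:2) for (.m in 1:2) for (.a in 1:2)
  .TRIPLE[.OUT_IDX[.t, .m, .a], ] <- c(.t, .m, .a)
rm(.t, .m, .a)

.as_outcome_index <- function(o) {
  if (is.character(o)) {
    idx <- match(o, OUTCOMES)
  } else {
    idx <- as.integer(o)
    idx[idx < 1L | idx > 8L] <- NA_integer_
  }
  if (anyNA(idx))
    stop("invalid outcome; expected O1..O8 or an index in 1..8", call. = FALSE)
  idx
}

#' Resolve a signaling-game outcome
#'
#' Maps a sender nature type, the message it sent, and the receiver's action
#' to the corresponding outcome of the extensive-form game tree.  The map is
#' the unique one consistent with the tree's three partitions: honest types
#' yield `O1`--`O4`; message `M1` yields `{O1, O2, O7, O8}`; action `A1`
#' yields `{O1, O4, O5, O8}`.
#'
#' @param type character vector, `"HONEST"` or `"DECEPTIVE"`.
#' @param message character vector, `"M1"` or `"M2"`.
#' @param action character vector, `"A1"` or `"A2"`.
#' @return Character vector of outcome labels `"O1"`..`"O8"`.
#' @examples
#' resolve_outcome("HONEST", "M1", "A1")     # "O1"
#' resolve_outcome("DECEPTIVE", "M1", "A1")  # "O8"
#' @seealso [decompose_outcome()] for the inverse.
#' @export
resolve_outcome <- function(type, message, action) {
  t <- match(type, SENDER_TYPES)
  m <- match(message, MESSAGES)
  a <- match(action, ACTIONS)
  if (anyNA(t)) stop("type must be one of: ", paste(SENDER_TYPES, collapse = ", "))
  if (anyNA(m)) stop("message must be one of: ", paste(MESSAGES, collapse = ", "))
  if (anyNA(a)) stop("action must be one of: ", paste(ACTIONS, collapse = ", "))
  OUTCOMES[.OUT_IDX[cbind(t, m, a)]]
}

#' Decompose an outcome into its game-tree coordinates
#'
#' Inverse of [resolve_outcome()]: recovers the (sender type, message,
#' action) triple that produces a given outcome.
#'
#' @param outcome outcome labels (`"O1"`..`"O8"`) or indices (1..8).
#' @return A data frame with columns `outcome`, `type`, `message`, `action`.
#' @examples
#' decompose_outcome("O8")  # DECEPTIVE, M1, A1
#' @export
decompose_outcome <- function(outcome) {
  idx <- .as_outcome_index(outcome)
  data.frame(outcome = OUTCOMES[idx],
             type    = SENDER_TYPES[.TRIPLE[idx, "type"]],
             message = MESSAGES[.TRIPLE[idx, "message"]],
             action  = ACTIONS[.TRIPLE[idx, "action"]],
             row.names = NULL)
}

#' Strategic type enumerations
#'
#' Senders have a fixed nature type and a fixed message, giving four sender
#' strategic types.  Receivers commit to an action for each possible message,
#' giving four receiver strategic types.  A cellularized endo-pair plays the
#' same (type, message, action) triple every generation, so its strategic
#' space is the eight payoff-distinct outcomes (the receiver's response to
#' the never-sent message is payoff-irrelevant inside a fixed pair).
#'
#' @return A data frame enumerating the strategic types of the class, with
#'   an `index` column giving the position used in population count
#'   matrices.
#' @examples
#' sender_strategies()
#' endo_strategies()
#' @export
sender_strategies <- function() {
  data.frame(index = 1:4,
             type    = SENDER_TYPES[c(1L, 1L, 2L, 2L)],
             message = MESSAGES[c(1L, 2L, 1L, 2L)])
}

#' @rdname sender_strategies
#' @export
receiver_strategies <- function() {
  data.frame(index = 1:4,
             on_M1 = ACTIONS[c(1L, 1L, 2L, 2L)],
             on_M2 = ACTIONS[c(1L, 2L, 1L, 2L)])
}

#' @rdname sender_strategies
#' @export
endo_strategies <- function() {
  cbind(index = 1:8, decompose_outcome(1:8))
}

#' Default payoff table
#'
#' The default `(U_S, U_R)` payoffs for outcomes `O1`..`O8`.  The table is
#' constructed to satisfy the structural constraints the model requires:
#' all payoffs non-negative (they feed Dirichlet concentration parameters),
#' `O1` (honest signal, trusting action) is Pareto efficient and the unique
#' maximizer of joint utility, `O8` tempts deception (`U_S(O8) > U_S(O1)`)
#' at the receiver's expense (`U_R(O8) < U_R(O2)`), and `O2` is the
#' receiver's "checking" refuge against deception.
#'
#' @return An 8 x 2 numeric matrix with rownames `O1`..`O8` and columns
#'   `US`, `UR`.
#' @examples
#' default_payoff_table()
#' @export
default_payoff_table <- function() {
  matrix(c(4, 4,   # O1 honest/M1/trust: cooperative optimum
           2, 2,   # O2 honest met by checking
           1, 1,   # O3
           1, 1,   # O4
           1, 1,   # O5
           1, 2,   # O6
           0, 2,   # O7 deception caught by checking
           5, 0),  # O8 successful deception against a trusting receiver
         ncol = 2L, byrow = TRUE,
         dimnames = list(OUTCOMES, c("US", "UR")))
}

.as_payoff_matrix <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table) || ncol(table) != 2L ||
      nrow(table) != 8L)
    stop("payoff table must be an 8 x 2 numeric matrix (columns US, UR)",
         call. = FALSE)
  if (is.null(rownames(table))) rownames(table) <- OUTCOMES
  if (!setequal(rownames(table), OUTCOMES))
    stop("payoff table rownames must be O1..O8", call. = FALSE)
  table <- table[OUTCOMES, , drop = FALSE]
  colnames(table) <- c("US", "UR")
  table
}

#' Look up the payoffs of an outcome
#'
#' @param table a payoff table as returned by [default_payoff_table()].
#' @param outcome outcome labels or indices.
#' @return `payoff()` returns a length-2 named vector `(US, UR)` for a
#'   single outcome, or an n x 2 matrix for several.  `joint_payoff()`
#'   returns `US + UR`, the inclusive utility credited to a cellularized
#'   endo-pair.
#' @examples
#' payoff(default_payoff_table(), "O1")
#' joint_payoff(default_payoff_table(), c("O1", "O8"))
#' @export
payoff <- function(table, outcome) {
  table <- .as_payoff_matrix(table)
  idx <- .as_outcome_index(outcome)
  out <- table[idx, , drop = FALSE]
  if (length(idx) == 1L) out[1L, ] else out
}

#' @rdname payoff
#' @export
joint_payoff <- function(table, outcome) {
  table <- .as_payoff_matrix(table)
  idx <- .as_outcome_index(outcome)
  unname(table[idx, "US"] + table[idx, "UR"])
}

.weakly_dominated <- function(us, ur) {
  vapply(seq_along(us), function(j) {
    any(us >= us[j] & ur >= ur[j] & (us > us[j] | ur > ur[j]))
  }, logical(1))
}

#' Validate a payoff table
#'
#' Checks the structural constraints required of a payoff table: shape and
#' completeness, non-negativity (utilities are reused as Dirichlet
#' concentration parameters), Pareto efficiency of `O1`, uniqueness of the
#' joint-utility maximum at `O1`, and the deception temptation
#' (`U_S(O8) > U_S(O1)` with `U_R(O8) < U_R(O2)`).
#'
#' @param table candidate payoff table (8 x 2 matrix or data frame,
#'   rownames `O1`..`O8`).
#' @return An object of class `payoff_validation`: a list with elements
#'   `valid` (logical) and `violations` (character vector naming each
#'   violated constraint; empty when valid).
#' @examples
#' validate_payoff_table(default_payoff_table())
#' @export
validate_payoff_table <- function(table) {
  violations <- character(0)
  table <- tryCatch(.as_payoff_matrix(table), error = function(e) {
    violations <<- conditionMessage(e)
    NULL
  })
  if (!is.null(table)) {
    us <- table[, "US"]; ur <- table[, "UR"]
    if (any(!is.finite(table)) || any(table < 0))
      violations <- c(violations, "non-negativity")
    joint <- us + ur
    if (!(joint[1L] > max(joint[-1L])))
      violations <- c(violations, "O1 unique joint max")
    if (.weakly_dominated(us, ur)[1L])
      violations <- c(violations, "O1 Pareto efficiency")
    if (!(us[8L] > us[1L] && ur[8L] < ur[2L]))
      violations <- c(violations, "deception temptation")
  }
  structure(list(valid = length(violations) == 0L, violations = violations),
            class = "payoff_validation")
}

#' @export
print.payoff_validation <- function(x, ...) {
  if (x$valid) {
    cat("Payoff table: valid\n")
  } else {
    cat("Payoff table: INVALID\n")
    cat(paste0("  - ", x$violations, "\n"), sep = "")
  }
  invisible(x)
}

#' Pareto front of a payoff table
#'
#' Returns the outcomes that are not weakly dominated: no other outcome is
#' at least as good for both players and strictly better for one.  Outcomes
#' with identical payoff pairs do not dominate each other, so duplicates are
#' either both on or both off the front.
#'
#' @param table a payoff table.
#' @return Character vector of undominated outcome labels.
#' @examples
#' pareto_front(default_payoff_table())
#' @export
pareto_front <- function(table) {
  table <- .as_payoff_matrix(table)
  OUTCOMES[!.weakly_dominated(table[, "US"], table[, "UR"])]
}
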