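#' Initialise a model-free SARSA learner
#'
#' State-action values start at 0 for every pair. The discount factor gamma is
#' fixed at 1 (exposed for completeness, not fitted). The learner is
#' goal-blind: it sees only the reward actually received, so goal-gated coins
#' enter as the gated amount, never the raw coin value.
#'
#' @param tree a `decision_tree` (sets the table dimensions).
#' @param alpha learning rate in (0, 1).
#' @param gamma discount factor, fixed at 1.
#' @return object of class `mf_state` with `Q1` (1 x 2 matrix, start-state
#'   action values) and `Q2` (`n_s2` x 2 matrix).
#' @export
mf_state <- function(tree, alpha, gamma = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  structure(
    list(Q1 = matrix(0, 1, 2), Q2 = matrix(0, tree$n_s2, 2),
         alpha = alpha, gamma = gamma),
    class = "mf_state")
}

#' @export
print.mf_state <- function(x, ...) {
  cat("<mf_state> alpha =", x$alpha, "gamma =", x$gamma, "\n")
  cat("Q1:", format(x$Q1, digits = 4), "\n")
  invisible(x)
}

#' One SARSA update
#'
#' Computes the reward-prediction error
#' `delta = r + gamma * Q(s', a') - Q(s, a)` (bootstrap 0 at a terminal next
#' state) and moves `Q(s, a)` by `alpha * delta`. Only that entry changes.
#'
#' @param mf an `mf_state`.
#' @param stage stage of `(s, a)`: 1 or 2.
#' @param state,action 0-based ids of the updated pair.
#' @param r_next reward observed on entering the next state.
#' @param next_state 0-based id of the next state, or `NULL` if terminal
#'   bookkeeping is not needed.
#' @param next_action 0-based next action, or `NULL` when the next state is
#'   terminal.
#' @return list `state` (updated `mf_state`) and `delta` (the RPE).
#' @export
mf_update <- function(mf, stage, state, action, r_next,
                      next_state = NULL, next_action = NULL) {
  q_sa <- if (stage == 1L) mf$Q1[state + 1L, action + 1L]
          else mf$Q2[state + 1L, action + 1L]
  bootstrap <- if (is.null(next_action)) 0
               else mf$Q2[next_state + 1L, next_action + 1L]
  delta <- r_next + mf$gamma * bootstrap - q_sa
  if (stage == 1L) {
    mf$Q1[state + 1L, action + 1L] <- q_sa + mf$alpha * delta
  } else {
    mf$Q2[state + 1L, action + 1L] <- q_sa + mf$alpha * delta
  }
  list(state = mf, delta = delta)
}

#' Apply the SARSA updates of one experienced trial
#'
#' Two updates in trial order: first `(s1, a1)` with intermediate reward 0 and
#' bootstrap from the pre-update `Q(s2, a2)`; then `(s2, a2)` with the
#' goal-contingent reward received at the terminal state and bootstrap 0.
#'
#' @param mf an `mf_state`.
#' @param trial one-row data.frame (or list) with `s1`, `a1`, `s2`, `a2`,
#'   `reward`.
#' @return list `state` (updated learner) and `deltas` (RPE of each update).
#' @export
mf_process_trial <- function(mf, trial) {
  up1 <- mf_update(mf, 1L, trial$s1, trial$a1, r_next = 0,
                   next_state = trial$s2, next_action = trial$a2)
  up2 <- mf_update(up1$state, 2L, trial$s2, trial$a2, r_next = trial$reward)
  list(state = up2$state, deltas = c(up1$delta, up2$delta))
}
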