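#' Softmax choice probabilities
#'
#' `P(a) = exp(tau * Q(a)) / sum_b exp(tau * Q(b))`, computed in the log
#' domain with max-subtraction for overflow safety. `tau = 0` yields the
#' uniform policy regardless of the values.
#'
#' @param q numeric vector of action values (length >= 2, finite).
#' @param tau inverse temperature, finite and non-negative.
#' @return probability vector summing to 1.
#' @export
softmax_probs <- function(q, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau < 0)
    stop("tau must be a single finite non-negative number")
  if (length(q) < 2 || any(!is.finite(q)))
    stop("q must hold at least two finite action values")
  z <- tau * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Replay a session with a learner and record pre-choice values
#'
#' Runs the model-free or model-based learner over the trials of a session in
#' order and records, for each of the two choices per trial, the action
#' values available at the moment of choice. These snapshots are what the
#' softmax likelihood is evaluated on.
#'
#' @param session session data.frame (see [simulate_subject()]).
#' @param tree the `decision_tree`.
#' @param model `"mf"` or `"mb"`.
#' @param rate the model's learning rate (alpha for MF, eta for MB).
#' @return object of class `learner_trace`: list with `q` (2n x 2 matrix of
#'   pre-choice values in choice order), `chosen` (0-based chosen actions),
#'   `trial` (trial index of each choice), `choice_stage` (1 or 2) and
#'   `model`.
#' @export
learner_trace <- function(session, tree, model = c("mf", "mb"), rate) {
  model <- match.arg(model)
  n <- nrow(session)
  q <- matrix(NA_real_, 2L * n, 2L)
  chosen <- integer(2L * n)
  if (model == "mf") {
    st <- mf_state(tree, alpha = rate)
    for (i in seq_len(n)) {
      tr <- session[i, ]
      q[2L * i - 1L, ] <- st$Q1[1, ]
      q[2L * i, ] <- st$Q2[tr$s2 + 1L, ]
      st <- mf_process_trial(st, tr)$state
    }
  } else {
    st <- mb_state(tree, eta = rate)
    for (i in seq_len(n)) {
      tr <- session[i, ]
      out <- mb_process_trial(st, tr, tree)
      q[2L * i - 1L, ] <- out$snapshots$q1
      q[2L * i, ] <- out$snapshots$q2
      st <- out$state
    }
  }
  chosen[seq(1L, 2L * n, by = 2L)] <- session$a1
  chosen[seq(2L, 2L * n, by = 2L)] <- session$a2
  structure(
    list(q = q, chosen = chosen,
         trial = rep(seq_len(n), each = 2L),
         choice_stage = rep(1:2, times = n), model = model),
    class = "learner_trace")
}

#' Per-choice log-likelihoods under a softmax policy
#'
#' Evaluates `log P(chosen action)` for every choice of a trace at inverse
#' temperature `tau`. Probabilities are floored at 1e-12 before the log so a
#' single near-impossible choice cannot produce an infinite penalty.
#'
#' @param trace a `learner_trace` (or any list with `q` and `chosen`).
#' @param tau inverse temperature.
#' @return list with `loglik` (per-choice vector), `lik` (per-choice
#'   probabilities of the chosen actions) and `total` (sum of `loglik`).
#' @export
choice_loglik <- function(trace, tau) {
  if (is.null(trace$q) || is.null(trace$chosen))
    stop("trace must supply pre-choice value snapshots and chosen actions")
  n <- nrow(trace$q)
  lik <- numeric(n)
  for (i in seq_len(n)) {
    p <- softmax_probs(trace$q[i, ], tau)
    lik[i] <- p[trace$chosen[i] + 1L]
  }
  lik_f <- pmax(lik, 1e-12)
  list(loglik = log(lik_f), lik = lik, total = sum(log(lik_f)))
}
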