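check_session_tree <- function(session, tree) {
  req <- c("goal_condition", "uncertainty", "goal_colour",
           "s1", "a1", "s2", "a2", "s3", "reward")
  miss <- setdiff(req, names(session))
  if (length(miss))
    stop("session is missing column(s): ", paste(miss, collapse = ", "))
  if (any(session$s2 < 0 | session$s2 >= tree$n_s2) ||
      any(session$s3 < 0 | session$s3 >= tree$n_terminal) ||
      any(!session$a1 %in% 0:1) || any(!session$a2 %in% 0:1))
    stop("session state/action codes are out of range for this tree")
  invisible(TRUE)
}

goal_reward_matrix <- function(session, tree) {
  key <- paste(session$goal_condition, session$goal_colour)
  uniq <- !duplicated(key)
  maps <- matrix(NA_real_, sum(uniq), tree$n_terminal)
  rownames(maps) <- key[uniq]
  for (i in which(uniq))
    maps[key[i], ] <- goal_reward_vector(tree, session$goal_condition[i],
                                         session$goal_colour[i])
  maps[key, , drop = FALSE]
}

succ2_matrix <- function(tree) {
  m <- matrix(NA_integer_, tree$n_s2 * 2L, 2L)
  for (j in seq_len(tree$n_s2) - 1L)
    for (a in 0:1)
      m[j * 2L + a + 1L, ] <- tree$succ2[j + 1L, a + 1L, ]
  m
}

#' Per-choice likelihoods of a session under a model at given parameters
#'
#' Replays the session with the compiled learner and returns the softmax
#' probability each model assigns to every observed choice, plus the total
#' negative log-likelihood (probabilities floored at 1e-12 before the log).
#'
#' @param session session data.frame.
#' @param tree the `decision_tree`.
#' @param model `"mf"` or `"mb"`.
#' @param rate learning rate (alpha for MF, eta for MB), in (0, 1).
#' @param tau inverse temperature, >= 0.
#' @return list with `lik` (length `2 * n_trials`) and `nll`.
#' @export
model_likelihood <- function(session, tree, model = c("mf", "mb"), rate, tau) {
  model <- match.arg(model)
  check_session_tree(session, tree)
  lik <- if (model == "mf") {
    mf_replay_cpp(as.integer(session$a1), as.integer(session$s2),
                  as.integer(session$a2), as.numeric(session$reward),
                  tree$n_s2, rate, tau)
  } else {
    mb_replay_cpp(as.integer(session$a1), as.integer(session$s2),
                  as.integer(session$a2), as.integer(session$s3),
                  goal_reward_matrix(session, tree),
                  matrix(as.integer(tree$succ1), 2, 2), succ2_matrix(tree),
                  tree$n_s2, rate, tau)
  }
  list(lik = lik, nll = -sum(log(pmax(lik, 1e-12))))
}

TAU_CAP <- 100

#' Fit a learning model to one subject's choices by maximum likelihood
#'
#' Minimises the negative log-likelihood of both choices of every trial over
#' (learning rate, inverse temperature) with multi-restart Nelder-Mead. The
#' search runs unconstrained in transformed space: the learning rate through
#' a logistic map to (0, 1) and tau through an exponential map capped at 100.
#' Restart initialisations are uniform over rate in (0.01, 0.99) and tau in
#' (0.1, 30). The default 200 restarts guards against local optima; tests and
#' exploratory runs may reduce it.
#'
#' @inheritParams model_likelihood
#' @param n_restarts number of random restarts (default 200).
#' @param seed integer seed making the restart draws reproducible.
#' @return object of class `fit_result`: `model`, `params` (named `rate`,
#'   `tau`), `nll`, `aic` (`2k + 2 nll`, k = 2), `bic`
#'   (`k log(n_choices) + 2 nll`), `per_choice_lik`, `n_choices`,
#'   `n_restarts_used`, `converged`, `best_restart`.
#' @export
fit_model <- function(session, tree, model = c("mf", "mb"),
                      n_restarts = 200L, seed = 1L) {
  model <- match.arg(model)
  check_session_tree(session, tree)
  if (nrow(session) < 10) stop("at least 10 trials are required to fit")

  a1 <- as.integer(session$a1); s2 <- as.integer(session$s2)
  a2 <- as.integer(session$a2); s3 <- as.integer(session$s3)
  rew <- as.numeric(session$reward)
  if (model == "mb") {
    gr <- goal_reward_matrix(session, tree)
    sc1 <- matrix(as.integer(tree$succ1), 2, 2)
    sc2 <- succ2_matrix(tree)
  }
  nll_fun <- function(x) {
    rate <- stats::plogis(x[1])
    tau <- min(exp(x[2]), TAU_CAP)
    lik <- if (model == "mf")
      mf_replay_cpp(a1, s2, a2, rew, tree$n_s2, rate, tau)
    else
      mb_replay_cpp(a1, s2, a2, s3, gr, sc1, sc2, tree$n_s2, rate, tau)
    -sum(log(pmax(lik, 1e-12)))
  }

  set.seed(seed)
  # Restart k consumes draws 2k-1 and 2k, so for a fixed seed the first m
  # restarts of a larger run coincide with an m-restart run.
  u <- matrix(runif(2L * n_restarts), ncol = 2, byrow = TRUE)
  inits <- cbind(stats::qlogis(0.01 + 0.98 * u[, 1]),
                 log(0.1 + 29.9 * u[, 2]))
  best <- NULL
  for (k in seq_len(n_restarts)) {
    opt <- optim(inits[k, ], nll_fun, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$restart <- k
    }
  }
  if (!is.finite(best$value)) stop("non-finite NLL at every restart")

  rate <- stats::plogis(best$par[1])
  tau <- min(exp(best$par[2]), TAU_CAP)
  lik <- pmax(model_likelihood(session, tree, model, rate, tau)$lik, 1e-12)
  nll <- -sum(log(lik))
  n_choices <- length(lik)
  structure(
    list(model = model, params = c(rate = rate, tau = tau), nll = nll,
         aic = 2 * 2 + 2 * nll, bic = 2 * log(n_choices) + 2 * nll,
         per_choice_lik = lik, n_choices = n_choices,
         n_restarts_used = n_restarts,
         converged = best$convergence == 0, best_restart = best$restart),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> model =", toupper(x$model),
      sprintf("| rate = %.3f tau = %.3f", x$params["rate"], x$params["tau"]),
      sprintf("| NLL = %.2f AIC = %.2f BIC = %.2f", x$nll, x$aic, x$bic), "\n")
  invisible(x)
}

#' Fit the MB and MF models independently to every subject of a cohort
#'
#' @param sessions named list of session data.frames (names = subject ids).
#' @param tree the `decision_tree`.
#' @param n_restarts restarts per fit.
#' @param seed master seed; each subject/model fit gets a derived seed that is
#'   recorded in the result.
#' @return named list per subject: `list(mb = <fit_result>, mf = <fit_result>,
#'   seed_mb = , seed_mf = )`. A failing subject aborts with an error naming
#'   the subject.
#' @export
fit_cohort <- function(sessions, tree, n_restarts = 200L, seed = 1L) {
  if (length(sessions) < 1) stop("empty cohort")
  ids <- names(sessions) %||% as.character(seq_along(sessions))
  out <- vector("list", length(sessions))
  names(out) <- ids
  for (i in seq_along(sessions)) {
    seed_mb <- (seed * 10007L + 2L * i) %% .Machine$integer.max
    seed_mf <- (seed * 10007L + 2L * i + 1L) %% .Machine$integer.max
    out[[i]] <- tryCatch(
      list(mb = fit_model(sessions[[i]], tree, "mb", n_restarts, seed_mb),
           mf = fit_model(sessions[[i]], tree, "mf", n_restarts, seed_mf),
           seed_mb = seed_mb, seed_mf = seed_mf),
      error = function(e)
        stop("fit failed for subject ", ids[i], ": ", conditionMessage(e),
             call. = FALSE))
  }
  out
}
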