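#' Arbitration state: average reward and deliberation cost
#'
#' Tracks the tonic reward expectation R-bar used to price a tree search at
#' R-bar * tau. In `"fixed"` mode (the promised-reward manipulation) R-bar
#' always reads as `fixed_value` and observations leave it unchanged.
#'
#' @param eta learning rate of the average-reward update, in (0, 1).
#' @param tau deliberation cost per tree edge (reward per unit time).
#' @param mode `"observed"` (default) or `"fixed"`.
#' @param fixed_value value R-bar is pinned to in fixed mode (the paper's
#'   manipulation pins it at the maximum reward, 1).
#' @param avg_reward initial R-bar in observed mode (0: no expectation
#'   before any experience).
#' @return An object of class `arbitration_state`.
#' @export
arbitration_state <- function(eta = 0.001, tau = 0.1,
                              mode = c("observed", "fixed"),
                              fixed_value = 1, avg_reward = 0) {
  mode <- match.arg(mode)
  stopifnot(eta > 0, eta < 1, tau >= 0)
  structure(list(avg_reward = avg_reward, eta = eta, tau = tau, mode = mode,
                 fixed_value = fixed_value), class = "arbitration_state")
}

#' Current average-reward reading
#' @param arb an [arbitration_state()].
#' @return R-bar (the fixed value in fixed mode).
#' @export
avg_reward <- function(arb) {
  if (identical(arb$mode, "fixed")) arb$fixed_value else arb$avg_reward
}

#' Gain of learning an action's true value
#'
#' Knowing that action a has value x only helps if it changes the policy:
#' for the currently best action, by revealing it is worse than the runner-up;
#' for any other action, by revealing it beats the current best.
#'
#' @param x candidate value.
#' @param best_mean,second_mean cache posterior means of the best and
#'   second-best actions.
#' @param is_best whether the action under consideration is the current best.
#' @return Non-negative gain.
#' @export
gain <- function(x, best_mean, second_mean, is_best) {
  if (is_best) {
    ifelse(x < second_mean, second_mean - x, 0)
  } else {
    ifelse(x > best_mean, x - best_mean, 0)
  }
}

#' Value of perfect information of a cache entry
#'
#' Expected [gain()] under the action's Beta posterior,
#' integral of G(x) p(Q = x) dx, computed by the fixed 512-node quadrature
#' over the sub-interval where the gain is nonzero (or by seeded Monte Carlo
#' draws with `method = "mc"`, matching the looser "by sampling" reading).
#'
#' @param table a [cache_q_table()].
#' @param state state index (needs >= 2 actions).
#' @param action action index or name.
#' @param method `"quadrature"` (deterministic, default) or `"mc"`.
#' @param mc_samples draw count for the Monte Carlo backend.
#' @return Non-negative VPI.
#' @export
vpi <- function(table, state, action, method = c("quadrature", "mc"),
                mc_samples = 10000L) {
  stopifnot(inherits(table, "cache_q_table"))
  method <- match.arg(method)
  if (is.character(action)) action <- match(action, table$actions)
  bs <- best_and_second(table, state)
  m <- cache_means(table)[state, ]
  a <- table$alpha[state, action]
  b <- table$beta[state, action]
  if (method == "quadrature") {
    vpi_cpp(a, b, action == bs[["best"]], m[[bs[["best"]]]],
            m[[bs[["second"]]]])
  } else {
    vpi_mc_cpp(a, b, action == bs[["best"]], m[[bs[["best"]]]],
               m[[bs[["second"]]]], as.integer(mc_samples))
  }
}

#' Which controller answers for an action
#'
#' The goal-directed tree is consulted only when the value of perfect
#' information strictly exceeds the opportunity cost R-bar * tau of
#' deliberating; equality resolves to the cheaper cache.
#'
#' @param vpi_value VPI of the action.
#' @param arb an [arbitration_state()].
#' @return `"tree"` or `"cache"`.
#' @export
select_system <- function(vpi_value, arb) {
  if (vpi_value > avg_reward(arb) * arb$tau) "tree" else "cache"
}

#' Update the average reward with a new observation
#'
#' Observed mode: R-bar <- (1 - eta) R-bar + eta r. Fixed mode: unchanged.
#' Only extrinsic plus action rewards of executed steps feed R-bar; intrinsic
#' rewards model no environmental income and are excluded.
#'
#' @param arb an [arbitration_state()].
#' @param r observed reward of the executed step.
#' @return The updated state.
#' @export
update_avg_reward <- function(arb, r) {
  if (identical(arb$mode, "observed"))
    arb$avg_reward <- (1 - arb$eta) * arb$avg_reward + arb$eta * r
  arb
}
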