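#' Discovery-probability matrix
#'
#' Prior probability of discovering node B when leaving node A by random
#' search, taken proportional to the inverse squared distance `1/d(A,B)^2`
#' and row-normalized so that each row sums to 1 over all destinations
#' B != A. The diagonal is zero. Nodes are ordered nest first, then plants,
#' matching `env$dist`.
#'
#' @param env a `bee_env` object.
#' @return `(n_plants + 1)` square matrix with zero diagonal and unit row
#'   sums.
#' @export
#' @examples
#' env <- generate_environment(5, seed = 1)
#' rowSums(discovery_probabilities(env))  # all 1
discovery_probabilities <- function(env) {
  d <- env$dist
  if (any(d[upper.tri(d)] <= 0)) {
    stop("coincident nodes: discovery prior undefined", call. = FALSE)
  }
  w <- 1 / d^2
  diag(w) <- 0
  w / rowSums(w)
}

#' Initialize the Q-table
#'
#' Each transition expectation starts at half the best possible perceived
#' value: `Q0(A,B) = 0.5 * n_max * p_d(A,B)`. Rows therefore sum to
#' `n_max / 2`.
#'
#' @param env a `bee_env`.
#' @param p_d discovery-probability matrix; computed from `env` if missing.
#' @return Square matrix of initial Q values (zero diagonal).
#' @export
init_q <- function(env, p_d = discovery_probabilities(env)) {
  0.5 * env$n_max * p_d
}

#' Perceived value of a realized transition
#'
#' On arriving at B from A the bee perceives
#' `v = n_t(B) * p_d(A,B)`, where `n_t(B)` is the nectar standing in B at
#' arrival, before any harvesting. The discovery prior discounts the value
#' of transitions that would have been hard to find by random search.
#'
#' @param n_arrival nectar standing at the destination on arrival (uL).
#' @param p_d_entry the `p_d(A,B)` entry for the realized transition.
#' @return The perceived value (uL-equivalent).
#' @export
perceived_value <- function(n_arrival, p_d_entry) n_arrival * p_d_entry

#' Q-value update rule
#'
#' Exponentially weighted update `Q <- alpha * v + (1 - alpha) * Q`,
#' applied only to the transition just realized. `alpha = 0` disables
#' learning entirely; `alpha = 1` replaces the expectation with the latest
#' experience. Experiencing `v < Q` lowers Q: negative reinforcement needs
#' no separate penalty term.
#'
#' @param q_prev previous expectation.
#' @param alpha learning rate in `[0, 1]`.
#' @param v perceived value of the realized transition.
#' @return Updated Q value.
#' @export
update_q <- function(q_prev, alpha, v) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  alpha * v + (1 - alpha) * q_prev
}

#' Softmax choice probabilities
#'
#' Probability of choosing destination B from the current node is
#' `exp(beta * Q(B)) / sum(exp(beta * Q(B')))` over the allowed
#' destinations. `beta = 0` gives a uniform choice; large `beta`
#' concentrates on the highest-valued transition. Uses max-subtraction for
#' floating-point stability (`beta * Q` can reach hundreds).
#'
#' @param q_values numeric vector of Q values of the allowed destinations.
#' @param beta exploration-exploitation parameter (>= 0).
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' softmax_probabilities(c(1, 0), beta = 10)
softmax_probabilities <- function(q_values, beta) {
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  z <- beta * q_values
  w <- exp(z - max(z))
  w / sum(w)
}

#' Sample the next destination
#'
#' Draws one destination among the allowed ones with softmax probabilities.
#' Working-memory exclusions and the current node must already have been
#' removed from `candidates`.
#'
#' @param candidates integer vector of candidate node indices.
#' @param q_values Q values aligned with `candidates`.
#' @param beta exploration-exploitation parameter.
#' @return One element of `candidates`.
#' @export
choose_destination <- function(candidates, q_values, beta) {
  if (length(candidates) == 0) stop("no allowed destination", call. = FALSE)
  if (length(candidates) == 1) return(candidates)
  candidates[sample.int(length(candidates), 1L,
                        prob = softmax_probabilities(q_values, beta))]
}

#' Working-memory exclusion set
#'
#' Plants whose last visit completed less than `wm_span` seconds ago are
#' excluded from the choice set. With `wm_span = 0` nothing is excluded.
#'
#' @param last_visit numeric vector of last visit completion times per
#'   plant (`-Inf` for plants never visited).
#' @param now current time (s).
#' @param wm_span working-memory span (s).
#' @return Logical vector, `TRUE` for excluded plants.
#' @export
working_memory_filter <- function(last_visit, now, wm_span) {
  (now - last_visit) < wm_span
}

#' Bout termination rule
#'
#' A bout ends when the crop is full or when flying the proposed next leg
#' would push the distance flown this bout beyond the maximum; the bee then
#' returns to the nest in a straight line (the homing leg is exempt from
#' the cap).
#'
#' @param crop_load current crop load (uL).
#' @param crop_capacity crop capacity (uL).
#' @param bout_distance distance flown so far this bout (m).
#' @param next_leg length of the proposed next leg (m).
#' @param max_bout_distance maximal distance flown per bout (m).
#' @return `TRUE` if the bout must end.
#' @export
should_end_bout <- function(crop_load, crop_capacity, bout_distance,
                            next_leg, max_bout_distance) {
  crop_load >= crop_capacity ||
    (bout_distance + next_leg) > max_bout_distance
}
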