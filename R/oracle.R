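# Reference agents ---------------------------------------------------------
#
# Two non-neural agents that plug into the same q_values() / planner surface
# as the DQN: a tabular Q-learner (an independent oracle on small grids,
# where the per-map MDP is finite and Q-learning provably converges) and a
# scripted agent with a user-supplied preference function (for exercising
# planner rules deterministically).

# decode unit-cube features back to the 0-based grid cell
decode_cell <- function(features, geometry) {
  x <- if (geometry$n_x > 1L) round(features[1] * (geometry$n_x - 1L)) else 0L
  y <- if (geometry$n_y > 1L) round(features[2] * (geometry$n_y - 1L)) else 0L
  as.integer(c(x, y))
}

#' Train a tabular Q-learning agent on a single map
#'
#' On a fixed map the confidence is a function of position, so the cell index
#' is a sufficient tabular state. Epsilon-greedy Q-learning with a constant
#' learning rate is run against the same environment (same rewards, same
#' episode cap) as the DQN; on small all-positive grids its greedy policy
#' converges to stopping at the optimal cell, which makes it an independent
#' oracle for the neural agent.
#'
#' @param map A [confidence_map()].
#' @param start 0-based start cell.
#' @param rparams A [reward_params()].
#' @param episodes Training episodes.
#' @param alpha Constant Q-learning step size.
#' @param gamma Discount factor.
#' @param epsilon_start,epsilon_end Linear exploration schedule endpoints
#'   (decaying over the first 60% of episodes).
#' @param episode_cap Forced episode termination bound.
#' @param seed Integer seed.
#' @return A `tabular_agent` holding the Q table (cells x 9 actions).
#' @export
train_tabular_q <- function(map, start, rparams = reward_params(),
                            episodes = 4000L, alpha = 0.2, gamma = 0.95,
                            epsilon_start = 1.0, epsilon_end = 0.05,
                            episode_cap = 100L, seed = 1L) {
  stopifnot(inherits(map, "confidence_map"))
  geom <- map$geometry
  n_states <- n_cells(geom)
  Q <- matrix(0, n_states, 9L)
  decay <- max(1L, as.integer(ceiling(0.6 * episodes)))
  cell_index <- function(pos) pos[1] + geom$n_x * pos[2] + 1L
  with_seed(seed, {
    for (ep in seq_len(episodes)) {
      eps <- epsilon_start +
        min(1, (ep - 1) / decay) * (epsilon_end - epsilon_start)
      state <- env_reset(map, start)
      while (!state$done) {
        s <- cell_index(state$position)
        a <- if (stats::runif(1) < eps) sample.int(9L, 1L) else which.max(Q[s, ])
        rec <- env_step(state, ACTIONS[a], map, rparams, episode_cap)
        s2 <- cell_index(rec$state_after$position)
        target <- if (rec$action == "STOP") {
          rec$reward
        } else {
          rec$reward + gamma * max(Q[s2, ])
        }
        Q[s, a] <- Q[s, a] + alpha * (target - Q[s, a])
        state <- rec$state_after
      }
    }
  })
  structure(list(Q = Q, geometry = geom), class = "tabular_agent")
}

#' @export
q_values.tabular_agent <- function(agent, features) {
  cell <- decode_cell(features, agent$geometry)
  agent$Q[cell[1] + agent$geometry$n_x * cell[2] + 1L, ]
}

#' A deterministic scripted agent
#'
#' Wraps a user-supplied function `q_fun(position, c_here)` returning 9
#' action values; useful for tracing planner rules with hand-written
#' preferences.
#'
#' @param q_fun Function of `(position, c_here)` returning 9 reals.
#' @param geometry The [grid_geometry()] the agent operates on.
#' @return A `scripted_agent`.
#' @export
scripted_agent <- function(q_fun, geometry) {
  structure(list(q_fun = q_fun, geometry = geometry), class = "scripted_agent")
}

#' @export
q_values.scripted_agent <- function(agent, features) {
  cell <- decode_cell(features, agent$geometry)
  q <- agent$q_fun(cell, features[3])
  stopifnot(length(q) == 9L)
  q
}
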