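# XYC grid-world environment ---------------------------------------------

#' The nine probe actions
#'
#' Eight compass moves (unit steps in X/Y; N is +1 along the body's vertical
#' axis, E is +1 along the frontal axis) plus STOP with zero displacement.
#' The vector order is the fixed tie-break and output ordering used
#' throughout the package.
#'
#' @format Character vector of length 9.
#' @export
ACTIONS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW", "STOP")

# displacement (dx, dy) per action, same order as ACTIONS
ACTION_DELTAS <- matrix(
  c( 1L,  0L,
     1L,  1L,
     0L,  1L,
    -1L,  1L,
    -1L,  0L,
    -1L, -1L,
     0L, -1L,
     1L, -1L,
     0L,  0L),
  ncol = 2, byrow = TRUE,
  dimnames = list(ACTIONS, c("dx", "dy"))
)

#' Reward-shaping parameters
#'
#' The seven reward terms used during training. The first three shorten the
#' search (a cost per move, an extra cost for pushing against the grid edge,
#' and a flat stop cost); the last four steer the probe away from local
#' confidence maxima (a fast-stop bonus at the optimal cell, a gain on the
#' per-move confidence change, a bonus for stopping at the optimal cell, and
#' a penalty `m_l * (c_m - c_p)` for stopping anywhere else, proportional to
#' the confidence shortfall at the stopping cell).
#'
#' @param move_cost Reward for performing one move.
#' @param out_of_range_cost Additional reward when a move leaves the grid
#'   (the probe stays in place).
#' @param stop_cost Flat reward for selecting STOP.
#' @param fast_optimal_bonus Bonus for stopping at the optimal cell after
#'   fewer than `fast_move_threshold` moves.
#' @param fast_move_threshold Move-count bound for the fast bonus (the
#'   terminal STOP itself is not counted).
#' @param delta_gain Gain on the confidence change per move.
#' @param optimal_stop_bonus Bonus for stopping at the optimal cell.
#' @param m_l Slope of the non-optimal stop penalty (larger values avoid
#'   local maxima more aggressively but risk overshooting the optimum).
#' @return A `reward_params` list.
#' @export
reward_params <- function(move_cost = -0.1,
                          out_of_range_cost = -0.3,
                          stop_cost = -3.0,
                          fast_optimal_bonus = 20.0,
                          fast_move_threshold = 35L,
                          delta_gain = 10.0,
                          optimal_stop_bonus = 5.0,
                          m_l = 40) {
  stopifnot(fast_move_threshold >= 1L, m_l > 0)
  structure(
    list(
      move_cost = move_cost,
      out_of_range_cost = out_of_range_cost,
      stop_cost = stop_cost,
      fast_optimal_bonus = fast_optimal_bonus,
      fast_move_threshold = as.integer(fast_move_threshold),
      delta_gain = delta_gain,
      optimal_stop_bonus = optimal_stop_bonus,
      m_l = m_l
    ),
    class = "reward_params"
  )
}

#' Apply one action to a grid position
#'
#' STOP and out-of-range attempts leave the position unchanged; other actions
#' shift it by the action's unit displacement.
#'
#' @param position 0-based `(x, y)` cell inside the grid.
#' @param action One of [ACTIONS].
#' @param geometry A [grid_geometry()].
#' @return List with `position` (the new cell) and `out_of_range` (TRUE iff
#'   the displaced cell fell outside the grid).
#' @export
apply_action <- function(position, action, geometry) {
  if (!in_grid(position, geometry)) {
    stop("position must lie inside the grid")
  }
  action <- match.arg(action, ACTIONS)
  delta <- ACTION_DELTAS[action, ]
  target <- position + delta
  if (in_grid(target, geometry)) {
    list(position = as.integer(target), out_of_range = FALSE)
  } else {
    list(position = as.integer(position), out_of_range = TRUE)
  }
}

#' Evaluate the shaped reward for one executed action
#'
#' All applicable reward terms sum. Movement actions receive `move_cost`,
#' plus `out_of_range_cost` when blocked, plus `delta_gain * (c_after -
#' c_before)` (zero for blocked moves, whose position does not change). STOP
#' receives `stop_cost`; stopping at the optimal cell adds
#' `optimal_stop_bonus`, plus `fast_optimal_bonus` when fewer than
#' `fast_move_threshold` moves preceded the stop; stopping anywhere else
#' subtracts `m_l * (c_m - c_p)` where `c_p` is the confidence at the
#' stopping cell.
#'
#' @param c_before,c_after Confidence before/after the action.
#' @param action One of [ACTIONS].
#' @param out_of_range TRUE when a movement action was blocked at the edge.
#' @param moves_before_stop Number of moves executed before a STOP (excluding
#'   the STOP itself); ignored for movement actions.
#' @param stopped_at_optimal TRUE when the action is STOP at the optimal cell.
#' @param c_m Confidence at the optimal cell (> 0).
#' @param params A [reward_params()].
#' @return List with `reward` and a named `breakdown` whose entries sum to
#'   `reward`.
#' @export
compute_reward <- function(c_before, c_after, action, out_of_range,
                           moves_before_stop, stopped_at_optimal, c_m, params) {
  stopifnot(c_before >= 0, c_before <= 1, c_after >= 0, c_after <= 1, c_m > 0)
  action <- match.arg(action, ACTIONS)
  breakdown <- numeric(0)
  if (action == "STOP") {
    breakdown["stop_cost"] <- params$stop_cost
    if (isTRUE(stopped_at_optimal)) {
      breakdown["optimal_stop_bonus"] <- params$optimal_stop_bonus
      if (moves_before_stop < params$fast_move_threshold) {
        breakdown["fast_optimal_bonus"] <- params$fast_optimal_bonus
      }
    } else {
      breakdown["local_stop_penalty"] <- -params$m_l * (c_m - c_after)
    }
  } else {
    breakdown["move_cost"] <- params$move_cost
    if (isTRUE(out_of_range)) {
      breakdown["out_of_range_cost"] <- params$out_of_range_cost
    }
    breakdown["delta"] <- params$delta_gain * (c_after - c_before)
  }
  list(reward = sum(breakdown), breakdown = breakdown)
}

#' Reset the environment at a start cell
#'
#' @param map A [confidence_map()].
#' @param start 0-based `(x, y)` start cell inside the grid.
#' @return An `env_state` with fields `position`, `c_here`, `moves_taken`,
#'   `done`.
#' @export
env_reset <- function(map, start) {
  stopifnot(inherits(map, "confidence_map"))
  start <- as.integer(start)
  if (!in_grid(start, map$geometry)) {
    stop(sprintf("start cell (%d, %d) lies outside the %d x %d grid",
                 start[1], start[2], map$geometry$n_x, map$geometry$n_y))
  }
  structure(
    list(position = start, c_here = cell_conf(map, start),
         moves_taken = 0L, done = FALSE),
    class = "env_state"
  )
}

#' Execute one environment step
#'
#' Applies the action, increments the move counter, evaluates the shaped
#' reward, and terminates the episode on STOP or when the episode cap is
#' reached (a cap termination carries no stop-condition rewards).
#'
#' @param state Current `env_state` (not done).
#' @param action One of [ACTIONS].
#' @param map The subject's [confidence_map()].
#' @param params A [reward_params()].
#' @param episode_cap Forced-termination bound on executed actions.
#' @return A `step_record` with `state_before`, `action`, `state_after`,
#'   `reward`, `reward_breakdown`, `out_of_range`.
#' @export
env_step <- function(state, action, map, params, episode_cap = 100L) {
  stopifnot(inherits(state, "env_state"))
  if (isTRUE(state$done)) stop("cannot step a terminated episode")
  action <- match.arg(action, ACTIONS)
  moved <- apply_action(state$position, action, map$geometry)
  c_after <- cell_conf(map, moved$position)
  stopped_at_optimal <- action == "STOP" &&
    all(state$position == map$optimal_cell)
  rew <- compute_reward(
    c_before = state$c_here, c_after = c_after, action = action,
    out_of_range = moved$out_of_range,
    moves_before_stop = state$moves_taken,
    stopped_at_optimal = stopped_at_optimal,
    c_m = map$c_m, params = params
  )
  moves_after <- state$moves_taken + 1L
  state_after <- structure(
    list(position = moved$position, c_here = c_after,
         moves_taken = moves_after,
         done = action == "STOP" || moves_after >= episode_cap),
    class = "env_state"
  )
  structure(
    list(state_before = state, action = action, state_after = state_after,
         reward = rew$reward, reward_breakdown = rew$breakdown,
         out_of_range = moved$out_of_range),
    class = "step_record"
  )
}
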