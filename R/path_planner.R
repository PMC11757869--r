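# Optimized path generation ----------------------------------------------
#
# The trained policy alone has three failure modes: it can oscillate over
# cells it has already searched, it can stop on a zero-confidence cell, and
# it cannot return to the best position found earlier. The planner wraps the
# greedy policy with three rules:
#   A. on a revisited cell, pick the best action not yet chosen there;
#   B. on STOP at a zero-confidence cell, travel back to the best visited
#      cell and resume;
#   C. on STOP elsewhere, terminate and estimate the highest-confidence
#      visited cell.

#' Per-cell visit ledger
#'
#' Tracks how often each cell was visited and which actions have already been
#' selected there (rule A masking). Masks persist for the whole search.
#'
#' @param geometry A [grid_geometry()].
#' @return A `visit_ledger` environment.
#' @export
visit_ledger <- function(geometry) {
  led <- new.env(parent = emptyenv())
  led$counts <- matrix(0L, geometry$n_x, geometry$n_y)
  led$chosen <- matrix(vector("list", n_cells(geometry)),
                       geometry$n_x, geometry$n_y)
  led$geometry <- geometry
  class(led) <- "visit_ledger"
  led
}

ledger_note_visit <- function(ledger, position) {
  i <- position[1] + 1L
  j <- position[2] + 1L
  ledger$counts[i, j] <- ledger$counts[i, j] + 1L
  invisible(ledger)
}

ledger_record_action <- function(ledger, position, action) {
  i <- position[1] + 1L
  j <- position[2] + 1L
  ledger$chosen[[i, j]] <- union(ledger$chosen[[i, j]], action)
  invisible(ledger)
}

#' Select the planner's next action at a state
#'
#' On a first visit the greedy argmax action is chosen. From the second visit
#' of a cell onward, the argmax is taken over actions not yet selected there
#' (rule A); when all nine are exhausted, `NA` is returned as the exhaustion
#' signal. The selected action is recorded in the ledger.
#'
#' @param agent Any agent with a [q_values()] method.
#' @param state An `env_state`.
#' @param ledger A [visit_ledger()].
#' @return One of [ACTIONS], or `NA_character_` when every action has been
#'   used at this cell.
#' @export
next_action <- function(agent, state, ledger) {
  if (isTRUE(state$done)) stop("state is terminal")
  geom <- ledger$geometry
  q <- q_values(agent, encode_state(state$position, state$c_here, geom))
  i <- state$position[1] + 1L
  j <- state$position[2] + 1L
  allowed <- rep(TRUE, 9L)
  if (ledger$counts[i, j] >= 2L) {
    allowed <- !(ACTIONS %in% ledger$chosen[[i, j]])
  }
  if (!any(allowed)) return(NA_character_)
  q_masked <- ifelse(allowed, q, -Inf)
  action <- ACTIONS[which.max(q_masked)]
  ledger_record_action(ledger, state$position, action)
  action
}

# action name for a unit step (sign(dx), sign(dy))
step_action_name <- function(dx, dy) {
  hit <- which(ACTION_DELTAS[, "dx"] == dx & ACTION_DELTAS[, "dy"] == dy)
  ACTIONS[hit[1]]
}

#' Shortest 8-connected return path to the best visited cell
#'
#' Computes a Chebyshev-shortest move sequence from the current (last
#' visited) cell to the visited cell with maximal confidence, taking the
#' earliest-visited cell among ties. Diagonal steps are used while both axes
#' differ.
#'
#' @param visited Matrix of visited 0-based cells (rows in visit order).
#' @param conf Confidence at each visited cell.
#' @param geometry A [grid_geometry()].
#' @return Character vector of movement actions (possibly empty).
#' @export
return_to_best <- function(visited, conf, geometry) {
  stopifnot(nrow(visited) >= 1L, nrow(visited) == length(conf))
  best <- which.max(conf)  # earliest among ties
  target <- visited[best, ]
  current <- visited[nrow(visited), ]
  path <- character(0)
  while (any(current != target)) {
    dx <- sign(target[1] - current[1])
    dy <- sign(target[2] - current[2])
    path <- c(path, step_action_name(dx, dy))
    current <- current + c(dx, dy)
  }
  path
}

#' Run one optimized probe search
#'
#' Rolls the agent's greedy policy through the planner rules until a
#' terminating STOP (rule C), ledger exhaustion, or the global step cap.
#' Every executed action — movements, rule-B return moves, and the final
#' STOP — counts toward `moves`. The estimated cell is the highest-confidence
#' visited cell (earliest among ties); `reached_optimal` records whether it
#' is the map's optimal cell.
#'
#' @param agent Any agent with a [q_values()] method.
#' @param map A [confidence_map()].
#' @param start 0-based start cell.
#' @param rparams A [reward_params()] used for the per-step reward audit.
#' @param cap Global bound on planner steps.
#' @return A `search_outcome` with fields `trajectory` (`visited` cell
#'   matrix, `conf`, `actions`, `per_step_rewards`), `estimated_cell`, `c_s`,
#'   `moves`, `reached_optimal`, `termination_reason`.
#' @export
plan_search <- function(agent, map, start, rparams = reward_params(),
                        cap = 500L) {
  geom <- map$geometry
  state <- env_reset(map, start)
  ledger <- visit_ledger(geom)
  ledger_note_visit(ledger, state$position)
  visited <- matrix(state$position, 1L, 2L)
  conf <- state$c_here
  actions_log <- character(0)
  rewards_log <- numeric(0)
  moves <- 0L
  reason <- "cap"
  huge_cap <- .Machine$integer.max %/% 2L

  record_move <- function(rec) {
    state <<- rec$state_after
    visited <<- rbind(visited, rec$state_after$position)
    conf <<- c(conf, rec$state_after$c_here)
    ledger_note_visit(ledger, rec$state_after$position)
    actions_log <<- c(actions_log, rec$action)
    rewards_log <<- c(rewards_log, rec$reward)
    moves <<- moves + 1L
  }

  iter <- 0L
  while (moves < cap && iter < 10L * cap) {
    iter <- iter + 1L
    action <- next_action(agent, state, ledger)
    if (is.na(action)) {
      reason <- "exhausted"
      break
    }
    if (action == "STOP") {
      if (state$c_here == 0) {
        # rule B: go back to the best cell on the trajectory and resume
        path <- return_to_best(visited, conf, geom)
        for (mv in path) {
          record_move(env_step(state, mv, map, rparams, episode_cap = huge_cap))
        }
        if (length(path) == 0L) {
          # already at the best visited cell: count the re-arrival so the
          # rejected STOP is masked on the next pass instead of looping
          ledger_note_visit(ledger, state$position)
        }
        next
      }
      # rule C: terminate here
      rec <- env_step(state, "STOP", map, rparams, episode_cap = huge_cap)
      actions_log <- c(actions_log, "STOP")
      rewards_log <- c(rewards_log, rec$reward)
      moves <- moves + 1L
      reason <- "stop"
      break
    }
    record_move(env_step(state, action, map, rparams, episode_cap = huge_cap))
  }

  best <- which.max(conf)  # earliest among ties
  estimated_cell <- as.integer(visited[best, ])
  structure(
    list(
      trajectory = list(visited = unname(visited), conf = conf,
                        actions = actions_log,
                        per_step_rewards = rewards_log),
      estimated_cell = estimated_cell,
      c_s = conf[best],
      moves = moves,
      reached_optimal = all(estimated_cell == map$optimal_cell),
      termination_reason = reason
    ),
    class = "search_outcome"
  )
}

#' @export
print.search_outcome <- function(x, ...) {
  cat(sprintf(
    "<search_outcome> estimated (%d, %d), c_s = %.4f, %d moves, %s%s\n",
    x$estimated_cell[1], x$estimated_cell[2], x$c_s, x$moves,
    x$termination_reason,
    if (x$reached_optimal) ", optimal" else ""
  ))
  invisible(x)
}

# Conventional baseline ----------------------------------------------------

#' Serpentine full-coverage scan path
#'
#' The conventional five-way traveling scan: each Y column is traversed along
#' the full X extent, alternating direction per column, visiting every cell
#' exactly once in `n_x * n_y - 1` moves (five passes on the default grid).
#'
#' @param geometry A [grid_geometry()].
#' @return Matrix of 0-based cells in scan order.
#' @export
five_way_scan <- function(geometry) {
  cells <- matrix(0L, n_cells(geometry), 2L)
  k <- 0L
  for (y in 0:(geometry$n_y - 1L)) {
    xs <- 0:(geometry$n_x - 1L)
    if (y %% 2L == 1L) xs <- rev(xs)
    for (x in xs) {
      k <- k + 1L
      cells[k, ] <- c(x, y)
    }
  }
  cells
}

#' Conventional full-coverage estimate
#'
#' Scans the whole grid with [five_way_scan()] and estimates the global
#' argmax cell, so the optimal cell is always reached at the cost of
#' `n_x * n_y - 1` moves.
#'
#' @param map A [confidence_map()].
#' @return A `search_outcome` with `termination_reason = "coverage"`.
#' @export
conventional_estimate <- function(map) {
  cells <- five_way_scan(map$geometry)
  conf <- apply(cells, 1L, function(p) cell_conf(map, p))
  best <- which.max(conf)
  structure(
    list(
      trajectory = list(visited = cells, conf = conf,
                        actions = character(0),
                        per_step_rewards = numeric(0)),
      estimated_cell = as.integer(cells[best, ]),
      c_s = conf[best],
      moves = nrow(cells) - 1L,
      reached_optimal = TRUE,
      termination_reason = "coverage"
    ),
    class = "search_outcome"
  )
}
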