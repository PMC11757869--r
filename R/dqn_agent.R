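# DQN agent ---------------------------------------------------------------

#' Encode a probe state as network features
#'
#' The XYC state is normalised to the unit cube: grid indices are divided by
#' their maximal index (degenerate single-cell axes map to 0) and the
#' confidence is already in \[0, 1\].
#'
#' @param position 0-based `(x, y)` cell.
#' @param c_here Confidence at the cell.
#' @param geometry A [grid_geometry()].
#' @return Numeric feature vector of length 3.
#' @export
encode_state <- function(position, c_here, geometry) {
  stopifnot(c_here >= 0, c_here <= 1)
  if (!in_grid(position, geometry)) stop("position outside the grid")
  x <- if (geometry$n_x > 1L) position[1] / (geometry$n_x - 1L) else 0
  y <- if (geometry$n_y > 1L) position[2] / (geometry$n_y - 1L) else 0
  c(x, y, c_here)
}

#' Action values of an agent at a state
#'
#' Generic over agent types: the DQN agent runs a deterministic forward pass;
#' tabular and scripted agents decode the features back to a grid cell.
#'
#' @param agent An agent object.
#' @param features Length-3 feature vector from [encode_state()].
#' @return Numeric vector of 9 action values ordered as [ACTIONS].
#' @export
q_values <- function(agent, features) UseMethod("q_values")

#' @export
q_values.dqn_agent <- function(agent, features) {
  if (length(features) != agent$net$config$input_dim) {
    stop("feature vector has the wrong length")
  }
  drop(mlp_forward(agent$net, matrix(features, nrow = 1L)))
}

#' Create an untrained DQN agent
#'
#' @param net_config A [q_network_config()].
#' @return A `dqn_agent` with seeded initial weights.
#' @export
new_dqn_agent <- function(net_config = q_network_config()) {
  structure(list(net = mlp_init(net_config)), class = "dqn_agent")
}

#' Number of trainable parameters of a DQN agent
#'
#' @param agent A `dqn_agent`.
#' @return Integer parameter count.
#' @export
n_params <- function(agent) mlp_n_params(agent$net)

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action is drawn from the
#' current RNG stream; otherwise the argmax action value wins, ties broken by
#' the fixed [ACTIONS] ordering.
#'
#' @param q Numeric vector of 9 action values.
#' @param epsilon Exploration probability in \[0, 1\].
#' @return One of [ACTIONS].
#' @export
select_action_epsilon_greedy <- function(q, epsilon) {
  stopifnot(length(q) == 9L, epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    ACTIONS[sample.int(9L, 1L)]
  } else {
    ACTIONS[which.max(q)]
  }
}

#' One-step temporal-difference target
#'
#' @param reward Immediate reward.
#' @param next_q Action values at the successor state (9 reals).
#' @param done TRUE for terminal transitions.
#' @param gamma Discount factor in \[0, 1\].
#' @return `reward` if done, else `reward + gamma * max(next_q)`.
#' @export
td_target <- function(reward, next_q, done, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  if (isTRUE(done)) reward else reward + gamma * max(next_q)
}

# Replay buffer ------------------------------------------------------------

#' Experience-replay buffer
#'
#' Fixed-capacity circular store of transitions; once full, the oldest
#' transition is evicted first. Backed by preallocated matrices for speed.
#'
#' @param capacity Maximum number of stored transitions.
#' @param feature_dim State feature length.
#' @return A `replay_buffer` environment.
#' @export
replay_buffer <- function(capacity, feature_dim = 3L) {
  stopifnot(capacity >= 1L)
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$s <- matrix(0, capacity, feature_dim)
  buf$a <- integer(capacity)
  buf$r <- numeric(capacity)
  buf$s2 <- matrix(0, capacity, feature_dim)
  buf$done <- numeric(capacity)
  buf$size <- 0L
  buf$head <- 0L  # next write slot (0-based)
  class(buf) <- "replay_buffer"
  buf
}

#' @rdname replay_buffer
#' @param buf A `replay_buffer`.
#' @param s,a,r,s2,done Transition: state features, action index (1-9),
#'   reward, successor features, terminal flag.
#' @export
replay_push <- function(buf, s, a, r, s2, done) {
  i <- buf$head + 1L
  buf$s[i, ] <- s
  buf$a[i] <- a
  buf$r[i] <- r
  buf$s2[i, ] <- s2
  buf$done[i] <- as.numeric(done)
  buf$head <- (buf$head + 1L) %% buf$capacity
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' @rdname replay_buffer
#' @export
replay_size <- function(buf) buf$size

#' @rdname replay_buffer
#' @param n Minibatch size.
#' @export
replay_sample <- function(buf, n) {
  idx <- sample.int(buf$size, n, replace = buf$size < n)
  list(s = buf$s[idx, , drop = FALSE], a = buf$a[idx], r = buf$r[idx],
       s2 = buf$s2[idx, , drop = FALSE], done = buf$done[idx])
}

# Training -----------------------------------------------------------------

#' DQN training configuration
#'
#' Defaults follow conservative small-scale DQN practice: a modest replay
#' buffer, linear exploration decay over the first 60% of episodes, and a
#' periodically synced target network.
#'
#' @param episodes Training episodes.
#' @param discount_gamma Discount factor.
#' @param learning_rate Adam learning rate.
#' @param batch_size Replay minibatch size.
#' @param replay_capacity Replay buffer capacity.
#' @param min_replay_before_learning Stored transitions required before
#'   updates begin.
#' @param epsilon_start,epsilon_end Exploration schedule endpoints.
#' @param epsilon_decay_episodes Episodes over which epsilon decays linearly;
#'   defaults to 60% of `episodes`.
#' @param target_sync_interval Learner steps between target-network syncs.
#' @param episode_cap Forced episode termination after this many actions.
#' @param seed Master seed for the whole training run.
#' @return A `train_config` list.
#' @export
train_config <- function(episodes = 5000L,
                         discount_gamma = 0.95,
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         replay_capacity = 10000L,
                         min_replay_before_learning = 500L,
                         epsilon_start = 1.0,
                         epsilon_end = 0.05,
                         epsilon_decay_episodes = NULL,
                         target_sync_interval = 200L,
                         episode_cap = 100L,
                         seed = 1L) {
  if (is.null(epsilon_decay_episodes)) {
    epsilon_decay_episodes <- max(1L, as.integer(ceiling(0.6 * episodes)))
  }
  stopifnot(
    episodes >= 1L, discount_gamma >= 0, discount_gamma <= 1,
    batch_size >= 1L, replay_capacity >= 1L,
    min_replay_before_learning >= 1L,
    epsilon_start >= 0, epsilon_start <= 1,
    epsilon_end >= 0, epsilon_end <= 1,
    epsilon_decay_episodes >= 1L, target_sync_interval >= 1L,
    episode_cap >= 1L
  )
  structure(
    list(episodes = as.integer(episodes), discount_gamma = discount_gamma,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         replay_capacity = as.integer(replay_capacity),
         min_replay_before_learning = as.integer(min_replay_before_learning),
         epsilon_start = epsilon_start, epsilon_end = epsilon_end,
         epsilon_decay_episodes = as.integer(epsilon_decay_episodes),
         target_sync_interval = as.integer(target_sync_interval),
         episode_cap = as.integer(episode_cap), seed = as.integer(seed)),
    class = "train_config"
  )
}

epsilon_at <- function(config, episode) {
  frac <- min(1, (episode - 1) / config$epsilon_decay_episodes)
  config$epsilon_start + frac * (config$epsilon_end - config$epsilon_start)
}

#' Train a DQN search policy on a cohort of confidence maps
#'
#' Each episode draws a map round-robin by episode index (keeping training
#' bit-reproducible under one seed), resets the probe at `start`, and rolls
#' out an epsilon-greedy episode. Transitions feed an experience-replay
#' buffer; minibatch updates regress the online network toward one-step TD
#' targets computed with a periodically synced target network. Only STOP
#' transitions are terminal for bootstrapping; cap-terminated episodes are
#' truncated without stop-condition rewards.
#'
#' @param maps Non-empty list of [confidence_map()] objects.
#' @param start 0-based `(x, y)` start cell.
#' @param rparams A [reward_params()].
#' @param net_config A [q_network_config()].
#' @param tconfig A [train_config()].
#' @return List with `agent` (a trained `dqn_agent`) and `log`, a data frame
#'   of per-episode return and epsilon.
#' @export
train_dqn <- function(maps, start, rparams = reward_params(),
                      net_config = q_network_config(),
                      tconfig = train_config()) {
  if (length(maps) == 0L) stop("training requires a non-empty map cohort")
  geometry <- maps[[1L]]$geometry
  seeds <- derive_seeds(tconfig$seed, 2L)
  net_config$init_seed <- seeds[1L]
  net <- mlp_init(net_config)
  target <- net
  opt <- adam_init(net, lr = tconfig$learning_rate)
  buf <- replay_buffer(tconfig$replay_capacity)
  returns <- numeric(tconfig$episodes)
  epsilons <- numeric(tconfig$episodes)
  learner_steps <- 0L
  n_actions <- 9L
  stop_idx <- match("STOP", ACTIONS)
  gamma <- tconfig$discount_gamma

  with_seed(seeds[2L], {
    for (ep in seq_len(tconfig$episodes)) {
      map <- maps[[(ep - 1L) %% length(maps) + 1L]]
      eps <- epsilon_at(tconfig, ep)
      epsilons[ep] <- eps
      state <- env_reset(map, start)
      feats <- encode_state(state$position, state$c_here, geometry)
      ep_return <- 0
      while (!state$done) {
        if (eps > 0 && stats::runif(1) < eps) {
          a_idx <- sample.int(n_actions, 1L)
        } else {
          q <- mlp_forward(net, matrix(feats, nrow = 1L))
          a_idx <- which.max(q)
        }
        rec <- env_step(state, ACTIONS[a_idx], map, rparams,
                        episode_cap = tconfig$episode_cap)
        state <- rec$state_after
        feats2 <- encode_state(state$position, state$c_here, geometry)
        replay_push(buf, feats, a_idx, rec$reward, feats2,
                    done = a_idx == stop_idx)
        ep_return <- ep_return + rec$reward
        feats <- feats2

        if (buf$size >= tconfig$min_replay_before_learning) {
          batch <- replay_sample(buf, tconfig$batch_size)
          nq <- mlp_forward(target, batch$s2)
          nmax <- nq[, 1L]
          for (j in 2:ncol(nq)) nmax <- pmax(nmax, nq[, j])
          y <- batch$r + gamma * (1 - batch$done) * nmax
          acts <- mlp_forward_cached(net, batch$s)
          grads <- mlp_grad(net, acts, batch$a, y)
          upd <- adam_step(net, grads, opt)
          net <- upd$net
          opt <- upd$opt
          learner_steps <- learner_steps + 1L
          if (learner_steps %% tconfig$target_sync_interval == 0L) {
            target <- net
          }
        }
      }
      returns[ep] <- ep_return
    }
  })
  list(
    agent = structure(list(net = net), class = "dqn_agent"),
    log = data.frame(episode = seq_len(tconfig$episodes),
                     return = returns, epsilon = epsilons)
  )
}

# Checkpoints --------------------------------------------------------------

#' Save / load an agent checkpoint
#'
#' The checkpoint is a JSON file: a plain header (network configuration,
#' layer shapes) plus the flat weight vector encoded as base64 of IEEE
#' doubles, so the round trip is bit-exact.
#'
#' @param agent A `dqn_agent`.
#' @param path Destination file.
#' @return `path` invisibly for `save_agent`; the restored agent for
#'   `load_agent`.
#' @export
save_agent <- function(agent, path) {
  stopifnot(inherits(agent, "dqn_agent"))
  net <- agent$net
  flat <- unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)))
  payload <- list(
    type = "dqn_agent",
    net_config = unclass(net$config),
    shapes = lapply(net$W, dim),
    weights_base64 = jsonlite::base64_enc(writeBin(flat, raw(), size = 8L))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$type, "dqn_agent")) stop("not a DQN agent checkpoint")
  cfg <- do.call(q_network_config, payload$net_config[
    c("depth_d", "width", "input_dim", "output_dim", "activation", "init_seed")
  ])
  raw_weights <- jsonlite::base64_dec(payload$weights_base64)
  flat <- readBin(raw_weights, "double", n = length(raw_weights) %/% 8L,
                  size = 8L)
  net <- mlp_init(cfg)
  offset <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- flat[(offset + 1L):(offset + k)]
    offset <- offset + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]][] <- flat[(offset + 1L):(offset + k)]
    offset <- offset + k
  }
  structure(list(net = net), class = "dqn_agent")
}
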