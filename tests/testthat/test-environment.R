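test_that("actions displace the probe by unit steps and clamp at the edge", {
  g <- grid_geometry(7, 5)
  expect_equal(apply_action(c(3, 2), "N", g),
               list(position = c(4L, 2L), out_of_range = FALSE))
  expect_equal(apply_action(c(6, 4), "NE", g),
               list(position = c(6L, 4L), out_of_range = TRUE))
  expect_equal(apply_action(c(3, 2), "STOP", g),
               list(position = c(3L, 2L), out_of_range = FALSE))
  expect_error(apply_action(c(9, 9), "N", g), "inside")
  # every movement action is a unit Chebyshev step; STOP is the identity
  for (a in ACTIONS) {
    res <- apply_action(c(3, 2), a, g)
    d <- res$position - c(3L, 2L)
    expect_lte(max(abs(d)), 1L)
    if (a == "STOP") expect_equal(d, c(0L, 0L))
  }
})

test_that("reward terms stack according to the reward table", {
  p <- reward_params()
  r <- function(...) compute_reward(...)$reward
  expect_equal(r(0, 0, "N", FALSE, 0, FALSE, 0.9, p), -0.1)
  expect_equal(r(0.30, 0.50, "E", FALSE, 0, FALSE, 0.9, p), -0.1 + 10 * 0.2)
  expect_equal(r(0.5, 0.5, "N", TRUE, 0, FALSE, 0.9, p), -0.1 - 0.3)
  expect_equal(r(0.9, 0.9, "STOP", FALSE, 10, TRUE, 0.9, p), -3 + 5 + 20)
  expect_equal(r(0.9, 0.9, "STOP", FALSE, 50, TRUE, 0.9, p), -3 + 5)
  expect_equal(r(0.7, 0.7, "STOP", FALSE, 10, FALSE, 0.9, p), -3 - 40 * 0.2)

  # additivity: reward always equals the sum of its breakdown
  rec <- compute_reward(0.2, 0.6, "NE", FALSE, 3, FALSE, 0.8, p)
  expect_equal(rec$reward, sum(rec$breakdown))
  rec2 <- compute_reward(0.2, 0.2, "STOP", FALSE, 3, FALSE, 0.8, p)
  expect_equal(rec2$reward, sum(rec2$breakdown))
  expect_named(rec2$breakdown, c("stop_cost", "local_stop_penalty"))
})

test_that("stop reward at a non-optimal cell rises with the stop confidence", {
  p <- reward_params(m_l = 40)
  cs <- seq(0, 0.8, by = 0.1)
  rewards <- vapply(cs, function(cp) {
    compute_reward(cp, cp, "STOP", FALSE, 5, FALSE, 0.9, p)$reward
  }, numeric(1))
  expect_true(all(diff(rewards) > 0))
  # slope equals m_l
  expect_equal(diff(rewards) / 0.1, rep(40, length(cs) - 1L))
  # stopping at the optimum always beats stopping anywhere else
  r_opt <- compute_reward(0.9, 0.9, "STOP", FALSE, 50, TRUE, 0.9, p)$reward
  expect_true(all(rewards < r_opt))
})

test_that("episodes reset, step and terminate correctly", {
  m <- make_map_3x3()
  p <- reward_params()
  s <- env_reset(m, c(2, 2))
  expect_equal(s$position, c(2L, 2L))
  expect_equal(s$c_here, 0.9)
  expect_equal(s$moves_taken, 0L)
  expect_error(env_reset(m, c(9, 9)), "outside")

  s0 <- env_reset(m, c(0, 0))
  rec <- env_step(s0, "NE", m, p)  # (0,0) -> (1,1), c 0.20 -> 0.50
  expect_equal(rec$state_after$position, c(1L, 1L))
  expect_equal(rec$reward, -0.1 + 10 * (0.50 - 0.20))
  expect_gt(rec$reward_breakdown[["delta"]], 0)

  stop_rec <- env_step(rec$state_after, "STOP", m, p)
  expect_true(stop_rec$state_after$done)
  expect_error(env_step(stop_rec$state_after, "N", m, p), "terminated")

  # cap termination without stop rewards
  s <- env_reset(m, c(0, 0))
  for (i in 1:3) {
    rec <- env_step(s, "N", m, p, episode_cap = 3L)
    s <- rec$state_after
  }
  expect_true(s$done)
  expect_false("stop_cost" %in% names(rec$reward_breakdown))
})

test_that("delta terms telescope to the net confidence change", {
  set.seed(401)
  p <- reward_params()
  for (trial in 1:50) {
    m <- generate_map(map_gen_params(seed = 500 + trial))
    s <- env_reset(m, c(sample(0:6, 1), sample(0:4, 1)))
    c_start <- s$c_here
    delta_sum <- 0
    for (k in 1:30) {
      a <- ACTIONS[sample.int(8L, 1L)]  # movement actions only
      rec <- env_step(s, a, m, p, episode_cap = 1000L)
      delta_sum <- delta_sum + rec$reward_breakdown[["delta"]]
      s <- rec$state_after
    }
    expect_equal(delta_sum, 10 * (s$c_here - c_start), tolerance = 1e-12)
  }
})
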