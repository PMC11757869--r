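test_that("revisited cells mask previously chosen actions", {
  m <- make_map_3x3()
  g <- m$geometry
  # scripted preferences: NE best, then E, then STOP, rest low
  prefs <- c(N = 1, NE = 9, E = 8, SE = 1, S = 1, SW = 1, W = 1, NW = 1, STOP = 7)
  ag <- scripted_agent(function(pos, c_here) unname(prefs[ACTIONS]), g)
  led <- visit_ledger(g)
  s <- env_reset(m, c(1, 1))
  # first visit: plain greedy
  led$counts[2, 2] <- 1L
  expect_identical(next_action(ag, s, led), "NE")
  # third visit with NE already chosen: second-best action
  led$counts[2, 2] <- 3L
  expect_identical(next_action(ag, s, led), "E")
  # exhaust everything
  led$chosen[[2, 2]] <- ACTIONS
  expect_true(is.na(next_action(ag, s, led)))
})

test_that("the return path is Chebyshev-shortest to the earliest best cell", {
  g <- grid_geometry(7, 5)
  visited <- rbind(c(2L, 2L), c(0L, 0L))
  path <- return_to_best(visited, c(0.9, 0.1), g)
  expect_identical(path, c("NE", "NE"))
  # current cell already best: empty path
  expect_length(return_to_best(rbind(c(1L, 1L)), 0.5, g), 0L)
  # tie: earliest-visited target wins
  visited <- rbind(c(1L, 1L), c(3L, 3L), c(0L, 0L))
  path <- return_to_best(visited, c(0.7, 0.7, 0.1), g)
  expect_identical(path, c("NE"))
  # mixed axis distances combine diagonal and straight steps
  visited <- rbind(c(4L, 1L), c(0L, 0L))
  path <- return_to_best(visited, c(0.9, 0.1), g)
  expect_identical(path, c("NE", "N", "N", "N"))
})

test_that("a zero-confidence stop triggers the return rule before terminating", {
  m <- make_map_3x3_zero()  # c(0,0) = 0, ridge at (2,2) = 0.8
  g <- m$geometry
  # an agent that always wants to stop immediately
  ag <- scripted_agent(function(pos, c_here) c(0, 0, 0, 0, 0, 0, 0, 0, 9), g)
  out <- plan_search(ag, m, c(0, 0), cap = 50)
  # trace: start (0,0) c=0 -> STOP selected -> rule B: best visited is the
  # start itself (empty return) -> STOP masked on the re-arrival -> first
  # unmasked action N -> (1,0), c=0.10 -> STOP accepted (rule C)
  expect_identical(out$termination_reason, "stop")
  expect_gt(out$c_s, 0)
  expect_identical(out$estimated_cell, c(1L, 0L))
})

test_that("rule C estimates the best visited cell, not the stop cell", {
  m <- make_map_3x3()
  g <- m$geometry
  # walk E twice along x = 0 (past c(0,1) = 0.35) then stop at (0,2) = 0.30
  step_count <- 0
  ag <- scripted_agent(function(pos, c_here) {
    if (pos[2] < 2) c(0, 0, 9, 0, 0, 0, 0, 0, 0) else c(0, 0, 0, 0, 0, 0, 0, 0, 9)
  }, g)
  out <- plan_search(ag, m, c(0, 0), cap = 50)
  expect_identical(out$termination_reason, "stop")
  expect_identical(out$estimated_cell, c(0L, 1L))
  expect_equal(out$c_s, 0.35)
  expect_equal(out$moves, 3L)  # two moves plus the terminating stop
  # estimate dominance: c_s >= every visited confidence
  expect_true(all(out$c_s >= out$trajectory$conf))
})

test_that("degenerate and adversarial agents still halt with an outcome", {
  m1 <- confidence_map(matrix(0.6, 1, 1), "one")
  ag <- scripted_agent(function(pos, c_here) rep(1, 9), m1$geometry)
  out <- plan_search(ag, m1, c(0, 0), cap = 50)
  expect_identical(out$estimated_cell, c(0L, 0L))
  expect_equal(out$c_s, 0.6)

  # an agent that always prefers a movement action loops until the ledger
  # masks it everywhere; the search still terminates
  m <- make_map_3x3()
  stubborn <- scripted_agent(function(pos, c_here) c(9, 8:1), m$geometry)
  out2 <- plan_search(stubborn, m, c(0, 0), cap = 200)
  expect_true(out2$termination_reason %in% c("stop", "exhausted", "cap"))
  expect_lte(out2$moves, 200)
})

test_that("the serpentine scan covers every cell exactly once", {
  for (g in list(grid_geometry(7, 5), grid_geometry(1, 1), grid_geometry(3, 4))) {
    cells <- five_way_scan(g)
    expect_equal(nrow(cells), g$n_x * g$n_y)
    expect_equal(nrow(unique(cells)), g$n_x * g$n_y)
    if (nrow(cells) > 1) {
      steps <- abs(diff(cells))
      expect_true(all(rowSums(steps) == 1L & apply(steps, 1, max) == 1L))
    }
  }
})

test_that("the conventional estimate always finds the optimum in 34 moves", {
  for (s in 1:10) {
    m <- generate_map(map_gen_params(seed = 3000 + s))
    out <- conventional_estimate(m)
    expect_identical(out$estimated_cell, m$optimal_cell)
    expect_equal(out$c_s, m$c_m)
    expect_equal(out$moves, 34L)
    expect_true(out$reached_optimal)
    expect_equal(loss_rate(out$c_s, m$c_m), 0)
  }
})

test_that("a converged tabular policy plans straight to the optimum", {
  m <- make_map_3x3()
  tab <- train_tabular_q(m, c(0, 0), episodes = 3000, seed = 8)
  out <- plan_search(tab, m, c(0, 0))
  expect_identical(out$estimated_cell, m$optimal_cell)
  expect_equal(out$c_s, m$c_m)
  expect_identical(out$termination_reason, "stop")
  # on cohorts where the optimum is reached, the search is cheaper than
  # full coverage (here: far cheaper)
  expect_lt(out$moves, 8L)
})
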