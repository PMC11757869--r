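test_that("loss rate measures the relative confidence shortfall", {
  expect_equal(loss_rate(0.8, 0.8), 0)
  expect_equal(loss_rate(0.0, 0.8), 1)
  expect_equal(loss_rate(0.6, 0.8), 0.25)
  expect_error(loss_rate(0.5, 0), "undefined")
  # bounded whenever 0 <= c_s <= c_m
  set.seed(9)
  cm <- runif(100, 0.1, 1)
  cs <- runif(100, 0, 1) * cm
  lc <- loss_rate(cs, cm)
  expect_true(all(lc >= 0 & lc <= 1))
})

test_that("pooled SD and Cohen's d match brute-force formulas", {
  expect_equal(pooled_sd(c(1, 2, 3), c(3, 4, 5)), 1)
  expect_equal(pooled_sd(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_error(pooled_sd(1, 2), "at least 3")
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), 2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(2, 2, 2), c(5, 5, 5)), "undefined")

  # textbook-formula oracle evaluated literally, on random inputs
  brute_pooled <- function(a, b) {
    sa2 <- sum((a - mean(a))^2) / (length(a) - 1)
    sb2 <- sum((b - mean(b))^2) / (length(b) - 1)
    sqrt(((length(a) - 1) * sa2 + (length(b) - 1) * sb2) /
           (length(a) + length(b) - 2))
  }
  set.seed(10)
  for (k in 1:100) {
    a <- rnorm(sample(2:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:30, 1), mean = runif(1, -2, 2))
    expect_equal(pooled_sd(a, b), brute_pooled(a, b))
    expect_equal(cohens_d(a, b), abs(mean(a) - mean(b)) / brute_pooled(a, b))
    # symmetry and shift invariance
    expect_equal(cohens_d(a, b), cohens_d(b, a))
    expect_equal(cohens_d(a + 5, b + 5), cohens_d(a, b))
    expect_equal(cohens_d(2 * a, 2 * b), cohens_d(a, b), tolerance = 1e-9)
  }
})

test_that("effect-size interpretation uses the <0.5 and >0.8 bands", {
  expect_equal(interpret_effects(0.19, 1.3),
               list(accuracy_maintained = TRUE, efficiency_improved = TRUE))
  expect_equal(interpret_effects(0.5, 0.8),
               list(accuracy_maintained = FALSE, efficiency_improved = FALSE))
  expect_equal(interpret_effects(0.49, 0.81),
               list(accuracy_maintained = TRUE, efficiency_improved = TRUE))
})

make_outcome <- function(c_s, moves) {
  structure(list(c_s = c_s, moves = moves), class = "search_outcome")
}

test_that("outcomes are banded and tabulated to 100%", {
  expect_equal(categorize_outcome(make_outcome(0.8, 20), 0.8),
               list(confidence_band = "C=C_m", move_band = "<35"))
  expect_equal(categorize_outcome(make_outcome(0, 10), 0.8),
               list(confidence_band = "C=0", move_band = "<35"))
  expect_equal(categorize_outcome(make_outcome(0.5, 40), 0.8),
               list(confidence_band = "0<C<C_m", move_band = ">=35"))

  # hand-built labelled set checked against direct counting
  labelled <- list(
    list(0.9, 10, "C=C_m", "<35"), list(0.9, 50, "C=C_m", ">=35"),
    list(0.9, 10, "C=C_m", "<35"), list(0.4, 12, "0<C<C_m", "<35"),
    list(0.4, 44, "0<C<C_m", ">=35"), list(0.0, 3, "C=0", "<35"),
    list(0.9, 34, "C=C_m", "<35"), list(0.2, 35, "0<C<C_m", ">=35"),
    list(0.9, 36, "C=C_m", ">=35"), list(0.0, 99, "C=0", ">=35")
  )
  outs <- lapply(labelled, function(s) make_outcome(s[[1]], s[[2]]))
  maps <- rep(list(list(c_m = 0.9)), length(labelled))
  tab <- summarize_outcomes(outs, maps)
  manual <- matrix(0, 3, 2, dimnames = dimnames(tab$table))
  for (s in labelled) manual[s[[3]], s[[4]]] <- manual[s[[3]], s[[4]]] + 10
  expect_equal(tab$table, manual)
  expect_equal(sum(tab$table), 100)
  expect_equal(sum(tab$row_totals), 100)
  expect_error(summarize_outcomes(list(), list()), "no outcomes")

  all_fast <- summarize_outcomes(
    list(make_outcome(0.9, 5)), list(list(c_m = 0.9))
  )
  expect_equal(all_fast$table["C=C_m", "<35"], 100)
})

test_that("the inspection-time model is a per-cell dwell", {
  expect_equal(inspection_time(make_outcome(0.9, 34)), 85.75)
  expect_equal(inspection_time(make_outcome(0.9, 0)), 2.45)
  t5 <- inspection_time(make_outcome(0.9, 5))
  t6 <- inspection_time(make_outcome(0.9, 6))
  expect_gt(t6, t5)
})

test_that("cross-validation partitions subjects and pools every trial once", {
  cohort <- fixture_cohort(n = 6, seed = 21)
  tc <- train_config(episodes = 40, min_replay_before_learning = 30, seed = 2)
  cv <- cross_validate(cohort, c(2, 2), reward_params(),
                       q_network_config(depth_d = 1), tc)
  test_idx <- sort(unlist(cv$folds))
  expect_equal(test_idx, 1:6)            # disjoint cover of the cohort
  expect_equal(nrow(cv$trials), 6L)      # pooled trial count = cohort size
  expect_length(cv$agents, 3L)
  expect_equal(sum(cv$outcome_table$table), 100)
  expect_error(cross_validate(cohort[1:2]), "at least 3")
  # conventional arm of every trial reaches the optimum at full cost
  expect_true(all(cv$trials$conv_moves == 34L))
  expect_true(all(cv$trials$conv_c_s == cv$trials$c_m))
})

test_that("parameter sweeps report effect sizes per value and select accuracy-first", {
  cohort <- fixture_cohort(n = 3, seed = 31)
  tc <- train_config(episodes = 30, min_replay_before_learning = 25, seed = 4)
  res <- sweep_parameter(cohort, "m_l", c(10, 40), tconfig = tc)
  expect_equal(nrow(res), 2L)
  expect_true(all(c("value", "d_c", "d_a") %in% names(res)))

  fake <- data.frame(value = c("a", "b"), d_c = c(0.3, 0.2), d_a = c(1.0, 0.9))
  expect_equal(select_sweep_choice(fake)$value, "b")
  tied <- data.frame(value = c("a", "b"), d_c = c(0.2, 0.2), d_a = c(0.9, 1.1))
  expect_equal(select_sweep_choice(tied)$value, "b")
})
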