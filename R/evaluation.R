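# Evaluation metrics and harness ------------------------------------------

#' Loss-of-confidence rate
#'
#' `L_c = 1 - c_s / c_m`: the relative confidence shortfall of the estimated
#' stopping position against the optimal cell. Zero when the optimum was
#' found, one when the estimate carries no confidence at all.
#'
#' @param c_s Confidence at the estimated cell (>= 0).
#' @param c_m Confidence at the optimal cell (> 0).
#' @return The loss rate.
#' @export
loss_rate <- function(c_s, c_m) {
  if (any(c_m <= 0)) stop("loss rate undefined for c_m <= 0")
  stopifnot(all(c_s >= 0))
  1 - c_s / c_m
}

#' Pooled standard deviation of two groups
#'
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))` with sample
#' variances — the spread estimate in Cohen's d.
#'
#' @param a,b Numeric vectors; together at least 3 values and at least one
#'   group with 2 or more.
#' @return The pooled standard deviation.
#' @export
pooled_sd <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  if (n_a + n_b < 3L || max(n_a, n_b) < 2L) {
    stop("pooled SD needs at least 3 values with one group of size >= 2")
  }
  v_a <- if (n_a >= 2L) stats::var(a) else 0
  v_b <- if (n_b >= 2L) stats::var(b) else 0
  sqrt(((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2))
}

#' Cohen's d effect size
#'
#' Absolute standardised mean difference `|mean(a) - mean(b)| / pooled_sd`.
#' Used both for `d_C` (stop confidences, accuracy) and `d_A` (search action
#' counts, efficiency).
#'
#' @param a,b Numeric vectors.
#' @return The effect size (>= 0).
#' @export
cohens_d <- function(a, b) {
  s <- pooled_sd(a, b)
  if (s == 0) stop("effect size undefined: pooled standard deviation is zero")
  abs(mean(a) - mean(b)) / s
}

#' Interpret the accuracy and efficiency effect sizes
#'
#' Accuracy is considered maintained when the confidence effect size `d_C`
#' stays below 0.5 (at most a small-to-medium shift against the full-coverage
#' baseline); efficiency is considered improved when the action-count effect
#' size `d_A` exceeds 0.8 (a large reduction).
#'
#' @param d_c Confidence effect size.
#' @param d_a Action-count effect size.
#' @return List with logicals `accuracy_maintained` and `efficiency_improved`.
#' @export
interpret_effects <- function(d_c, d_a) {
  stopifnot(is.finite(d_c), is.finite(d_a))
  list(accuracy_maintained = d_c < 0.5, efficiency_improved = d_a > 0.8)
}

#' Categorise one search outcome
#'
#' Bands an outcome by its stop confidence (`C = C_m`, `0 < C < C_m`,
#' `C = 0`; equality tested with tolerance 1e-12 on stored confidences) and
#' its move count (fewer than `threshold` or not).
#'
#' @param outcome A `search_outcome`.
#' @param c_m Optimal-cell confidence of the outcome's map.
#' @param threshold Move-count band boundary.
#' @return List with `confidence_band` and `move_band` strings.
#' @export
categorize_outcome <- function(outcome, c_m, threshold = 35L) {
  stopifnot(c_m > 0)
  tol <- 1e-12
  confidence_band <- if (abs(outcome$c_s - c_m) <= tol) {
    "C=C_m"
  } else if (outcome$c_s <= tol) {
    "C=0"
  } else {
    "0<C<C_m"
  }
  move_band <- if (outcome$moves < threshold) "<35" else ">=35"
  list(confidence_band = confidence_band, move_band = move_band)
}

#' Tabulate outcome categories as percentages
#'
#' Builds the 3 x 2 percentage table of confidence band against move band,
#' with row and column totals; the grand total is 100%.
#'
#' @param outcomes List of `search_outcome` objects.
#' @param maps Matching list of [confidence_map()]s.
#' @param threshold Move-count band boundary.
#' @return List with `table` (3 x 2 matrix of percentages), `row_totals`,
#'   `col_totals`, `n`.
#' @export
summarize_outcomes <- function(outcomes, maps, threshold = 35L) {
  if (length(outcomes) == 0L) stop("no outcomes to summarise")
  stopifnot(length(outcomes) == length(maps))
  bands <- c("C=C_m", "0<C<C_m", "C=0")
  move_bands <- c("<35", ">=35")
  counts <- matrix(0L, 3L, 2L, dimnames = list(bands, move_bands))
  for (i in seq_along(outcomes)) {
    cat_i <- categorize_outcome(outcomes[[i]], maps[[i]]$c_m, threshold)
    counts[cat_i$confidence_band, cat_i$move_band] <-
      counts[cat_i$confidence_band, cat_i$move_band] + 1L
  }
  pct <- 100 * counts / length(outcomes)
  list(table = pct, row_totals = rowSums(pct), col_totals = colSums(pct),
       n = length(outcomes))
}

#' Inspection-time model
#'
#' Models wall-clock inspection time as a constant dwell per visited cell
#' (including the start cell): `(moves + 1) * seconds_per_cell`. The default
#' dwell of 2.45 s/cell puts a full 35-cell coverage scan near 86 s, the
#' scale of a slow serpentine sweep of the chest.
#'
#' @param seconds_per_cell Dwell per cell in seconds (> 0).
#' @return A `time_params` list.
#' @export
time_params <- function(seconds_per_cell = 2.45) {
  stopifnot(seconds_per_cell > 0)
  structure(list(seconds_per_cell = seconds_per_cell), class = "time_params")
}

#' @rdname time_params
#' @param outcome A `search_outcome`.
#' @param params A `time_params` object.
#' @return Modelled inspection time in seconds.
#' @export
inspection_time <- function(outcome, params = time_params()) {
  (outcome$moves + 1) * params$seconds_per_cell
}

# Cross-validation ---------------------------------------------------------

# contiguous three-way split of 1..n, sizes as equal as possible
three_fold_split <- function(n) {
  bounds <- round(seq(0, n, length.out = 4))
  lapply(1:3, function(k) (bounds[k] + 1L):bounds[k + 1L])
}

#' Subject-wise three-fold cross-validation
#'
#' Splits the cohort into three contiguous subject groups A, B, C; trains
#' model alpha on A+B, beta on B+C, gamma on A+C; and evaluates alpha on C,
#' beta on A, gamma on B, so every subject is searched exactly once by a
#' model that never saw it. Each test search is compared with the
#' full-coverage baseline on the same map.
#'
#' @param cohort List of [confidence_map()]s (>= 3 subjects).
#' @param start 0-based probe start cell.
#' @param rparams A [reward_params()].
#' @param net_config A [q_network_config()].
#' @param tconfig A [train_config()]; per-fold training seeds are derived
#'   from its `seed`.
#' @param planner_cap Planner step bound per search.
#' @param move_threshold Move-count band boundary for the outcome table.
#' @return List with `agents` (3 trained agents), `folds` (test indices per
#'   fold), `trials` (per-subject data frame), `outcome_table`, and summary
#'   statistics (`d_c`, `d_a`, `mean_l_c`, `mean_l_c_nonoptimal`,
#'   `attainment_rate`, `mean_moves`, `mean_time_s`, `conventional_time_s`).
#' @export
cross_validate <- function(cohort, start = c(2L, 2L),
                           rparams = reward_params(),
                           net_config = q_network_config(),
                           tconfig = train_config(),
                           planner_cap = 500L,
                           move_threshold = 35L) {
  n <- length(cohort)
  if (n < 3L) stop("cross-validation needs at least 3 subjects")
  groups <- three_fold_split(n)  # A, B, C
  train_groups <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))  # alpha, beta, gamma
  test_groups <- c(3L, 1L, 2L)
  fold_seeds <- derive_seeds(tconfig$seed, 3L)

  agents <- vector("list", 3L)
  trials <- NULL
  outcomes <- list()
  trial_maps <- list()
  for (f in 1:3) {
    train_idx <- unlist(groups[train_groups[[f]]])
    test_idx <- groups[[test_groups[f]]]
    cfg <- tconfig
    cfg$seed <- fold_seeds[f]
    fit <- train_dqn(cohort[train_idx], start, rparams, net_config, cfg)
    agents[[f]] <- fit$agent
    for (i in test_idx) {
      map <- cohort[[i]]
      out <- plan_search(fit$agent, map, start, rparams, cap = planner_cap)
      conv <- conventional_estimate(map)
      outcomes[[length(outcomes) + 1L]] <- out
      trial_maps[[length(trial_maps) + 1L]] <- map
      trials <- rbind(trials, data.frame(
        subject_id = map$subject_id, fold = c("alpha", "beta", "gamma")[f],
        c_s = out$c_s, c_m = map$c_m, l_c = loss_rate(out$c_s, map$c_m),
        moves = out$moves, reached_optimal = out$reached_optimal,
        termination = out$termination_reason,
        conv_c_s = conv$c_s, conv_moves = conv$moves,
        stringsAsFactors = FALSE
      ))
    }
  }

  d_c <- cohens_d(trials$c_s, trials$conv_c_s)
  d_a <- cohens_d(trials$moves, trials$conv_moves)
  tp <- time_params()
  nonopt <- trials$l_c[!trials$reached_optimal]
  list(
    agents = agents,
    folds = lapply(1:3, function(f) groups[[test_groups[f]]]),
    trials = trials,
    outcome_table = summarize_outcomes(outcomes, trial_maps, move_threshold),
    d_c = d_c,
    d_a = d_a,
    mean_l_c = mean(trials$l_c),
    mean_l_c_nonoptimal = if (length(nonopt)) mean(nonopt) else 0,
    attainment_rate = mean(trials$reached_optimal),
    mean_moves = mean(trials$moves),
    mean_time_s = mean((trials$moves + 1) * tp$seconds_per_cell),
    conventional_time_s = mean((trials$conv_moves + 1) * tp$seconds_per_cell)
  )
}

# Parameter sweeps ---------------------------------------------------------

#' Sweep one tuning parameter through cross-validation
#'
#' Re-runs [cross_validate()] for each candidate value of the network depth
#' `D`, the stop-penalty slope `m_l`, or the start cell, and reports the
#' accuracy (`d_c`) and efficiency (`d_a`) effect sizes per value.
#'
#' @param cohort List of [confidence_map()]s.
#' @param param One of `"D"`, `"m_l"`, `"start"`.
#' @param values Vector of candidate values (for `"start"`, a list of
#'   `(x, y)` cells).
#' @param start Fixed start cell for the `D` / `m_l` sweeps.
#' @param rparams,net_config,tconfig Fixed settings for the non-swept
#'   parameters.
#' @return Data frame with one row per value: `value`, `d_c`, `d_a`,
#'   `attainment_rate`, `mean_moves`.
#' @export
sweep_parameter <- function(cohort, param = c("D", "m_l", "start"), values,
                            start = c(2L, 2L),
                            rparams = reward_params(),
                            net_config = q_network_config(),
                            tconfig = train_config()) {
  param <- match.arg(param)
  if (length(values) == 0L) stop("empty sweep grid")
  if (param != "start" && !is.list(values)) values <- as.list(values)
  rows <- lapply(seq_along(values), function(k) {
    v <- values[[k]]
    nc <- net_config
    rp <- rparams
    st <- start
    if (param == "D") nc$depth_d <- as.integer(v)
    if (param == "m_l") rp$m_l <- v
    if (param == "start") st <- as.integer(v)
    cv <- cross_validate(cohort, st, rp, nc, tconfig)
    data.frame(
      value = if (param == "start") paste(v, collapse = ",") else v,
      d_c = cv$d_c, d_a = cv$d_a,
      attainment_rate = cv$attainment_rate, mean_moves = cv$mean_moves,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Accuracy-first parameter selection
#'
#' Picks the sweep row with the smallest `d_c` (accuracy matters most in a
#' healthcare setting), breaking ties by the largest `d_a`.
#'
#' @param sweep Data frame from [sweep_parameter()].
#' @return The selected row.
#' @export
select_sweep_choice <- function(sweep) {
  stopifnot(nrow(sweep) >= 1L)
  best <- which(sweep$d_c == min(sweep$d_c))
  if (length(best) > 1L) best <- best[which.max(sweep$d_a[best])]
  sweep[best, , drop = FALSE]
}
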