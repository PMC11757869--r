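# Shared fixtures and independent mini-oracles used across test files.

# A 3x3 map with strictly positive confidences and the optimum at (2, 2).
# NB: matrices fill column-major, so each written triple is one Y column.
make_map_3x3 <- function() {
  confidence_map(
    matrix(c(0.20, 0.40, 0.30,
             0.35, 0.50, 0.45,
             0.30, 0.60, 0.90), 3, 3),
    subject_id = "fx3"
  )
}

# A 3x3 map with a zero start cell and a secondary ridge.
make_map_3x3_zero <- function() {
  confidence_map(
    matrix(c(0.00, 0.10, 0.20,
             0.00, 0.30, 0.40,
             0.05, 0.45, 0.80), 3, 3),
    subject_id = "fx3z"
  )
}

# Strict 8-neighbour local maxima of a confidence matrix (0-based cells),
# computed by exhaustive comparison - independent of package internals.
find_local_maxima <- function(c) {
  hits <- NULL
  for (i in seq_len(nrow(c))) {
    for (j in seq_len(ncol(c))) {
      if (c[i, j] <= 0) next
      nb <- c[max(1, i - 1):min(nrow(c), i + 1),
              max(1, j - 1):min(ncol(c), j + 1)]
      if (sum(nb >= c[i, j]) == 1L) hits <- rbind(hits, c(i - 1L, j - 1L))
    }
  }
  hits
}

# Independent Table-row reward oracle: sums the applicable reward rows for
# one executed action from first principles, without calling compute_reward.
oracle_reward <- function(action, c_before, c_after, out_of_range,
                          moves_before_stop, at_optimal, c_m,
                          m_l = 40, threshold = 35) {
  if (action == "STOP") {
    r <- -3.0
    if (at_optimal) {
      r <- r + 5.0
      if (moves_before_stop < threshold) r <- r + 20.0
    } else {
      r <- r - m_l * (c_m - c_after)
    }
    r
  } else {
    r <- -0.1
    if (out_of_range) r <- r - 0.3
    r + 10.0 * (c_after - c_before)
  }
}

# Confidence at a 0-based cell, read straight from the stored grid.
conf_at <- function(map, position) {
  map$c[position[1] + 1L, position[2] + 1L]
}

# Small default-parameter cohort reused by several test files (generation is
# cheap and deterministic).
fixture_cohort <- function(n = 6L, seed = 11L) {
  generate_cohort(map_gen_params(), n, seed)
}
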