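# Confidence-map domain types --------------------------------------------

#' Grid geometry of the chest search plane
#'
#' The probe moves on a rectangular grid anchored at the xiphoid process.
#' `n_x` counts cells along the body's vertical axis (X, increasing toward the
#' head) and `n_y` along the frontal axis (Y, increasing laterally). The
#' default 7 x 5 grid has the 35 cells a full serpentine scan covers in five
#' passes.
#'
#' @param n_x,n_y Positive integer cell counts.
#' @return A `grid_geometry` object.
#' @export
#' @examples
#' grid_geometry()          # 7 x 5 default
#' grid_geometry(3, 3)
grid_geometry <- function(n_x = 7L, n_y = 5L) {
  n_x <- as.integer(n_x)
  n_y <- as.integer(n_y)
  stopifnot(length(n_x) == 1L, length(n_y) == 1L, n_x >= 1L, n_y >= 1L)
  structure(list(n_x = n_x, n_y = n_y), class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d (%d cells)\n", x$n_x, x$n_y, x$n_x * x$n_y))
  invisible(x)
}

n_cells <- function(geometry) geometry$n_x * geometry$n_y

# TRUE iff 0-based cell (x, y) lies inside the grid.
in_grid <- function(position, geometry) {
  position[1] >= 0L && position[1] <= geometry$n_x - 1L &&
    position[2] >= 0L && position[2] <= geometry$n_y - 1L
}

# Confidence at a 0-based cell; `c` is stored as an n_x x n_y matrix.
cell_conf <- function(map, position) {
  map$c[position[1] + 1L, position[2] + 1L]
}

#' Construct a confidence map
#'
#' A confidence map stores, for one subject, the median object-detection
#' confidence of the target heart component at every probe grid cell. The
#' global maximum must be unique and positive: it defines the optimal probe
#' position and its confidence `c_m`.
#'
#' @param c Numeric matrix (`n_x` rows, `n_y` columns) of confidences in
#'   \[0, 1\]. Row i holds X index i - 1, column j holds Y index j - 1.
#' @param subject_id Opaque subject label.
#' @param geometry Optional [grid_geometry()]; defaults to the matrix shape.
#' @return A `confidence_map` with fields `subject_id`, `geometry`, `c`,
#'   `optimal_cell` (0-based `(x, y)` of the unique argmax) and `c_m`.
#' @export
#' @examples
#' m <- confidence_map(matrix(c(0.1, 0.5, 0.2, 0.9), 2, 2), "demo")
#' m$optimal_cell  # c(1, 1)
confidence_map <- function(c, subject_id = "subject", geometry = NULL) {
  stopifnot(is.matrix(c), is.numeric(c))
  if (is.null(geometry)) geometry <- grid_geometry(nrow(c), ncol(c))
  stopifnot(nrow(c) == geometry$n_x, ncol(c) == geometry$n_y)
  if (anyNA(c)) stop("confidence map contains NA values")
  if (any(c < 0) || any(c > 1)) {
    stop("confidence values must lie in [0, 1]")
  }
  c_m <- max(c)
  if (c_m <= 0) stop("degenerate map: all confidences are zero")
  top <- which(c == c_m)
  if (length(top) > 1L) {
    stop("tie at the global maximum: the optimal cell must be unique")
  }
  optimal_cell <- c((top - 1L) %% nrow(c), (top - 1L) %/% nrow(c))
  structure(
    list(
      subject_id = as.character(subject_id),
      geometry = geometry,
      c = unname(c),
      optimal_cell = as.integer(optimal_cell),
      c_m = c_m
    ),
    class = "confidence_map"
  )
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf(
    "<confidence_map> subject '%s', %d x %d grid, optimal cell (%d, %d), c_m = %.4f\n",
    x$subject_id, x$geometry$n_x, x$geometry$n_y,
    x$optimal_cell[1], x$optimal_cell[2], x$c_m
  ))
  invisible(x)
}

# Frame simulation --------------------------------------------------------

#' Simulate per-frame detection confidences at one probe position
#'
#' While the probe dwells in a cell the detector scores each acquired frame;
#' frame-to-frame variation is modelled as zero-centred Gaussian noise around
#' the cell's true confidence, clipped to \[0, 1\].
#'
#' @param true_c True cell confidence in \[0, 1\].
#' @param k Number of frames (>= 1).
#' @param noise Standard deviation of per-frame noise.
#' @param seed Integer seed; the draw is deterministic for a fixed seed.
#' @return Numeric vector of `k` confidences in \[0, 1\].
#' @export
#' @examples
#' sample_frames(0.5, 3, noise = 0, seed = 1)  # c(0.5, 0.5, 0.5)
sample_frames <- function(true_c, k, noise, seed) {
  stopifnot(length(true_c) == 1L, true_c >= 0, true_c <= 1, noise >= 0)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1: no frames to simulate")
  frames <- with_seed(seed, true_c + stats::rnorm(k, mean = 0, sd = noise))
  pmin(pmax(frames, 0), 1)
}

#' Aggregate frame confidences into one cell confidence
#'
#' The per-cell confidence is the median over frames, which suppresses
#' transient detector dropouts. Even-length inputs use the midpoint of the two
#' central order statistics.
#'
#' @param frames Non-empty numeric vector.
#' @return The median confidence.
#' @export
aggregate_frames <- function(frames) {
  if (length(frames) == 0L) stop("cannot aggregate an empty frame sequence")
  stats::median(frames)
}

# Synthetic generator -----------------------------------------------------

#' Parameters of the synthetic confidence-map generator
#'
#' The generator emulates the statistical structure of chest-surface
#' detection-confidence maps: a single cardiac confidence peak biased toward
#' the lower-left of the chest, periodic rib-shadow attenuation along the
#' vertical (X) axis that produces intermittent local maxima, a central
#' zero-confidence band where the sternum and lungs block imaging,
#' per-subject variation of the peak position, and per-frame detection noise
#' aggregated by the median.
#'
#' @param geometry A [grid_geometry()].
#' @param heart_center_mean Real `(x, y)` cell coordinates of the population
#'   mean peak position.
#' @param heart_center_spread Per-axis standard deviation of the subject's
#'   peak position.
#' @param peak_height Maximum confidence before attenuation, in (0, 1\].
#' @param peak_width Isotropic squared-exponential decay scale, in cells.
#' @param rib_period Cell spacing of shadowed rows along X (>= 2).
#' @param rib_attenuation Multiplicative factor in \[0, 1\] applied on
#'   shadowed rows (1 disables shadows).
#' @param dead_zone_columns Integer vector of 0-based Y columns forced to
#'   zero confidence (sternal/lung band).
#' @param noise_spread Per-cell additive noise standard deviation.
#' @param frames_per_cell Simulated detector frames per cell (k).
#' @param frame_noise_spread Per-frame noise standard deviation.
#' @param seed Integer seed; the generated map is a pure function of the
#'   parameters and this seed.
#' @return A `map_gen_params` list.
#' @export
map_gen_params <- function(geometry = grid_geometry(),
                           heart_center_mean = c(2, 3),
                           heart_center_spread = c(0.8, 0.6),
                           peak_height = 0.9,
                           peak_width = 1.6,
                           rib_period = 2L,
                           rib_attenuation = 0.4,
                           dead_zone_columns = 2L,
                           noise_spread = 0.02,
                           frames_per_cell = 5L,
                           frame_noise_spread = 0.05,
                           seed = 1L) {
  stopifnot(
    inherits(geometry, "grid_geometry"),
    length(heart_center_mean) == 2L,
    length(heart_center_spread) == 2L, all(heart_center_spread >= 0),
    peak_height > 0, peak_height <= 1,
    peak_width > 0,
    rib_period >= 2L,
    rib_attenuation >= 0, rib_attenuation <= 1,
    noise_spread >= 0, frame_noise_spread >= 0,
    frames_per_cell >= 1L
  )
  dead_zone_columns <- as.integer(dead_zone_columns)
  stopifnot(all(dead_zone_columns >= 0L), all(dead_zone_columns <= geometry$n_y - 1L))
  structure(
    list(
      geometry = geometry,
      heart_center_mean = as.numeric(heart_center_mean),
      heart_center_spread = as.numeric(heart_center_spread),
      peak_height = peak_height,
      peak_width = peak_width,
      rib_period = as.integer(rib_period),
      rib_attenuation = rib_attenuation,
      dead_zone_columns = dead_zone_columns,
      noise_spread = noise_spread,
      frames_per_cell = as.integer(frames_per_cell),
      frame_noise_spread = frame_noise_spread,
      seed = as.integer(seed)
    ),
    class = "map_gen_params"
  )
}

# Break exact ties at the global maximum by an infinitesimal deterministic
# bump on the lexicographically smallest tied cell (ties are forbidden in the
# data model). If the tied value already sits at 1, the other tied cells are
# nudged down instead so values stay in [0, 1].
break_argmax_ties <- function(c) {
  m <- max(c)
  if (m <= 0) return(c)
  idx <- which(c == m)
  if (length(idx) < 2L) return(c)
  # column-major linear order == lexicographic (Y, then X); convert to
  # lexicographic (X, then Y) order on 0-based (x, y)
  xy <- cbind((idx - 1L) %% nrow(c), (idx - 1L) %/% nrow(c))
  first <- idx[order(xy[, 1], xy[, 2])][1]
  eps <- max(m, .Machine$double.xmin) * .Machine$double.eps
  if (m + eps <= 1) {
    c[first] <- m + eps
  } else {
    others <- setdiff(idx, first)
    c[others] <- m - eps
  }
  c
}

#' Generate one synthetic confidence map
#'
#' Builds an isotropic squared-exponential confidence peak around a sampled
#' heart centre, attenuates rib-shadow rows, zeroes the sternal dead band,
#' then perturbs every remaining cell by simulating `frames_per_cell`
#' detector frames (plus per-cell noise) and taking their median. Output is
#' fully determined by `params$seed`.
#'
#' @param params A [map_gen_params()] object.
#' @return A [confidence_map()].
#' @export
#' @examples
#' m <- generate_map(map_gen_params(seed = 7))
#' m$c_m > 0
generate_map <- function(params) {
  stopifnot(inherits(params, "map_gen_params"))
  geom <- params$geometry
  seeds <- derive_seeds(params$seed, 3L)

  center <- with_seed(seeds[1], {
    params$heart_center_mean + stats::rnorm(2, 0, params$heart_center_spread)
  })
  rib_phase <- with_seed(seeds[2], sample.int(params$rib_period, 1L) - 1L)

  x <- 0:(geom$n_x - 1L)
  y <- 0:(geom$n_y - 1L)
  d2 <- outer((x - center[1])^2, (y - center[2])^2, `+`)
  surface <- params$peak_height * exp(-d2 / params$peak_width^2)

  shadowed <- (x %% params$rib_period) == rib_phase
  surface[shadowed, ] <- surface[shadowed, ] * params$rib_attenuation
  if (length(params$dead_zone_columns) > 0L) {
    surface[, params$dead_zone_columns + 1L] <- 0
  }

  # per-cell noise then per-frame simulation + median, on non-dead cells only
  cell_seeds <- with_seed(seeds[3], sample.int(.Machine$integer.max, length(surface) + 1L))
  cell_noise <- with_seed(cell_seeds[length(cell_seeds)], {
    stats::rnorm(length(surface), 0, params$noise_spread)
  })
  dead <- matrix(FALSE, geom$n_x, geom$n_y)
  if (length(params$dead_zone_columns) > 0L) dead[, params$dead_zone_columns + 1L] <- TRUE
  out <- surface
  for (i in seq_along(surface)) {
    if (dead[i]) {
      out[i] <- 0
      next
    }
    true_c <- min(1, max(0, surface[i] + cell_noise[i]))
    frames <- sample_frames(true_c, params$frames_per_cell,
                            params$frame_noise_spread, cell_seeds[i])
    out[i] <- aggregate_frames(frames)
  }
  out <- pmin(pmax(out, 0), 1)
  if (max(out) <= 0) {
    stop("degenerate map: peak fell entirely inside the dead zone; resample the seed")
  }
  out <- break_argmax_ties(out)
  confidence_map(out, subject_id = sprintf("seed%d", params$seed), geometry = geom)
}

#' Generate a cohort of synthetic subjects
#'
#' Each subject's map uses an independently derived sub-seed, so heart-centre
#' position and noise vary across subjects while the whole cohort stays a
#' pure function of `seed`. Degenerate maps (all-zero after the dead band)
#' are resampled with advanced sub-seeds up to a bounded retry budget.
#'
#' @param params A [map_gen_params()] template; its own `seed` is ignored.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Cohort-level integer seed.
#' @param max_retries Retry budget per subject for degenerate maps.
#' @return List of [confidence_map()] objects with unique `subject_id`s.
#' @export
generate_cohort <- function(params, n_subjects, seed, max_retries = 25L) {
  stopifnot(inherits(params, "map_gen_params"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  sub_seeds <- derive_seeds(seed, n_subjects)
  maps <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s <- sub_seeds[i]
    map <- NULL
    for (try in 0:max_retries) {
      p <- params
      p$seed <- as.integer((s + try) %% .Machine$integer.max)
      map <- tryCatch(generate_map(p), error = function(e) NULL)
      if (!is.null(map)) break
    }
    if (is.null(map)) {
      stop(sprintf("subject %d: map generation stayed degenerate after %d retries",
                   i, max_retries))
    }
    map$subject_id <- sprintf("S%02d", i)
    maps[[i]] <- map
  }
  maps
}
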