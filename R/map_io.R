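# Map file I/O ------------------------------------------------------------
#
# On-disk dialect: a CSV grid of decimal confidences (row = X index
# ascending, column = Y index ascending) plus a JSON sidecar holding the
# subject id, geometry and the stored optimal cell. Confidences are written
# with 17 significant digits, so the round trip is lossless for doubles.

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".json", path) else paste0(path, ".json")
}

#' Write a confidence map to CSV + JSON sidecar
#'
#' @param map A [confidence_map()].
#' @param path Destination CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "confidence_map"))
  # grid rows are X indices: transpose storage so each CSV line is one X row
  lines <- apply(map$c, 1, function(row) {
    paste(vapply(row, function(v) format(v, digits = 17, scientific = FALSE),
                 character(1)), collapse = ",")
  })
  writeLines(lines, path)
  meta <- list(
    subject_id = map$subject_id,
    n_x = map$geometry$n_x,
    n_y = map$geometry$n_y,
    optimal_cell = as.integer(map$optimal_cell),
    c_m = map$c_m
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a confidence map written by [write_map()]
#'
#' Confidences are validated against \[0, 1\], the global maximum must be
#' unique, and the recomputed optimal cell must match the one stored in the
#' sidecar.
#'
#' @param path CSV path written by [write_map()].
#' @return A [confidence_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  n_y <- length(rows[[1]])
  if (any(vapply(rows, length, integer(1)) != n_y)) {
    stop("ragged CSV grid: all rows must have the same number of columns")
  }
  c <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(c)) stop("non-numeric confidence value in ", path)
  if (any(c < 0) || any(c > 1)) {
    stop("confidence value outside [0, 1] in ", path)
  }
  if (sum(c == max(c)) > 1L) {
    stop("tie at the global maximum in ", path, ": optimal cell must be unique")
  }
  meta_path <- sidecar_path(path)
  subject_id <- "subject"
  stored_optimal <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    subject_id <- meta$subject_id
    stored_optimal <- as.integer(meta$optimal_cell)
  }
  map <- confidence_map(c, subject_id = subject_id)
  if (!is.null(stored_optimal) && !identical(map$optimal_cell, stored_optimal)) {
    stop("stored optimal cell disagrees with the recomputed argmax in ", meta_path)
  }
  map
}
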