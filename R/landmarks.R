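# Long-format landmark tibbles and their array form.
#
# The user-facing representation of a set of landmark configurations is a
# long tibble with columns (specimen, point, x, y): one row per digitized
# point, points ordered 1..k within each specimen. Internally the
# superimposition code works on an n x k x 2 array.

#' Validate a landmark tibble
#'
#' Checks that `landmarks` is a long table of 2D configurations: columns
#' `specimen`, `point`, `x`, `y`; every specimen has the same points
#' `1..k` with `k >= 3`; all coordinates finite (missing landmarks are a
#' hard error — the methods here assume complete configurations).
#'
#' @param landmarks A data frame with columns `specimen`, `point`, `x`, `y`.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_landmarks <- function(landmarks) {
  req <- c("specimen", "point", "x", "y")
  missing_cols <- setdiff(req, names(landmarks))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  landmarks <- tibble::as_tibble(landmarks)
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    bad <- unique(landmarks$specimen[!is.finite(landmarks$x) |
                                       !is.finite(landmarks$y)])
    abort(paste0("non-finite coordinates for specimen(s): ",
                 paste(bad, collapse = ", ")))
  }
  ks <- table(landmarks$specimen)
  if (length(unique(as.integer(ks))) > 1) {
    abort(paste0("specimens differ in landmark count: ",
                 paste(names(ks), as.integer(ks), sep = "=", collapse = ", ")))
  }
  k <- as.integer(ks[1])
  if (k < 3) abort("configurations need at least 3 landmarks")
  ok <- landmarks |>
    dplyr::group_by(.data$specimen) |>
    dplyr::summarise(ok = all(sort(.data$point) == seq_len(k)),
                     .groups = "drop")
  if (!all(ok$ok)) {
    abort(paste0("points must be 1..k within each specimen; offending: ",
                 paste(ok$specimen[!ok$ok], collapse = ", ")))
  }
  landmarks
}

# n x k x 2 array from a long landmark tibble; specimen order = order of
# first appearance, point order 1..k.
lm_to_array <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  ids <- unique(landmarks$specimen)
  k <- nrow(landmarks) / length(ids)
  landmarks <- dplyr::arrange(landmarks,
                              match(.data$specimen, ids), .data$point)
  arr <- array(NA_real_, dim = c(length(ids), k, 2),
               dimnames = list(ids, NULL, c("x", "y")))
  arr[, , 1] <- matrix(landmarks$x, nrow = length(ids), byrow = TRUE)
  arr[, , 2] <- matrix(landmarks$y, nrow = length(ids), byrow = TRUE)
  arr
}

array_to_lm <- function(arr) {
  ids <- dimnames(arr)[[1]] %||% paste0("specimen_", seq_len(dim(arr)[1]))
  k <- dim(arr)[2]
  tibble(
    specimen = rep(ids, each = k),
    point = rep(seq_len(k), times = dim(arr)[1]),
    x = as.vector(t(arr[, , 1, drop = TRUE])),
    y = as.vector(t(arr[, , 2, drop = TRUE]))
  )
}

# Flatten an n x k x 2 array to n x 2k (x1, y1, x2, y2, ...).
flatten_coords <- function(arr) {
  n <- dim(arr)[1]
  k <- dim(arr)[2]
  out <- matrix(NA_real_, n, 2 * k)
  out[, seq(1, 2 * k, by = 2)] <- arr[, , 1]
  out[, seq(2, 2 * k, by = 2)] <- arr[, , 2]
  rownames(out) <- dimnames(arr)[[1]]
  out
}

unflatten_coords <- function(mat) {
  k <- ncol(mat) / 2
  arr <- array(NA_real_, dim = c(nrow(mat), k, 2),
               dimnames = list(rownames(mat), NULL, c("x", "y")))
  arr[, , 1] <- mat[, seq(1, 2 * k, by = 2), drop = FALSE]
  arr[, , 2] <- mat[, seq(2, 2 * k, by = 2), drop = FALSE]
  arr
}

#' Centroid size of each configuration
#'
#' Centroid size is the square root of the summed squared distances of a
#' configuration's points from their centroid — the size measure removed by
#' the scaling step of Procrustes superimposition. A degenerate
#' configuration with all points identical has centroid size 0; callers
#' must treat 0 as unusable before scaling.
#'
#' @param landmarks A landmark tibble (see [validate_landmarks()]).
#' @return A tibble with one row per specimen: `specimen`, `csize`.
#' @export
#' @examples
#' sq <- tibble::tibble(specimen = "a", point = 1:4,
#'                      x = c(-1, 1, 1, -1), y = c(-1, -1, 1, 1))
#' centroid_size(sq) # sqrt(8)
centroid_size <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  landmarks |>
    dplyr::group_by(specimen = .data$specimen) |>
    dplyr::summarise(
      csize = sqrt(sum((.data$x - mean(.data$x))^2 +
                         (.data$y - mean(.data$y))^2)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$specimen, unique(landmarks$specimen)))
}

# centroid size of a single k x 2 matrix
csize_mat <- function(m) {
  sqrt(sum(scale(m, scale = FALSE)^2))
}

center_mat <- function(m) {
  sweep(m, 2, colMeans(m))
}
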