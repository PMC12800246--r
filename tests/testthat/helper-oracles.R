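# Independent oracles and small fixture generators used across tests.

# random landmark configuration tibble (one specimen)
random_config <- function(k, id = "sp1", lim = 3) {
  tibble::tibble(specimen = id, point = seq_len(k),
                 x = stats::runif(k, -lim, lim),
                 y = stats::runif(k, -lim, lim))
}

# random sample of n configurations: one base shape plus noise, so GPA is
# well conditioned
random_sample <- function(n, k, noise = 0.1, prefix = "sp") {
  base_x <- stats::runif(k, -2, 2)
  base_y <- stats::runif(k, -2, 2)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(specimen = sprintf("%s%03d", prefix, i),
                   point = seq_len(k),
                   x = base_x + stats::rnorm(k, sd = noise),
                   y = base_y + stats::rnorm(k, sd = noise))
  }))
}

# apply a random similarity transform (rotation, translation, positive
# scaling) independently to each specimen of a landmark tibble
random_similarity <- function(landmarks) {
  landmarks |>
    dplyr::group_by(specimen) |>
    dplyr::group_modify(function(d, key) {
      th <- stats::runif(1, 0, 2 * pi)
      s <- exp(stats::rnorm(1, 0, 0.5))
      tx <- stats::runif(1, -10, 10)
      ty <- stats::runif(1, -10, 10)
      x <- s * (cos(th) * d$x - sin(th) * d$y) + tx
      y <- s * (sin(th) * d$x + cos(th) * d$y) + ty
      tibble::tibble(point = d$point, x = x, y = y)
    }) |>
    dplyr::ungroup() |>
    dplyr::select(specimen, point, x, y)
}

# center and scale a k x 2 matrix to unit centroid size
normalize_shape <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# Grid-search oracle for the optimal rotation: residual distance of
# `moving` rotated onto `target`, minimized over a fine angle grid.
grid_search_residual <- function(moving, target, step = 1e-4) {
  angles <- seq(0, 2 * pi, by = step)
  best <- Inf
  for (th in angles) {
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    d <- sqrt(sum((moving %*% rot - target)^2))
    if (d < best) best <- d
  }
  best
}

# Brute-force convex hull area: find hull edges by testing, for every
# ordered point pair, whether all remaining points lie on one side; order
# the hull vertices around their centroid and apply the shoelace formula.
# Independent of the monotone-chain construction.
brute_force_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(NA_real_)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      side <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
      others <- side[-c(i, j)]
      if (all(others <= 1e-12) || all(others >= -1e-12)) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  hull <- pts[on_hull, , drop = FALSE]
  if (nrow(hull) < 3) return(0)
  ctr <- colMeans(hull)
  ord <- order(atan2(hull[, 2] - ctr[2], hull[, 1] - ctr[1]))
  hull <- hull[ord, , drop = FALSE]
  x <- hull[, 1]
  y <- hull[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Brute-force alternating-minimization GPA oracle: center and scale all
# configurations, then alternate {rotate each to the current mean by
# grid-refined angle search; recompute the normalized mean} until the
# mean stabilizes. Independent of the SVD-based implementation.
brute_force_gpa <- function(mats, n_outer = 200, tol = 1e-12) {
  mats <- lapply(mats, normalize_shape)
  consensus <- mats[[1]]
  best_angle <- function(m, target) {
    # coarse-to-fine grid search over rotation angle
    th_best <- 0
    width <- 2 * pi
    centre <- 0
    for (pass in 1:8) {
      angles <- seq(centre - width / 2, centre + width / 2,
                    length.out = 200)
      res <- vapply(angles, function(th) {
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        sum((m %*% rot - target)^2)
      }, numeric(1))
      th_best <- angles[which.min(res)]
      centre <- th_best
      width <- width / 50
    }
    th_best
  }
  for (it in seq_len(n_outer)) {
    mats <- lapply(mats, function(m) {
      th <- best_angle(m, consensus)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      m %*% rot
    })
    new_consensus <- normalize_shape(Reduce(`+`, mats) / length(mats))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }
  list(mats = mats, consensus = consensus)
}

# per-My rasterization oracle for range-through richness: sample ages on
# a fine grid, assign each to its interval under the older-boundary rule,
# count species present
raster_richness <- function(metadata, scale, step = 0.01) {
  vapply(seq_len(nrow(scale)), function(i) {
    sum(vapply(seq_len(nrow(metadata)), function(s) {
      ages <- seq(metadata$lad_ma[s], metadata$fad_ma[s], by = step)
      ages <- unique(c(ages, metadata$fad_ma[s]))
      idx <- paleodisp:::interval_index(ages, scale)
      any(idx == i, na.rm = TRUE)
    }, logical(1)))
  }, numeric(1))
}

# metadata table with valid vocabularies for n species
fake_metadata <- function(n, fad = NULL, lad = NULL) {
  fad <- fad %||% stats::runif(n, 320, 420)
  lad <- lad %||% pmax(fad - stats::runif(n, 0, 20), 298.9)
  tibble::tibble(
    species = sprintf("sp%03d", seq_len(n)),
    group = sample(sarc_groups(), n, replace = TRUE),
    habitat = sample(sarc_habitats(), n, replace = TRUE),
    palaeoenvironment = sample(c(sarc_palaeoenvironments(), NA), n,
                               replace = TRUE),
    locality = sample(c("Miguasha", "Gogo", "Bear Gulch"), n,
                      replace = TRUE),
    fad_ma = fad,
    lad_ma = lad,
    ontogeny = "adult"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
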