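# Generalized Procrustes analysis with iterative semi-landmark sliding.
#
# Conventions:
#  * rotations are proper (det = +1); reflections are never introduced,
#    since all reconstructions are digitized in the same orientation;
#  * every aligned configuration is centered at the origin with unit
#    centroid size;
#  * semi-landmarks slide along the chord between their curve neighbours
#    under the Procrustes-distance minimisation criterion (projection of
#    the deviation from the consensus onto the tangent), not bending
#    energy;
#  * the final aligned sample is rotated as a whole into a canonical
#    orientation (consensus principal axes, deterministic sign rule) so
#    the result is invariant to arbitrary similarity transforms of the
#    input configurations.

#' Optimal rotation of one shape onto another
#'
#' Least-squares proper rotation (determinant +1, no reflection) of
#' `moving` onto `target`, both `k x 2`, centered and typically unit
#' centroid size. Computed from the SVD of the 2x2 cross-product matrix.
#' A rank-0 cross-product (degenerate shapes) yields the identity with a
#' warning.
#'
#' @param moving,target `k x 2` coordinate matrices.
#' @return A list with `rotated` (`k x 2`), `angle` (radians,
#'   counter-clockwise), and `rotation` (the 2x2 matrix applied on the
#'   right).
#' @export
opa_rotate <- function(moving, target) {
  moving <- as.matrix(moving)
  target <- as.matrix(target)
  if (!all(dim(moving) == dim(target))) {
    abort("moving and target must have identical dimensions")
  }
  cp <- crossprod(moving, target)
  if (sum(cp^2) < 1e-300) {
    warn("degenerate (rank-0) cross-product; returning identity rotation")
    return(list(rotated = moving, angle = 0, rotation = diag(2)))
  }
  sv <- svd(cp)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  list(rotated = moving %*% rot,
       angle = atan2(rot[1, 2], rot[1, 1]),
       rotation = rot)
}

#' Procrustes distance between two configurations
#'
#' The square root of the minimal summed squared point-wise distance over
#' proper rotations, after centering and scaling both configurations to
#' unit centroid size. This is the metric under which semi-landmarks are
#' slid and GPA converges.
#'
#' @param a,b `k x 2` coordinate matrices with the same `k`.
#' @return A non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  a <- center_mat(as.matrix(a))
  b <- center_mat(as.matrix(b))
  sa <- csize_mat(a)
  sb <- csize_mat(b)
  if (sa == 0 || sb == 0) abort("degenerate configuration (centroid size 0)")
  a <- a / sa
  b <- b / sb
  fit <- opa_rotate(a, b)
  sqrt(sum((fit$rotated - b)^2))
}

#' Slide semi-landmarks toward the consensus along their tangents
#'
#' For each specimen and each semi-landmark `p` with curve neighbours
#' `(b, a)`, the tangent direction is the unit chord from `b` to `a` in
#' that specimen; `p` moves along the tangent by the projection of its
#' deviation from the consensus point, which minimises its squared
#' distance to the consensus along the tangent line (the
#' Procrustes-distance minimisation criterion). Fixed landmarks are
#' untouched. Coincident neighbours (zero-length tangent) leave the point
#' unslid with a warning. Callers re-center and re-scale afterwards.
#'
#' @param coords An `n x k x 2` array of current aligned coordinates.
#' @param consensus A `k x 2` consensus shape.
#' @param sliders A sliders tibble (`before`, `slider`, `after`).
#' @return The updated `n x k x 2` array.
#' @export
slide_semilandmarks <- function(coords, consensus, sliders) {
  if (nrow(sliders) == 0) return(coords)
  validate_sliders(sliders, dim(coords)[2])
  warned <- FALSE
  for (r in seq_len(nrow(sliders))) {
    b <- sliders$before[r]
    s <- sliders$slider[r]
    a <- sliders$after[r]
    u <- coords[, a, , drop = FALSE] - coords[, b, , drop = FALSE]
    u <- matrix(u, ncol = 2)
    len <- sqrt(rowSums(u^2))
    ok <- len > 1e-12
    if (!all(ok) && !warned) {
      warn("coincident slider neighbours; leaving affected point(s) unslid")
      warned <- TRUE
    }
    u[ok, ] <- u[ok, , drop = FALSE] / len[ok]
    dev <- cbind(consensus[s, 1] - coords[, s, 1],
                 consensus[s, 2] - coords[, s, 2])
    t_step <- rowSums(dev * u)
    t_step[!ok] <- 0
    coords[, s, 1] <- coords[, s, 1] + t_step * u[, 1]
    coords[, s, 2] <- coords[, s, 2] + t_step * u[, 2]
  }
  coords
}

#' Generalized Procrustes analysis
#'
#' Iteratively removes translation, scale and rotation from a sample of
#' 2D landmark configurations, optionally sliding semi-landmarks toward
#' the evolving consensus under the Procrustes-distance criterion, until
#' the consensus change (root summed squared difference) falls below
#' `tol` or `max_iter` is reached. The aligned sample is then rotated as
#' a whole into a canonical orientation (consensus major axis along x,
#' deterministic sign rule), so the output is invariant to arbitrary
#' per-specimen similarity transforms of the input.
#'
#' When sliders are given, semi-landmarks are slid for a fixed number of
#' passes (`slide_iter`, default 5), each pass interleaved with
#' re-centering, re-scaling and re-rotation; superimposition then
#' iterates to the consensus tolerance with the slid positions frozen.
#' The cap exists because iterated tangent sliding lets semi-landmarks
#' creep along the outline — an almost shape-neutral reparameterization
#' that moves consensus *coordinates* indefinitely while changing the
#' Procrustes fit negligibly; a handful of passes captures all of the
#' fit improvement.
#'
#' @param landmarks A landmark tibble (`specimen`, `point`, `x`, `y`)
#'   with at least two specimens sharing the same `k`.
#' @param sliders Optional sliders tibble; `NULL` for fixed landmarks
#'   only.
#' @param tol Convergence tolerance on the consensus change.
#' @param max_iter Maximum number of alignment iterations; on
#'   non-convergence the best state is returned with `converged = FALSE`
#'   and a warning.
#' @param slide_iter Number of semi-landmark sliding passes.
#' @return An object of class `gpa_fit`: aligned coordinates
#'   (`n x k x 2`, each configuration centered with unit centroid size),
#'   `consensus` (`k x 2` mean shape), `centroid_sizes` (original units),
#'   `n_iterations`, `converged`, `specimens`, and the sliders used.
#' @export
#' @examples
#' set.seed(1)
#' lms <- simulate_dataset(sim_truth(k_fixed = 6, k_semi = 0,
#'                                   n_per_group = c(Dipnoi = 5), seed = 1))
#' fit <- gpa(lms$landmarks)
#' glance(fit)
gpa <- function(landmarks, sliders = NULL, tol = 1e-8, max_iter = 100,
                slide_iter = 5) {
  arr <- lm_to_array(landmarks)
  n <- dim(arr)[1]
  k <- dim(arr)[2]
  if (n < 2) abort("GPA needs at least 2 configurations")
  if (!is.null(sliders) && nrow(sliders) > 0) {
    validate_sliders(sliders, k)
  } else {
    sliders <- NULL
  }
  csizes <- numeric(n)
  for (i in seq_len(n)) {
    m <- center_mat(arr[i, , ])
    csizes[i] <- csize_mat(arr[i, , ])
    if (csizes[i] == 0) {
      abort(paste0("degenerate configuration (centroid size 0): ",
                   dimnames(arr)[[1]][i]))
    }
    arr[i, , ] <- m / csizes[i]
  }
  consensus <- arr[1, , ]
  update_consensus <- function(arr) {
    nc <- apply(arr, c(2, 3), mean)
    nc <- center_mat(nc)
    nc / csize_mat(nc)
  }
  iter <- 0L
  if (!is.null(sliders)) {
    for (s in seq_len(slide_iter)) {
      iter <- iter + 1L
      for (i in seq_len(n)) {
        arr[i, , ] <- opa_rotate(arr[i, , ], consensus)$rotated
      }
      arr <- slide_semilandmarks(arr, consensus, sliders)
      for (i in seq_len(n)) {
        m <- center_mat(arr[i, , ])
        arr[i, , ] <- m / csize_mat(m)
        arr[i, , ] <- opa_rotate(arr[i, , ], consensus)$rotated
      }
      consensus <- update_consensus(arr)
    }
  }
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      arr[i, , ] <- opa_rotate(arr[i, , ], consensus)$rotated
    }
    new_consensus <- update_consensus(arr)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("GPA did not converge in ", max_iter,
                " iterations; returning best state"))
  }
  # Final pass against the converged reference, then canonical
  # orientation. The reported consensus is the arithmetic mean of the
  # aligned coordinates (the internal reference is its unit-size
  # rescaling).
  for (i in seq_len(n)) {
    arr[i, , ] <- opa_rotate(arr[i, , ], consensus)$rotated
  }
  consensus <- apply(arr, c(2, 3), mean)
  rot <- canonical_rotation(consensus)
  for (i in seq_len(n)) arr[i, , ] <- arr[i, , ] %*% rot
  consensus <- consensus %*% rot
  structure(
    list(coords = arr,
         consensus = consensus,
         centroid_sizes = setNames(csizes, dimnames(arr)[[1]]),
         n_iterations = iter,
         converged = converged,
         specimens = dimnames(arr)[[1]],
         sliders = sliders,
         tol = tol),
    class = "gpa_fit"
  )
}

# Rotation taking a centered shape to a canonical orientation: major
# principal axis along x, with the x- (then y-) third-moment sign rule
# resolving the 180-degree ambiguity. Deterministic for generic shapes.
canonical_rotation <- function(consensus) {
  sv <- svd(center_mat(consensus))
  v <- sv$v
  if (det(v) < 0) v[, 2] <- -v[, 2]
  rotated <- consensus %*% v
  sk_x <- sum(rotated[, 1]^3)
  sk_y <- sum(rotated[, 2]^3)
  flip <- if (abs(sk_x) > 1e-9) sk_x < 0 else sk_y < 0
  if (flip) v <- v %*% diag(c(-1, -1))
  v
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes analysis\n")
  cat("  specimens:  ", length(x$specimens), "\n", sep = "")
  cat("  landmarks:  ", dim(x$coords)[2],
      if (!is.null(x$sliders)) paste0(" (", nrow(x$sliders),
                                      " semi-landmarks slid)") else "",
      "\n", sep = "")
  cat("  iterations: ", x$n_iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  invisible(x)
}

#' Tidy an aligned sample
#'
#' @param x A `gpa_fit` object.
#' @param ... Unused.
#' @return A long tibble of aligned coordinates (`specimen`, `point`,
#'   `x`, `y`).
#' @method tidy gpa_fit
#' @export
tidy.gpa_fit <- function(x, ...) {
  array_to_lm(x$coords)
}

#' @rdname tidy.gpa_fit
#' @return For `glance()`: a one-row tibble with `n`, `k`,
#'   `n_semilandmarks`, `n_iterations`, `converged`, `mean_csize`.
#' @method glance gpa_fit
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble(
    n = length(x$specimens),
    k = dim(x$coords)[2],
    n_semilandmarks = if (is.null(x$sliders)) 0L else nrow(x$sliders),
    n_iterations = x$n_iterations,
    converged = x$converged,
    mean_csize = mean(x$centroid_sizes)
  )
}

#' Plot an aligned sample
#'
#' Scatter of all aligned landmarks with the consensus shape overlaid.
#'
#' @param object A `gpa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gpa_fit
#' @export
autoplot.gpa_fit <- function(object, ...) {
  pts <- tidy(object)
  cons <- tibble(point = seq_len(nrow(object$consensus)),
                 x = object$consensus[, 1], y = object$consensus[, 2])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "firebrick", size = 1.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (shape units)", y = "y (shape units)",
                  title = "Procrustes-aligned sample and consensus")
}

# Flattened (x1, y1, ..., xk, yk) aligned coordinates of a gpa_fit.
aligned_matrix <- function(fit) {
  flatten_coords(fit$coords)
}
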