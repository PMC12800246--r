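# Principal component analysis of aligned shape coordinates and
# morphospace construction.

#' Principal component analysis of an aligned sample
#'
#' Eigen-decomposition of the covariance (divisor `n - 1`) of the
#' flattened aligned coordinates `(x1, y1, ..., xk, yk)` about their
#' mean. Axes with numerically zero eigenvalues are truncated. Axis
#' signs are fixed deterministically by making the largest-magnitude
#' loading of each axis positive (PCA signs are otherwise arbitrary, so
#' comparisons to published morphospaces must stay sign-agnostic).
#'
#' By default the PCA runs on the Procrustes coordinates directly;
#' `tangent = TRUE` first projects the centered data orthogonally off the
#' consensus direction (orthogonal projection to the tangent space of
#' shape space at the consensus). For the small shape variation typical
#' of these data the two options are nearly indistinguishable; the switch
#' exists so that this can be checked.
#'
#' @param fit A [gpa()] result.
#' @param tangent Project to tangent space before the PCA?
#' @return An object of class `shape_pca` with elements `scores`
#'   (`n x m`), `eigenvalues`, `prop_variance`, `loadings` (`2k x m`),
#'   `mean_vector` (length `2k`), `specimens`.
#' @export
shape_pca <- function(fit, tangent = FALSE) {
  if (!inherits(fit, "gpa_fit")) abort("fit must be a gpa_fit (see gpa())")
  x <- aligned_matrix(fit)
  n <- nrow(x)
  if (n < 3) abort("PCA needs at least 3 specimens")
  mean_vector <- colMeans(x)
  xc <- sweep(x, 2, mean_vector)
  if (tangent) {
    cvec <- as.vector(t(fit$consensus))
    u <- cvec / sqrt(sum(cvec^2))
    xc <- xc - (xc %*% u) %*% t(u)
  }
  sv <- svd(xc)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig) * 1e-12
  eig <- eig[keep]
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                               nrow = sum(keep))
  # deterministic axis signs: largest-|loading| entry positive
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(loadings) <- colnames(scores)
  rownames(scores) <- fit$specimens
  structure(
    list(scores = scores,
         eigenvalues = eig,
         prop_variance = eig / sum(eig),
         loadings = loadings,
         mean_vector = mean_vector,
         specimens = fit$specimens,
         tangent = tangent),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA: ", length(x$specimens), " specimens, ",
      length(x$eigenvalues), " axes\n", sep = "")
  pv <- utils::head(x$prop_variance, 5)
  cat("  variance explained: ",
      paste0(sprintf("PC%d %.2f%%", seq_along(pv), 100 * pv),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a shape PCA
#'
#' @param x A `shape_pca` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble of scores, one row per specimen, columns
#'   `specimen`, `PC1`, `PC2`, ... `glance()`: one row with `n`,
#'   `n_axes`, `total_variance`, `pc1_prop`, `pc2_prop`.
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  dplyr::bind_cols(tibble(specimen = x$specimens),
                   tibble::as_tibble(x$scores))
}

#' @rdname tidy.shape_pca
#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(
    n = length(x$specimens),
    n_axes = length(x$eigenvalues),
    total_variance = sum(x$eigenvalues),
    pc1_prop = x$prop_variance[1],
    pc2_prop = if (length(x$prop_variance) > 1) x$prop_variance[2] else NA_real_
  )
}

#' Per-group point sets on a PC plane
#'
#' Returns the scatter data for a morphospace: specimen scores on a pair
#' of PC axes joined with a grouping label, plus each group's convex-hull
#' vertices (hulls only for groups with at least 3 specimens; a
#' single-specimen group is a single dot).
#'
#' @param ord A [shape_pca()] result.
#' @param groups Either a vector of labels (one per specimen, in specimen
#'   order) or a data frame with columns `species` and the grouping
#'   column named by `group_col`.
#' @param axes Integer pair of PC indices, default `c(1, 2)`.
#' @param group_col Column of `groups` to use when it is a data frame.
#' @return A list with tibbles `points` (`specimen`, `group`, `x`, `y`)
#'   and `hulls` (`group`, `x`, `y`, hull vertices in order).
#' @export
morphospace <- function(ord, groups, axes = c(1, 2), group_col = "group") {
  if (!inherits(ord, "shape_pca")) abort("ord must be a shape_pca")
  if (any(axes < 1) || any(axes > ncol(ord$scores))) {
    abort(paste0("axes must be within 1..", ncol(ord$scores)))
  }
  labels <- resolve_groups(groups, ord$specimens, group_col)
  pts <- tibble(
    specimen = ord$specimens,
    group = labels,
    x = ord$scores[, axes[1]],
    y = ord$scores[, axes[2]]
  )
  hulls <- pts |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) return(d[0, c("x", "y")])
      h <- convex_hull(cbind(d$x, d$y))
      tibble(x = h[, 1], y = h[, 2])
    }) |>
    dplyr::ungroup()
  list(points = pts, hulls = hulls)
}

# groups: vector in specimen order, or data frame keyed by species.
resolve_groups <- function(groups, specimens, group_col = "group") {
  if (is.data.frame(groups)) {
    if (!all(c("species", group_col) %in% names(groups))) {
      abort(paste0("grouping data frame needs columns 'species' and '",
                   group_col, "'"))
    }
    missing <- setdiff(specimens, groups$species)
    if (length(missing) > 0) {
      abort(paste0("no metadata for specimen(s): ",
                   paste(missing, collapse = ", ")))
    }
    groups[[group_col]][match(specimens, groups$species)]
  } else {
    if (length(groups) != length(specimens)) {
      abort("groups must have one label per specimen")
    }
    groups
  }
}

#' Plot a morphospace
#'
#' Scatter of PC scores coloured by group with per-group convex hulls
#' (groups of one or two specimens are shown as points only).
#'
#' @param object A `shape_pca`.
#' @param groups,axes,group_col Passed to [morphospace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, groups = NULL, axes = c(1, 2),
                               group_col = "group", ...) {
  if (is.null(groups)) groups <- rep("all", length(object$specimens))
  ms <- morphospace(object, groups, axes = axes, group_col = group_col)
  pv <- 100 * object$prop_variance[axes]
  ggplot2::ggplot(ms$points,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$group)) +
    ggplot2::geom_polygon(data = ms$hulls,
                          ggplot2::aes(fill = .data$group),
                          alpha = 0.15, show.legend = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC%d (%.2f%%)", axes[1], pv[1]),
      y = sprintf("PC%d (%.2f%%)", axes[2], pv[2]),
      colour = "group"
    )
}
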