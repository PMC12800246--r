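# Group-wise disparity statistics: Procrustes variance with permutation
# pairwise tests, convex-hull morphospace occupation, the
# variance-weighted multi-PC hull area, and sum of variances.
#
# Conventions: the group Procrustes variance uses divisor n (the
# group-wise disparity convention under which the published values of
# this kind are reproducible); per-axis score variances use divisor
# n - 1. Each function documents its own divisor so they are never
# silently mixed.

#' Group-wise Procrustes variance
#'
#' For each group, the mean squared Procrustes deviation of its members
#' from the group mean shape: the sum over members of squared Euclidean
#' distance (flattened aligned coordinates) from the group mean, divided
#' by the group size `n` (set `unbiased = TRUE` for `n - 1`). The
#' groups' primary disparity statistic; a group of identical shapes has
#' variance 0, a singleton group has variance 0 by construction but is
#' still reported with its `n` so downstream code can treat it as
#' undefined where appropriate.
#'
#' @param x A [gpa()] result, or a numeric matrix of flattened
#'   coordinates (rows = specimens).
#' @param groups Group label per specimen (vector, or data frame with
#'   `species` + grouping column; see [morphospace()]).
#' @param unbiased Use divisor `n - 1` instead of the default `n`.
#' @param group_col Column name when `groups` is a data frame.
#' @return A tibble with columns `group`, `n`, `pv` and `share`
#'   (`pv / sum(pv)`).
#' @export
procrustes_variance <- function(x, groups, unbiased = FALSE,
                                group_col = "group") {
  mat <- coords_matrix(x)
  labels <- resolve_groups(groups, rownames(mat) %||%
                             as.character(seq_len(nrow(mat))), group_col)
  if (length(labels) != nrow(mat)) {
    abort("groups must have one label per specimen")
  }
  keep <- !is.na(labels)
  if (!all(keep)) {
    inform(paste0("dropping ", sum(!keep),
                  " specimen(s) with missing group label"))
  }
  pv <- pv_by_group(mat[keep, , drop = FALSE], labels[keep],
                    unbiased = unbiased)
  out <- tibble(group = names(pv),
                n = as.integer(table(labels[keep])[names(pv)]),
                pv = unname(pv))
  out$share <- out$pv / sum(out$pv)
  out
}

# fast path: named vector of per-group PV (divisor n by default)
pv_by_group <- function(mat, labels, unbiased = FALSE) {
  labels <- as.character(labels)
  ug <- unique(labels)
  pv <- setNames(numeric(length(ug)), ug)
  for (g in ug) {
    rows <- which(labels == g)
    xg <- mat[rows, , drop = FALSE]
    ctr <- colMeans(xg)
    ss <- sum(sweep(xg, 2, ctr)^2)
    div <- if (unbiased) max(length(rows) - 1, 1) else length(rows)
    pv[g] <- ss / div
  }
  pv
}

coords_matrix <- function(x) {
  if (inherits(x, "gpa_fit")) return(aligned_matrix(x))
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && all(c("specimen", "point", "x", "y") %in%
                                names(x))) {
    return(flatten_coords(lm_to_array(x)))
  }
  abort("x must be a gpa_fit, a coordinate matrix, or a landmark tibble")
}

#' Pairwise permutation test on Procrustes variances
#'
#' Observed statistic per pair of groups: the absolute difference of
#' their Procrustes variances. The null distribution is built by
#' randomly permuting group labels across all specimens `n_perm` times
#' and recomputing all pairwise statistics; `p = (count of permuted
#' statistics >= observed + 1) / (n_perm + 1)`. The p-value matrix is
#' symmetric with unit diagonal; groups of 1 specimen take part in the
#' permutations but their comparisons are reported with `p = NA`.
#'
#' @inheritParams procrustes_variance
#' @param n_perm Number of permutations (default 999; fewer than 99
#'   draws a resolution warning).
#' @param seed Integer seed; mandatory for reproducible runs.
#' @return An object of class `pv_test` with the observed `pv` tibble,
#'   symmetric matrices `abs_diff` and `p_value`, `n_perm` and `seed`.
#'   Use [tidy.pv_test()] for a long tibble.
#' @export
pairwise_pv_test <- function(x, groups, n_perm = 999, seed = NULL,
                             group_col = "group") {
  if (n_perm < 99) {
    warn("fewer than 99 permutations gives poor p-value resolution")
  }
  mat <- coords_matrix(x)
  labels <- resolve_groups(groups, rownames(mat) %||%
                             as.character(seq_len(nrow(mat))), group_col)
  keep <- !is.na(labels)
  mat <- mat[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  ug <- sort(unique(labels))
  if (length(ug) < 2) abort("need at least 2 groups to compare")
  obs <- pv_by_group(mat, labels)[ug]
  n_g <- table(labels)[ug]
  ngrp <- length(ug)
  abs_diff <- abs(outer(obs, obs, `-`))
  exceed <- matrix(0, ngrp, ngrp, dimnames = dimnames(abs_diff))
  run_perms <- function() {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      pvp <- pv_by_group(mat, perm)[ug]
      stat <- abs(outer(pvp, pvp, `-`))
      exceed <<- exceed + (stat >= abs_diff)
    }
  }
  if (!is.null(seed)) withr::with_seed(seed, run_perms()) else run_perms()
  p <- (exceed + 1) / (n_perm + 1)
  diag(p) <- 1
  singleton <- names(n_g)[n_g < 2]
  p[singleton, ] <- NA_real_
  p[, singleton] <- NA_real_
  diag(p) <- ifelse(ug %in% singleton, NA_real_, 1)
  structure(
    list(pv = tibble(group = ug, n = as.integer(n_g), pv = unname(obs)),
         abs_diff = abs_diff,
         p_value = p,
         n_perm = n_perm,
         seed = seed),
    class = "pv_test"
  )
}

#' @export
print.pv_test <- function(x, ...) {
  cat("Pairwise Procrustes-variance permutation test (",
      x$n_perm, " permutations)\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a pairwise Procrustes-variance test
#'
#' @param x A `pv_test` object.
#' @param ... Unused.
#' @return One row per unordered pair: `group1`, `group2`, `abs_diff`,
#'   `p_value`.
#' @method tidy pv_test
#' @export
tidy.pv_test <- function(x, ...) {
  ug <- x$pv$group
  pairs <- utils::combn(seq_along(ug), 2)
  tibble(
    group1 = ug[pairs[1, ]],
    group2 = ug[pairs[2, ]],
    abs_diff = x$abs_diff[cbind(pairs[1, ], pairs[2, ])],
    p_value = x$p_value[cbind(pairs[1, ], pairs[2, ])]
  )
}

#' Convex hull of a 2D point set
#'
#' Andrew's monotone-chain construction. Returns the hull vertices in
#' counter-clockwise order (without repeating the first vertex).
#'
#' @param points A two-column matrix or data frame of coordinates.
#' @return A matrix of hull vertices.
#' @export
convex_hull <- function(points) {
  pts <- unique(as.matrix(points))
  if (ncol(pts) != 2) abort("points must have two columns")
  if (nrow(pts) == 1) return(pts)
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    hull <- integer(0)
    for (i in idx) {
      while (length(hull) >= 2 &&
               cross(pts[hull[length(hull) - 1], ],
                     pts[hull[length(hull)], ], pts[i, ]) <= 0) {
        hull <- hull[-length(hull)]
      }
      hull <- c(hull, i)
    }
    hull
  }
  lower <- build(seq_len(nrow(pts)))
  upper <- build(rev(seq_len(nrow(pts))))
  pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
}

#' Area of the convex hull of a 2D point set
#'
#' Monotone-chain hull plus the shoelace formula over the hull vertices;
#' the morphospace-occupation statistic. Collinear input has area 0.
#' Fewer than 3 points leaves the area undefined (`NA`), matching the
#' rule that hull occupation cannot be estimated for groups with two
#' species or less.
#'
#' @param points A two-column matrix or data frame of coordinates.
#' @return A non-negative number, or `NA_real_` for fewer than 3 points.
#' @export
#' @examples
#' convex_hull_area(cbind(c(0, 2, 0), c(0, 0, 2))) # 2
convex_hull_area <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3) return(NA_real_)
  h <- convex_hull(pts)
  if (nrow(h) < 3) return(0)
  x <- h[, 1]
  y <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Per-group convex-hull areas on a PC plane
#'
#' @param ord A [shape_pca()] result.
#' @param groups Group labels (vector or data frame; see
#'   [morphospace()]).
#' @param axes PC plane, default `c(1, 2)`.
#' @param group_col Column name when `groups` is a data frame.
#' @return A tibble `group`, `n`, `hull_area` (`NA` when `n < 3`).
#' @export
hull_areas <- function(ord, groups, axes = c(1, 2), group_col = "group") {
  if (!inherits(ord, "shape_pca")) abort("ord must be a shape_pca")
  labels <- resolve_groups(groups, ord$specimens, group_col)
  sc <- ord$scores[, axes, drop = FALSE]
  tibble(group = labels, x = sc[, 1], y = sc[, 2]) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      hull_area = if (dplyr::n() >= 3) {
        convex_hull_area(cbind(.data$x, .data$y))
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Variance-weighted hull area over the first PCs
#'
#' For every unordered pair of axes `(i, j)` with `i < j <= n_pcs`, the
#' group's convex-hull area on that plane is weighted by the combined
#' proportion of variance the two axes explain, and the weighted areas
#' are summed. The raw weighted sum is reported by default; with
#' `normalize = TRUE` the result is divided by the sum of the pair
#' weights (a weighted average over planes).
#'
#' @inheritParams hull_areas
#' @param n_pcs Number of leading PCs (default 5, i.e. 10 planes).
#' @param normalize Divide by the sum of pair weights?
#' @return A tibble `group`, `n`, `weighted_hull_area` (`NA` when
#'   `n < 3`).
#' @export
weighted_hull_area <- function(ord, groups, n_pcs = 5, normalize = FALSE,
                               group_col = "group") {
  if (!inherits(ord, "shape_pca")) abort("ord must be a shape_pca")
  n_pcs <- min(n_pcs, ncol(ord$scores))
  if (n_pcs < 2) abort("need at least 2 PCs for a weighted hull area")
  labels <- resolve_groups(groups, ord$specimens, group_col)
  pairs <- utils::combn(n_pcs, 2)
  weights <- ord$prop_variance[pairs[1, ]] + ord$prop_variance[pairs[2, ]]
  ug <- unique(labels[!is.na(labels)])
  res <- purrr::map_dfr(ug, function(g) {
    rows <- which(!is.na(labels) & labels == g)
    if (length(rows) < 3) {
      return(tibble(group = g, n = length(rows),
                    weighted_hull_area = NA_real_))
    }
    areas <- vapply(seq_len(ncol(pairs)), function(p) {
      convex_hull_area(ord$scores[rows, pairs[, p], drop = FALSE])
    }, numeric(1))
    total <- sum(areas * weights)
    if (normalize) total <- total / sum(weights)
    tibble(group = g, n = length(rows), weighted_hull_area = total)
  })
  dplyr::arrange(res, .data$group)
}

#' Sum of per-axis score variances
#'
#' Disparity of a subset of specimens as the sum over PC axes of the
#' per-axis variance of their scores (divisor `n - 1`). Applied to the
#' full sample this equals the sum of the PCA eigenvalues; applied to a
#' time bin's members it is the bin's disparity. Undefined (`NA`) for
#' fewer than 2 specimens.
#'
#' @param scores A numeric matrix of PC scores (rows = specimens), or a
#'   `shape_pca` from which all scores are taken.
#' @return A non-negative number, or `NA_real_` when `n < 2`.
#' @export
sum_of_variances <- function(scores) {
  if (inherits(scores, "shape_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) return(NA_real_)
  sum(apply(scores, 2, stats::var))
}

#' Full disparity table for one grouping variable
#'
#' Combines per-group Procrustes variance and disparity shares,
#' PC-plane and variance-weighted hull areas, and the pairwise
#' permutation test into one object.
#'
#' @param fit A [gpa()] result.
#' @param ord The matching [shape_pca()].
#' @param groups Group labels (vector or data frame).
#' @param axes PC plane for the headline hull area.
#' @param n_pcs PCs for the weighted hull area.
#' @param n_perm,seed Permutation settings (see [pairwise_pv_test()]).
#' @param group_col Column name when `groups` is a data frame.
#' @return An object of class `disparity_table`; `tidy()` gives the
#'   per-group table, `glance()` the settings, and the `pairwise`
#'   element holds the `pv_test`.
#' @export
disparity_table <- function(fit, ord, groups, axes = c(1, 2), n_pcs = 5,
                            n_perm = 999, seed = NULL,
                            group_col = "group") {
  pv <- procrustes_variance(fit, groups, group_col = group_col)
  hulls <- hull_areas(ord, groups, axes = axes, group_col = group_col)
  wha <- weighted_hull_area(ord, groups, n_pcs = n_pcs,
                            group_col = group_col)
  pw <- pairwise_pv_test(fit, groups, n_perm = n_perm, seed = seed,
                         group_col = group_col)
  per_group <- pv |>
    dplyr::left_join(hulls[, c("group", "hull_area")], by = "group") |>
    dplyr::left_join(wha[, c("group", "weighted_hull_area")], by = "group")
  structure(
    list(per_group = per_group,
         pairwise = pw,
         axes = axes,
         n_pcs = n_pcs,
         n_perm = n_perm,
         seed = seed),
    class = "disparity_table"
  )
}

#' @export
print.disparity_table <- function(x, ...) {
  cat("Disparity table (hull plane PC", x$axes[1], "-PC", x$axes[2],
      ", ", x$n_perm, " permutations)\n", sep = "")
  print(x$per_group, ...)
  invisible(x)
}

#' Tidy a disparity table
#'
#' @param x A `disparity_table`.
#' @param ... Unused.
#' @return `tidy()`: per-group tibble (`group`, `n`, `pv`, `share`,
#'   `hull_area`, `weighted_hull_area`). `glance()`: settings row.
#' @method tidy disparity_table
#' @export
tidy.disparity_table <- function(x, ...) x$per_group

#' @rdname tidy.disparity_table
#' @method glance disparity_table
#' @export
glance.disparity_table <- function(x, ...) {
  tibble(n_groups = nrow(x$per_group), axes = paste(x$axes, collapse = "-"),
         n_pcs = x$n_pcs, n_perm = x$n_perm,
         seed = x$seed %||% NA_integer_)
}

#' Plot the disparity shares of a disparity table
#'
#' Bar chart of each group's share of the summed Procrustes variances
#' (the quantity shown as pie charts in disparity studies).
#'
#' @param object A `disparity_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disparity_table
#' @export
autoplot.disparity_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$group,
                                                     -.data$share),
                                  y = 100 * .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "share of total disparity (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
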