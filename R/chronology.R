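# Geological time handling: equal-width bins, interval assignment by
# first occurrence, range-through richness, and disparity-through-time
# curves.
#
# Age convention: ages are in Ma and decrease toward the present;
# start_ma is the older edge of an interval. An age lying exactly on a
# shared boundary belongs to the OLDER interval (consistent with
# first-appearance semantics); the oldest interval is closed at its old
# edge.

#' Divide a time span into equal-width bins
#'
#' @param start_ma Older edge of the span (Ma).
#' @param end_ma Younger edge of the span (Ma); must be `< start_ma`.
#' @param n_bins Number of bins (`>= 1`).
#' @return A timescale tibble (`interval`, `start_ma`, `end_ma`) of
#'   `n_bins` contiguous bins of width `(start_ma - end_ma) / n_bins`,
#'   ordered old to young.
#' @export
#' @examples
#' equal_bins(425.6, 298.9, 7) # seven bins of 18.1 My
equal_bins <- function(start_ma, end_ma, n_bins) {
  if (!(start_ma > end_ma)) abort("start_ma must be greater than end_ma")
  if (n_bins < 1) abort("n_bins must be at least 1")
  width <- (start_ma - end_ma) / n_bins
  starts <- start_ma - (seq_len(n_bins) - 1) * width
  ends <- c(starts[-1], end_ma)
  tibble(
    interval = sprintf("bin_%02d", seq_len(n_bins)),
    start_ma = starts,
    end_ma = ends
  )
}

# Index of the interval containing each age, or NA when outside the
# scale. Boundary ages go to the older interval; the oldest interval is
# closed at its old edge.
interval_index <- function(ages, scale) {
  vapply(ages, function(a) {
    hit <- which((a < scale$start_ma |
                    (seq_len(nrow(scale)) == 1 & a <= scale$start_ma)) &
                   a >= scale$end_ma)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

#' Assign species to time intervals by first occurrence
#'
#' Each species is assigned to the interval containing its first
#' occurrence age (`fad_ma`) — its interval of appearance — even when
#' its stratigraphic range spans several intervals. A first occurrence
#' exactly on a boundary goes to the older interval.
#'
#' @param metadata A metadata tibble (needs `species`, `fad_ma`).
#' @param scale A timescale tibble (`interval`, `start_ma`, `end_ma`).
#' @return The input with an added `interval` column.
#' @export
assign_interval <- function(metadata, scale) {
  scale <- validate_timescale(scale)
  idx <- interval_index(metadata$fad_ma, scale)
  if (anyNA(idx)) {
    abort(paste0("first occurrence outside the time scale for species: ",
                 paste(metadata$species[is.na(idx)], collapse = ", ")))
  }
  metadata$interval <- scale$interval[idx]
  metadata
}

#' Range-through richness per interval
#'
#' Counts, for each interval, the species whose stratigraphic range
#' `[lad_ma, fad_ma]` overlaps it, assuming presence throughout the
#' range. A range endpoint touching a shared boundary counts as presence
#' in the older interval only, matching the boundary convention of
#' [assign_interval()].
#'
#' @inheritParams assign_interval
#' @return A tibble `interval`, `start_ma`, `end_ma`, `richness`.
#' @export
range_through_richness <- function(metadata, scale) {
  scale <- validate_timescale(scale)
  n_int <- nrow(scale)
  richness <- integer(n_int)
  for (i in seq_len(n_int)) {
    # species present in interval i: some age in [lad, fad] belongs to it
    present <- (metadata$lad_ma < scale$start_ma[i] |
                  (i == 1 & metadata$lad_ma <= scale$start_ma[i])) &
      metadata$fad_ma >= scale$end_ma[i]
    richness[i] <- sum(present)
  }
  dplyr::bind_cols(scale, tibble(richness = richness))
}

#' Disparity through time
#'
#' Groups specimens by their interval of appearance (see
#' [assign_interval()]) and computes a disparity metric per interval:
#' either the Procrustes variance of the interval's members (on aligned
#' coordinates, divisor `n`) or the sum of per-axis variances of their
#' PC scores (divisor `n - 1`). Intervals with fewer than 2 species get
#' `NA` — the variance of a single specimen is undefined, and plotting a
#' zero would fabricate signal.
#'
#' @param fit A [gpa()] result.
#' @param ord The matching [shape_pca()]; only needed for
#'   `metric = "sum_of_variances"`.
#' @param metadata Metadata covering every specimen in `fit` (matched by
#'   `species`).
#' @param scale A timescale tibble, e.g. [sarcopterygian_epochs()] or
#'   [equal_bins()].
#' @param metric `"procrustes_variance"` or `"sum_of_variances"`.
#' @return A tibble `interval`, `start_ma`, `end_ma`, `mid_ma`, `n`,
#'   `metric`, `disparity` (one row per interval, old to young).
#' @export
disparity_through_time <- function(fit, ord = NULL, metadata, scale,
                                   metric = c("procrustes_variance",
                                              "sum_of_variances")) {
  metric <- match.arg(metric)
  scale <- validate_timescale(scale)
  missing <- setdiff(fit$specimens, metadata$species)
  if (length(missing) > 0) {
    abort(paste0("no metadata for specimen(s): ",
                 paste(missing, collapse = ", ")))
  }
  meta <- metadata[match(fit$specimens, metadata$species), ]
  meta <- assign_interval(meta, scale)
  if (metric == "sum_of_variances") {
    if (is.null(ord)) abort("sum_of_variances needs the ordination (ord)")
    mat <- ord$scores
  } else {
    mat <- aligned_matrix(fit)
  }
  per <- purrr::map_dfr(seq_len(nrow(scale)), function(i) {
    rows <- which(meta$interval == scale$interval[i])
    disp <- if (length(rows) < 2) {
      NA_real_
    } else if (metric == "procrustes_variance") {
      unname(pv_by_group(mat[rows, , drop = FALSE],
                         rep("g", length(rows))))
    } else {
      sum_of_variances(mat[rows, , drop = FALSE])
    }
    tibble(interval = scale$interval[i],
           start_ma = scale$start_ma[i],
           end_ma = scale$end_ma[i],
           mid_ma = (scale$start_ma[i] + scale$end_ma[i]) / 2,
           n = length(rows),
           metric = metric,
           disparity = disp)
  })
  per
}

#' Plot a disparity-through-time or richness curve
#'
#' Time runs old to young (age axis reversed). Intervals with undefined
#' disparity are left blank.
#'
#' @param curve A tibble from [disparity_through_time()] (column
#'   `disparity`) or [range_through_richness()] (column `richness`).
#' @return A ggplot object.
#' @export
plot_through_time <- function(curve) {
  value_col <- if ("disparity" %in% names(curve)) "disparity" else "richness"
  if (!"mid_ma" %in% names(curve)) {
    curve$mid_ma <- (curve$start_ma + curve$end_ma) / 2
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$mid_ma,
                                      y = .data[[value_col]])) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Ma)", y = value_col)
}
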