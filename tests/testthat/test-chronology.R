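# Time binning, interval assignment, richness and
# disparity-through-time.

test_that("equal bins reproduce the study span arithmetic and tile", {
  bins <- equal_bins(425.6, 298.9, 7)
  expect_equal(nrow(bins), 7)
  expect_equal(bins$start_ma - bins$end_ma, rep(18.1, 7),
               tolerance = 1e-9)
  expect_equal(bins$start_ma[1], 425.6)
  expect_equal(bins$end_ma[7], 298.9)

  five <- equal_bins(10, 0, 5)
  expect_equal(five$start_ma - five$end_ma, rep(2, 5))

  withr::local_seed(71)
  for (i in 1:100) {
    s <- stats::runif(1, 50, 500)
    e <- s - stats::runif(1, 1, 200)
    nb <- sample(1:12, 1)
    b <- equal_bins(s, e, nb)
    # contiguous tiling: each bin starts where the previous ended
    expect_equal(b$start_ma[-1], b$end_ma[-nb], tolerance = 1e-9)
    expect_equal(b$start_ma[1], s)
    expect_equal(b$end_ma[nb], e)
  }
  expect_error(equal_bins(10, 10, 2), "greater")
})

test_that("species are assigned to their interval of appearance", {
  epochs <- sarcopterygian_epochs()
  # Famennian FAD (within the Upper Devonian), Tournaisian LAD: the
  # species spans the Devonian-Carboniferous boundary but is classified
  # by appearance
  md <- fake_metadata(1, fad = 365, lad = 350)
  out <- assign_interval(md, epochs)
  expect_equal(out$interval, "Upper Devonian")

  # FAD exactly on a boundary goes to the older interval
  md2 <- fake_metadata(1, fad = 358.9, lad = 350)
  expect_equal(assign_interval(md2, epochs)$interval, "Upper Devonian")
  # and the oldest interval is closed at its old edge
  md3 <- fake_metadata(1, fad = 425.6, lad = 425)
  expect_equal(assign_interval(md3, epochs)$interval, "Ludlow")

  # deterministic across repeated calls
  expect_identical(assign_interval(md, epochs), assign_interval(md, epochs))
  # FAD outside the scale errors with the species named
  md4 <- fake_metadata(1, fad = 500, lad = 400)
  expect_error(assign_interval(md4, epochs), "sp001")
})

test_that("range-through richness counts intersecting ranges", {
  stages <- sarcopterygian_stages()
  # one species spanning the whole scale is present everywhere
  md <- fake_metadata(1, fad = 425.6, lad = 298.9)
  rc <- range_through_richness(md, stages)
  expect_equal(rc$richness, rep(1, nrow(stages)))
  # a species confined within one stage is counted exactly once
  md2 <- fake_metadata(1, fad = 380, lad = 379)
  rc2 <- range_through_richness(md2, stages)
  expect_equal(sum(rc2$richness), 1)
  expect_equal(rc2$interval[rc2$richness == 1], "Frasnian")
})

test_that("richness equals a per-My rasterization oracle", {
  withr::local_seed(72)
  stages <- sarcopterygian_stages()
  md <- fake_metadata(50, fad = stats::runif(50, 300, 425.6))
  md$lad_ma <- pmax(md$fad_ma - stats::runif(50, 0, 40), 298.9)
  rc <- range_through_richness(md, stages)
  expect_equal(rc$richness, raster_richness(md, stages),
               ignore_attr = TRUE)
})

test_that("adding a species never decreases richness", {
  withr::local_seed(73)
  stages <- sarcopterygian_stages()
  md <- fake_metadata(20, fad = stats::runif(20, 310, 420))
  base <- range_through_richness(md, stages)$richness
  for (i in 1:10) {
    extra <- fake_metadata(1, fad = stats::runif(1, 300, 425))
    extra$species <- "extra"
    grown <- range_through_richness(dplyr::bind_rows(md, extra),
                                    stages)$richness
    expect_true(all(grown >= base))
  }
})

test_that("disparity through time reduces to whole-sample statistics", {
  withr::local_seed(74)
  lms <- random_sample(8, 7)
  fit <- gpa(lms)
  ord <- shape_pca(fit)
  md <- fake_metadata(8, fad = stats::runif(8, 360, 370), lad = rep(359, 8))
  md$species <- fit$specimens
  dtt <- disparity_through_time(fit, ord, md, sarcopterygian_epochs(),
                                metric = "procrustes_variance")
  defined <- dtt[!is.na(dtt$disparity), ]
  expect_equal(nrow(defined), 1)
  expect_equal(defined$interval, "Upper Devonian")
  expect_equal(defined$disparity,
               procrustes_variance(fit, rep("all", 8))$pv,
               tolerance = 1e-12)
  sov <- disparity_through_time(fit, ord, md, sarcopterygian_epochs(),
                                metric = "sum_of_variances")
  expect_equal(sov$disparity[sov$interval == "Upper Devonian"],
               sum(ord$eigenvalues), tolerance = 1e-9)
})

test_that("singleton intervals yield NA, not zero", {
  withr::local_seed(75)
  lms <- random_sample(5, 6)
  fit <- gpa(lms)
  ord <- shape_pca(fit)
  md <- fake_metadata(5, fad = c(418, 417, 421, 330, 330),
                      lad = c(417, 416, 420, 329, 329))
  md$species <- fit$specimens
  dtt <- disparity_through_time(fit, ord, md, sarcopterygian_epochs())
  expect_equal(dtt$n[dtt$interval == "Lower Devonian"], 2L)
  expect_equal(dtt$n[dtt$interval == "Pridoli"], 1L)
  expect_true(is.na(dtt$disparity[dtt$interval == "Pridoli"]))
  expect_true(is.na(dtt$disparity[dtt$interval == "Ludlow"]))
})

test_that("a doubled-noise bin shows the highest disparity", {
  withr::local_seed(76)
  bins <- equal_bins(425.6, 298.9, 7)
  k <- 10
  base <- normalize_shape(matrix(stats::runif(2 * k, -1, 1), ncol = 2))
  n_per_bin <- 12
  mids <- (bins$start_ma + bins$end_ma) / 2
  hot <- 4
  lms <- list(); fads <- numeric(0)
  idx <- 0
  for (b in seq_len(7)) {
    s <- if (b == hot) 0.06 else 0.03
    for (j in seq_len(n_per_bin)) {
      idx <- idx + 1
      lms[[idx]] <- tibble::tibble(
        specimen = sprintf("s%03d", idx), point = seq_len(k),
        x = base[, 1] + stats::rnorm(k, sd = s),
        y = base[, 2] + stats::rnorm(k, sd = s))
      fads <- c(fads, mids[b])
    }
  }
  lms <- dplyr::bind_rows(lms)
  fit <- gpa(lms)
  ord <- shape_pca(fit)
  md <- fake_metadata(idx, fad = fads, lad = pmax(fads - 1, 298.9))
  md$species <- fit$specimens
  dtt <- disparity_through_time(fit, ord, md, bins,
                                metric = "sum_of_variances")
  expect_equal(which.max(dtt$disparity), hot)
})

test_that("epoch and equal-bin curves are rank-congruent", {
  # same synthetic data binned two ways: when bins roughly coincide the
  # two disparity curves should agree in rank order
  withr::local_seed(77)
  k <- 10
  base <- normalize_shape(matrix(stats::runif(2 * k, -1, 1), ncol = 2))
  epochs <- sarcopterygian_epochs()
  sds <- seq(0.02, 0.08, length.out = nrow(epochs))
  lms <- list(); fads <- numeric(0)
  idx <- 0
  for (b in seq_len(nrow(epochs))) {
    for (j in 1:10) {
      idx <- idx + 1
      mid <- (epochs$start_ma[b] + epochs$end_ma[b]) / 2
      lms[[idx]] <- tibble::tibble(
        specimen = sprintf("s%03d", idx), point = seq_len(k),
        x = base[, 1] + stats::rnorm(k, sd = sds[b]),
        y = base[, 2] + stats::rnorm(k, sd = sds[b]))
      fads <- c(fads, mid)
    }
  }
  lms <- dplyr::bind_rows(lms)
  fit <- gpa(lms)
  ord <- shape_pca(fit)
  md <- fake_metadata(idx, fad = fads, lad = pmax(fads - 0.5, 298.9))
  md$species <- fit$specimens
  d_epoch <- disparity_through_time(fit, ord, md, epochs,
                                    metric = "sum_of_variances")
  d_bins <- disparity_through_time(fit, ord, md, equal_bins(425.6, 298.9, 7),
                                   metric = "sum_of_variances")
  ok <- !is.na(d_epoch$disparity) & !is.na(d_bins$disparity)
  rho <- stats::cor(d_epoch$disparity[ok], d_bins$disparity[ok],
                    method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("timescale validation rejects gaps and misordering", {
  bad <- tibble::tibble(interval = c("a", "b"),
                        start_ma = c(400, 380), end_ma = c(390, 370))
  expect_error(paleodisp:::validate_timescale(bad), "contiguous")
  rev_tbl <- tibble::tibble(interval = c("a", "b"),
                            start_ma = c(380, 400), end_ma = c(370, 380))
  expect_error(paleodisp:::validate_timescale(rev_tbl), "ordered")
})
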