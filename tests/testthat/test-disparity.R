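# Disparity statistics: Procrustes variance, permutation tests, hull
# areas, weighted hull areas, sum of variances.

test_that("procrustes variance matches closed forms", {
  # identical shapes: zero variance
  mat <- matrix(rep(c(1, 2, 3, 4), 5), nrow = 5, byrow = TRUE)
  expect_equal(unname(paleodisp:::pv_by_group(mat, rep("g", 5))), 0)
  # two specimens differing by d in one coordinate: PV = d^2/4
  d <- 0.6
  two <- rbind(c(0, 0, 0, 0), c(d, 0, 0, 0))
  expect_equal(unname(paleodisp:::pv_by_group(two, c("g", "g"))),
               d^2 / 4)
})

test_that("procrustes variance calibrates against isotropic noise", {
  # one group, isotropic per-coordinate noise sd s, k = 20 landmarks:
  # superimposition removes 4 dof so PV ~ s^2 * (2k - 4)
  withr::local_seed(51)
  n <- 1000
  k <- 20
  s <- 0.01
  base <- normalize_shape(matrix(stats::runif(2 * k, -1, 1), ncol = 2))
  lms <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(specimen = sprintf("s%04d", i), point = seq_len(k),
                   x = base[, 1] + stats::rnorm(k, sd = s),
                   y = base[, 2] + stats::rnorm(k, sd = s))
  }))
  fit <- gpa(lms)
  pv <- procrustes_variance(fit, rep("g", n))
  expect_equal(pv$pv, s^2 * (2 * k - 4), tolerance = 0.1)
})

test_that("group shares sum to one and singletons are tolerated", {
  withr::local_seed(52)
  fit <- gpa(random_sample(7, 8))
  pv <- procrustes_variance(fit, c("A", "A", "A", "B", "B", "B", "C"))
  expect_equal(sum(pv$share), 1, tolerance = 1e-9)
  expect_equal(pv$n[pv$group == "C"], 1L)
  expect_equal(pv$pv[pv$group == "C"], 0)
})

test_that("a group compared with itself has statistic 0 and p = 1", {
  withr::local_seed(53)
  mat <- matrix(stats::rnorm(40), nrow = 10)
  labels <- rep(c("g1", "g2"), each = 5)
  # identical composition: duplicate the rows so both groups coincide
  mat2 <- rbind(mat[1:5, ], mat[1:5, ])
  pw <- pairwise_pv_test(mat2, labels, n_perm = 199, seed = 9)
  td <- tidy(pw)
  expect_equal(td$abs_diff, 0)
  expect_equal(td$p_value, 1)
})

test_that("permutation p-values are symmetric and reproducible", {
  withr::local_seed(54)
  mat <- matrix(stats::rnorm(120), nrow = 20)
  labels <- sample(rep(c("A", "B", "C"), length.out = 20))
  pw1 <- pairwise_pv_test(mat, labels, n_perm = 199, seed = 3)
  pw2 <- pairwise_pv_test(mat, labels, n_perm = 199, seed = 3)
  expect_identical(pw1$p_value, pw2$p_value)
  expect_equal(pw1$p_value, t(pw1$p_value))
  expect_equal(diag(pw1$p_value), rep(1, 3), ignore_attr = TRUE)
  # swapping which group is called which does not change the p-value
  swapped <- ifelse(labels == "A", "B", ifelse(labels == "B", "A", "C"))
  pw3 <- pairwise_pv_test(mat, swapped, n_perm = 199, seed = 3)
  expect_equal(pw3$p_value["A", "B"], pw1$p_value["A", "B"])
  expect_warning(pairwise_pv_test(mat, labels, n_perm = 50, seed = 1),
                 "resolution")
})

test_that("the permutation test detects a planted 4x variance ratio", {
  # two groups, n = 30 each, noise sds s and 2s (PV ratio 4): the test
  # should reject at alpha = 0.05 in at least 90% of replicates
  withr::local_seed(55)
  n_rep <- 200
  rejections <- 0
  for (r in seq_len(n_rep)) {
    mat <- rbind(matrix(stats::rnorm(30 * 10, sd = 1), nrow = 30),
                 matrix(stats::rnorm(30 * 10, sd = 2), nrow = 30))
    labels <- rep(c("lo", "hi"), each = 30)
    pw <- pairwise_pv_test(mat, labels, n_perm = 999, seed = r)
    if (tidy(pw)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / n_rep, 0.90)
})

test_that("singleton groups get NA p-values but keep their PV", {
  withr::local_seed(56)
  mat <- matrix(stats::rnorm(36), nrow = 9)
  labels <- c(rep("A", 4), rep("B", 4), "C")
  pw <- pairwise_pv_test(mat, labels, n_perm = 99, seed = 2)
  td <- tidy(pw)
  expect_true(all(is.na(td$p_value[td$group1 == "C" | td$group2 == "C"])))
  expect_false(anyNA(td$abs_diff))
})

test_that("convex hull area matches closed forms", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                  c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(convex_hull_area(square), 1)
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(convex_hull_area(tri), 2)
  collinear <- cbind(0:5, 0:5)
  expect_equal(convex_hull_area(collinear), 0)
  expect_true(is.na(convex_hull_area(rbind(c(0, 0), c(1, 1)))))
})

test_that("hull area equals the brute-force oracle on random sets", {
  withr::local_seed(57)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(60), ncol = 2)
    expect_equal(convex_hull_area(pts), brute_force_hull_area(pts),
                 tolerance = 1e-10)
  }
})

test_that("hull area is invariant to ordering and rotation", {
  withr::local_seed(58)
  pts <- matrix(stats::rnorm(40), ncol = 2)
  a0 <- convex_hull_area(pts)
  expect_equal(convex_hull_area(pts[sample(20), ]), a0, tolerance = 1e-12)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(convex_hull_area(pts %*% rot), a0, tolerance = 1e-9)
})

test_that("weighted hull area: degenerate weighting, homogeneity, oracle", {
  withr::local_seed(59)
  # rank-2 scores: all variance on PCs 1-2 so the weighted sum reduces
  # to the plain PC1-PC2 hull area
  sc <- cbind(stats::rnorm(12, sd = 2), stats::rnorm(12, sd = 1))
  fake <- structure(list(
    scores = cbind(sc, matrix(0, 12, 3)),
    prop_variance = c(0.8, 0.2, 0, 0, 0),
    eigenvalues = c(0.8, 0.2, 0, 0, 0),
    specimens = sprintf("s%02d", 1:12)), class = "shape_pca")
  colnames(fake$scores) <- paste0("PC", 1:5)
  wha <- weighted_hull_area(fake, rep("g", 12), n_pcs = 5)
  expect_equal(wha$weighted_hull_area, convex_hull_area(sc),
               tolerance = 1e-12)

  # doubling all scores quadruples the weighted area
  fake2 <- fake
  fake2$scores <- 2 * fake$scores
  wha2 <- weighted_hull_area(fake2, rep("g", 12), n_pcs = 5)
  expect_equal(wha2$weighted_hull_area, 4 * wha$weighted_hull_area,
               tolerance = 1e-12)

  # independent recomputation on full-rank scores
  sc5 <- matrix(stats::rnorm(60), ncol = 5,
                dimnames = list(NULL, paste0("PC", 1:5)))
  pvar <- c(0.4, 0.25, 0.15, 0.12, 0.08)
  fake5 <- structure(list(scores = sc5, prop_variance = pvar,
                          eigenvalues = pvar,
                          specimens = sprintf("s%02d", 1:12)),
                     class = "shape_pca")
  expected <- 0
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expected <- expected +
        brute_force_hull_area(sc5[, c(i, j)]) * (pvar[i] + pvar[j])
    }
  }
  wha5 <- weighted_hull_area(fake5, rep("g", 12), n_pcs = 5)
  expect_equal(wha5$weighted_hull_area, expected, tolerance = 1e-10)
  # normalized variant divides by the sum of pair weights
  whan <- weighted_hull_area(fake5, rep("g", 12), n_pcs = 5,
                             normalize = TRUE)
  w_sum <- sum(utils::combn(5, 2, function(ij) sum(pvar[ij])))
  expect_equal(whan$weighted_hull_area,
               wha5$weighted_hull_area / w_sum, tolerance = 1e-12)
})

test_that("sum of variances agrees with eigenvalues and raw coordinates", {
  withr::local_seed(60)
  fit <- gpa(random_sample(12, 9))
  ord <- shape_pca(fit)
  expect_equal(sum_of_variances(ord), sum(ord$eigenvalues),
               tolerance = 1e-9)
  # on a random subset it equals the total variance of the subset's
  # aligned coordinates about the subset mean
  rows <- sample(12, 6)
  sub_scores <- ord$scores[rows, , drop = FALSE]
  x <- paleodisp:::aligned_matrix(fit)[rows, , drop = FALSE]
  direct <- sum(sweep(x, 2, colMeans(x))^2) / (6 - 1)
  expect_equal(sum_of_variances(sub_scores), direct, tolerance = 1e-9)
  expect_true(is.na(sum_of_variances(ord$scores[1, , drop = FALSE])))
})

test_that("whole-sample PV equals summed score variances (divisor n)", {
  withr::local_seed(61)
  fit <- gpa(random_sample(11, 7))
  ord <- shape_pca(fit)
  n <- 11
  pv_all <- procrustes_variance(fit, rep("all", n))$pv
  sov_n <- sum(apply(ord$scores, 2, function(v) {
    sum((v - mean(v))^2) / n
  }))
  expect_equal(pv_all, sov_n, tolerance = 1e-9)
})

test_that("planted group noise ratio is recovered as a PV ratio", {
  withr::local_seed(62)
  truth <- sim_truth(
    n_per_group = c(Dipnoi = 200, Actinistia = 200),
    k_fixed = 8, k_semi = 24,
    noise_sd = c(Dipnoi = 0.01, Actinistia = 0.02),
    offset_magnitude = 0, seed = 62)
  d <- simulate_dataset(truth)
  fit <- gpa(d$landmarks, d$sliders)
  pv <- procrustes_variance(fit, d$metadata)
  ratio <- pv$pv[pv$group == "Actinistia"] / pv$pv[pv$group == "Dipnoi"]
  expect_gte(ratio, 3.4)
  expect_lte(ratio, 4.6)
})

test_that("disparity_table assembles all statistics coherently", {
  withr::local_seed(63)
  truth <- sim_truth(n_per_group = c(Dipnoi = 6, Actinistia = 6,
                                     Tetrapoda = 1),
                     k_fixed = 6, k_semi = 6, seed = 63)
  d <- simulate_dataset(truth)
  fit <- gpa(d$landmarks, d$sliders)
  ord <- shape_pca(fit)
  dt <- disparity_table(fit, ord, d$metadata, n_perm = 99, seed = 1)
  td <- tidy(dt)
  expect_setequal(td$group, c("Dipnoi", "Actinistia", "Tetrapoda"))
  expect_equal(sum(td$share), 1, tolerance = 1e-9)
  expect_true(is.na(td$hull_area[td$group == "Tetrapoda"]))
  expect_true(is.na(td$weighted_hull_area[td$group == "Tetrapoda"]))
  expect_false(anyNA(td$hull_area[td$n >= 3]))
  expect_s3_class(autoplot(dt), "ggplot")
  expect_equal(glance(dt)$n_perm, 99)
})
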