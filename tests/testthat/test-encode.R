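test_that("PLS1 matches a literal NIPALS reference up to sign", {
  set.seed(21)
  X <- matrix(rnorm(48), 6, 8)
  y <- rnorm(6)
  got <- fit_pls(X, y, n_components = 3)
  ref <- nipals_reference(X, y, 3)
  for (a in 1:3) {
    s <- sign(sum(got$weights[, a] * ref$W[, a]))
    expect_equal(got$weights[, a], s * ref$W[, a], tolerance = 1e-8)
    expect_equal(got$modes[, a], s * as.vector(ref$P[, a]), tolerance = 1e-8)
    expect_equal(got$scores[, a], s * as.vector(ref$scores[, a]), tolerance = 1e-8)
    expect_equal(got$q[a], s * ref$q[a], tolerance = 1e-8)
  }
})

test_that("PLS finds a planted single-column signal immediately", {
  set.seed(22)
  X <- cbind(matrix(rnorm(60 * 16, sd = 0.1), 60, 16), rnorm(60),
             matrix(rnorm(60 * 43, sd = 0.1), 60, 43))
  y <- X[, 17]
  m <- fit_pls(X, y, 3)
  expect_gt(m$explained_outcome_variance[1], 0.99)
})

test_that("PLS errors on degenerate inputs", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fit_pls(X, rep(1, 10), 2), "constant")
  expect_error(fit_pls(X, rnorm(10), 10), "n_components")
  expect_error(fit_pls(X, rnorm(9), 2), "length")
})

test_that("full-rank PLS reconstructs training shapes", {
  set.seed(23)
  X <- matrix(rnorm(8 * 30), 8, 30)
  y <- rnorm(8)
  m <- fit_pls(X, y, 7)
  for (k in c(1, 5)) {
    rec <- reconstruct(m, m$scores[k, ])
    expect_equal(as.vector(t(cloud_points(rec))), X[k, ], tolerance = 1e-6)
  }
})

test_that("in-sample outcome fit of PLS dominates PCA at equal rank", {
  set.seed(24)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- X %*% rnorm(50) * 0.1 + rnorm(20)
  for (nc in c(2, 5)) {
    pls <- fit_pls(X, y, nc)
    pca <- fit_pca(X, nc, y = y)
    expect_gte(sum(pls$explained_outcome_variance) + 1e-10,
               sum(pca$explained_outcome_variance))
  }
})

test_that("PCA modes are orthonormal leading directions", {
  set.seed(25)
  planted <- rnorm(40)
  planted <- planted / sqrt(sum(planted^2))
  X <- outer(rnorm(30, sd = 5), planted) + matrix(rnorm(1200, sd = 0.1), 30, 40)
  m <- fit_pca(X, 4)
  expect_gt(abs(sum(m$modes[, 1] * planted)), 0.999)
  expect_equal(crossprod(m$modes), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)

  # reconstruction error non-increasing with more components
  errs <- vapply(1:4, function(nc) {
    mm <- fit_pca(X, nc)
    sum((scale(X, scale = FALSE) - mm$scores %*% t(mm$modes))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))

  expect_warning(fit_pca(matrix(rnorm(12), 4, 3), 10), "rank")
})

test_that("reconstruct is affine in the scores around the mean shape", {
  set.seed(26)
  X <- matrix(rnorm(10 * 30), 10, 30)
  m <- fit_pca(X, 3, mean_shape = matrix(0, 10, 3))
  ms <- reconstruct(m, c(0, 0, 0))
  expect_equal(as.vector(t(cloud_points(ms))), m$center, tolerance = 1e-12)

  a <- c(1.2, -0.5, 2)
  r1 <- as.vector(t(cloud_points(reconstruct(m, a)))) - m$center
  r2 <- as.vector(t(cloud_points(reconstruct(m, 2 * a)))) - m$center
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
  expect_error(reconstruct(m, c(1, 2)), "length")
})

test_that("mode signs are fixed with the largest-magnitude entry positive", {
  set.seed(27)
  X <- matrix(rnorm(15 * 40), 15, 40)
  for (m in list(fit_pls(X, rnorm(15), 3), fit_pca(X, 3))) {
    for (a in seq_len(m$n_components)) {
      u <- m$modes[, a]
      expect_gt(u[which.max(abs(u))], 0)
    }
  }
})

test_that("explained variance curves are monotone and saturate on pure signal", {
  set.seed(28)
  lat <- rnorm(30)
  X <- outer(lat, rnorm(50)) + matrix(rnorm(1500, sd = 1e-3), 30, 50)
  y <- 2 * lat
  m <- fit_pls(X, y, 4)
  ev <- explained_variance_curve(m, y)
  expect_gt(ev$cumulative[1], 0.999)
  expect_true(all(diff(ev$cumulative) >= -1e-12))
  expect_true(all(ev$per_component >= -1e-12 & ev$per_component <= 1 + 1e-12))
  expect_equal(ev$per_component, diff(c(0, ev$cumulative)), tolerance = 1e-12)
})

test_that("PLS and PCA agree when the outcome is the first principal score", {
  set.seed(29)
  X <- outer(rnorm(25, sd = 4), rnorm(60)) + matrix(rnorm(1500, sd = 0.2), 25, 60)
  pca <- fit_pca(X, 3)
  y <- as.vector(pca$scores[, 1])
  pls <- fit_pls(X, y, 3)
  expect_gt(abs(sum(pls$modes[, 1] * pca$modes[, 1])) /
              sqrt(sum(pls$modes[, 1]^2)), 0.99)
})

test_that("mode variation shapes are symmetric about the mean", {
  fx <- small_cohort()
  coh <- fx$cohort
  m <- fit_pls(coh$deviations, coh$outcomes, 3, mean_shape = coh$mean_shape)
  shapes <- mode_variation_meshes(m, 1)
  expect_length(shapes, 5)
  mid <- cloud_points(shapes[["+0sigma"]])
  expect_equal(mid, coh$mean_shape, tolerance = 1e-9, ignore_attr = TRUE)
  pair_mean <- (cloud_points(shapes[["-1sigma"]]) +
                  cloud_points(shapes[["+1sigma"]])) / 2
  expect_equal(pair_mean, mid, tolerance = 1e-9)
  expect_error(mode_variation_meshes(m, 9), "mode index")
})

test_that("size-dominated mode sweeps volume monotonically", {
  # cohort varying only in overall size: mode 1 is the size mode
  sds <- setNames(rep(0, 8), names(latent_population()$sd))
  sds["size_scale"] <- 0.1
  synth <- generate_cohort(K = 8, truth = ground_truth(noise_sd = 0),
                           population = latent_population(sd = sds),
                           seed = 13, n_theta = 24, n_phi = 32)
  coh <- build_cohort(synth$meshes, synth$outcomes, n_points = 600, seed = 13)
  m <- fit_pca(coh$deviations, 2, mean_shape = coh$mean_shape)
  shapes <- mode_variation_meshes(m, 1)
  # RMS radius as a size proxy for point clouds
  size_of <- function(cl) sqrt(mean(rowSums(cloud_points(cl)^2)))
  sizes <- vapply(shapes, size_of, numeric(1))
  expect_true(all(diff(sizes) > 0) || all(diff(sizes) < 0))
})

test_that("VIP satisfies its exact identities and rejects PCA models", {
  set.seed(30)
  X <- matrix(rnorm(20 * 60), 20, 60)
  y <- rnorm(20)
  m <- fit_pls(X, y, 4)
  v <- vip(m)
  expect_equal(mean(v$per_variable^2), 1, tolerance = 1e-10)
  expect_true(all(v$per_variable >= 0))
  expect_length(v$per_point, 20)

  # single component: VIP_j = sqrt(p) |w_j| / ||w||
  m1 <- fit_pls(X, y, 1)
  v1 <- vip(m1)
  w <- m1$weights[, 1]
  expect_equal(v1$per_variable, sqrt(60) * abs(w) / sqrt(sum(w^2)),
               tolerance = 1e-10)

  expect_error(vip(fit_pca(X, 2)), "PLS")
})

test_that("PLS1 scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(33)
  X <- matrix(rnorm(30 * 25), 30, 25)
  y <- X %*% rnorm(25) * 0.2 + rnorm(30)
  ours <- fit_pls(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  for (a in 1:3) {
    r <- cor(ours$scores[, a], ref$variates$X[, a])
    expect_gt(abs(r), 1 - 1e-8)
  }
})
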