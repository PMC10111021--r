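test_that("downsample keeps exact-n sources, errors on short ones, and is uniform", {
  pts <- matrix(rnorm(300), 100, 3)
  same <- downsample(pts, 100)
  expect_setequal(asplit(cloud_points(same), 1), asplit(pts, 1))
  expect_error(downsample(pts, 101), "fewer")
  expect_error(downsample(pts, 0), "positive")
  expect_error(downsample(pts, -5), "positive")

  # farthest-point subsets are more even than random subsets: compare the
  # coefficient of variation of nearest-neighbour distances on a sphere
  sph <- make_icosphere(radius = 10, subdiv = 4)
  fps <- cloud_points(downsample(sph, 500, seed = 1, method = "fps"))
  nn_cv <- function(p) {
    # nearest non-self neighbour distances
    d <- vapply(seq_len(nrow(p)), function(i) {
      dd <- colSums((t(p[-i, , drop = FALSE]) - p[i, ])^2)
      sqrt(min(dd))
    }, numeric(1))
    sd(d) / mean(d)
  }
  set.seed(2)
  rnd <- sph$vertices[sample(nrow(sph$vertices), 500), ]
  expect_lt(nn_cv(fps), nn_cv(rnd))

  # both strategies are deterministic
  expect_identical(cloud_points(downsample(sph, 500, seed = 1)),
                   cloud_points(downsample(sph, 500, seed = 1)))
  expect_identical(cloud_points(downsample(sph, 500, method = "stride")),
                   cloud_points(downsample(sph, 500, method = "stride")))
})

test_that("centering zeroes the centroid and preserves shape", {
  pts <- matrix(rnorm(60), 20, 3)
  ctr <- center_cloud(lv_cloud(pts))
  expect_lt(sqrt(sum(colMeans(cloud_points(ctr))^2)), 1e-9)
  expect_equal(cloud_points(center_cloud(ctr)), cloud_points(ctr),
               tolerance = 1e-12)

  shifted <- center_cloud(lv_cloud(sweep(pts, 2, c(5, -3, 2), "+")))
  expect_equal(cloud_points(shifted), cloud_points(ctr), tolerance = 1e-12)

  # translation invariance of all pairwise distances
  expect_equal(as.vector(dist(cloud_points(ctr))), as.vector(dist(pts)),
               tolerance = 1e-12)
})

test_that("reference selection minimizes joint surface/volume distance to the mean", {
  spheres <- lapply(c(8, 10, 12), function(r) make_icosphere(r, subdiv = 2))
  expect_equal(select_reference(spheres), 2L)

  same <- list(spheres[[1]], spheres[[1]], spheres[[1]])
  expect_equal(select_reference(same), 1L)
  expect_equal(select_reference(spheres[2]), 1L)

  # equals the brute-force criterion on generator meshes
  set.seed(4)
  meshes <- lapply(1:5, function(i)
    generate_lv_mesh(latent_params(size_scale = runif(1, 0.9, 1.1)),
                     n_theta = 20, n_phi = 24))
  sv <- t(vapply(meshes, function(m) unlist(surface_and_volume(m)), numeric(2)))
  crit <- (sv[, 1] - mean(sv[, 1]))^2 + (sv[, 2] - mean(sv[, 2]))^2
  expect_equal(select_reference(meshes), which.min(crit))
})

test_that("ICP is exact on identical clouds and recovers known transforms", {
  m <- generate_lv_mesh(latent_params(bump_amplitudes = c(3, -2, 2, -1)),
                        n_theta = 30, n_phi = 40)
  p <- cloud_points(center_cloud(downsample(m, 800, seed = 1)))

  fit0 <- icp_align(p, p)
  expect_equal(fit0$transform$R, diag(3), tolerance = 1e-9)
  expect_lt(sum(fit0$transform$T^2), 1e-18)
  expect_lt(fit0$transform$E, 1e-12)
  expect_equal(fit0$transform$s, 1)

  set.seed(8)
  R0 <- random_rotation(10)
  q <- sweep(p %*% t(R0), 2, c(3, 0, 0), "+")
  fit <- icp_align(p, q)
  comp <- fit$transform$R %*% t(R0)
  expect_lt(max(abs(comp - diag(3))), 1e-6)
  expect_lt(fit$transform$E, 1e-10)

  # E equals the brute-force residual sum for the returned correspondence
  aligned <- cloud_points(fit$aligned)
  nn <- nn_brute(aligned, q)
  expect_equal(fit$transform$E, sum(nn$dist2), tolerance = 1e-9)
  expect_equal(fit$transform$residuals, sqrt(nn$dist2), tolerance = 1e-9)
})

test_that("ICP error history is non-increasing", {
  set.seed(12)
  m1 <- generate_lv_mesh(latent_params(), n_theta = 24, n_phi = 32)
  m2 <- generate_lv_mesh(latent_params(size_scale = 1.07, chamber_scale = 0.62),
                         n_theta = 24, n_phi = 32)
  p <- cloud_points(center_cloud(downsample(m1, 600, seed = 1)))
  q <- cloud_points(center_cloud(downsample(m2, 600, seed = 1)))
  fit <- icp_align(p %*% t(random_rotation(15)), q)
  expect_true(all(diff(fit$transform$E_history) <= 1e-9))
})

test_that("rigid alignment preserves all pairwise distances", {
  set.seed(3)
  p <- matrix(rnorm(240), 80, 3)
  q <- sweep(p %*% t(random_rotation(25)), 2, c(4, -2, 7), "+")
  fit <- icp_align(p, q)
  expect_equal(as.vector(dist(cloud_points(fit$aligned))), as.vector(dist(p)),
               tolerance = 1e-9)
})

test_that("correspondence recovers permutations and beats the greedy baseline", {
  m <- generate_lv_mesh(latent_params(), n_theta = 24, n_phi = 32)
  tp <- cloud_points(center_cloud(downsample(m, 500, seed = 1)))
  tmpl <- lv_cloud(tp)

  same <- correspond(lv_cloud(tp), tmpl)
  expect_identical(cloud_points(same), tp)

  set.seed(5)
  perm0 <- sample(500)
  shuffled <- lv_cloud(tp[perm0, , drop = FALSE])
  rec <- correspond(shuffled, tmpl)
  expect_identical(cloud_points(rec), tp)
  expect_true(rec$corresponded)

  # perturbed cloud: assignment is a bijection and its cost does not exceed
  # sequential nearest-neighbour-with-removal
  set.seed(6)
  noisy <- tp[perm0, ] + matrix(rnorm(1500, 0, 0.4), 500, 3)
  matched <- correspond(lv_cloud(noisy), tmpl, scale_invariant = FALSE)
  # bijection: every source point used exactly once
  expect_equal(sort(match(asplit(cloud_points(matched), 1), asplit(noisy, 1))),
               1:500)
  cost_pkg <- sum((cloud_points(matched) - tp)^2)
  cost_greedy <- match_cost(tp, noisy, greedy_removal_match(tp, noisy))
  expect_lte(cost_pkg, cost_greedy + 1e-9)

  expect_error(correspond(lv_cloud(tp[1:10, ]), tmpl), "equal N")
})

test_that("mean shape is the exact pointwise average", {
  cl <- lv_cloud(matrix(rnorm(90), 30, 3), corresponded = TRUE)
  expect_equal(cloud_points(mean_shape(list(cl, cl, cl))), cloud_points(cl))

  neg <- lv_cloud(-cloud_points(cl), corresponded = TRUE)
  expect_equal(max(abs(cloud_points(mean_shape(list(cl, neg))))), 0)

  set.seed(7)
  clouds <- lapply(1:5, function(i) lv_cloud(matrix(rnorm(90), 30, 3)))
  got <- cloud_points(mean_shape(clouds))
  want <- matrix(0, 30, 3)
  for (c_ in clouds) want <- want + cloud_points(c_)
  expect_equal(got, want / 5, tolerance = 1e-12)

  expect_error(mean_shape(list()), "empty")
  expect_error(mean_shape(list(cl, lv_cloud(matrix(1, 4, 3)))), "mismatch")
})

test_that("build_cohort produces exact deviations with near-zero column means", {
  fx <- small_cohort()
  coh <- fx$cohort
  K <- length(fx$synth$outcomes)
  N <- coh$n_points

  # deviations + mean reconstruct each cloud exactly
  mean_flat <- as.vector(t(coh$mean_shape))
  for (k in c(1, K)) {
    expect_equal(coh$deviations[k, ] + mean_flat,
                 as.vector(t(coh$clouds[[k]])), tolerance = 1e-12)
  }
  expect_lt(max(abs(colMeans(coh$deviations))), 1e-9)
  expect_equal(dim(coh$deviations), c(K, 3 * N))

  # identical shapes give zero deviations
  pop0 <- latent_population(sd = setNames(rep(0, 8), names(latent_population()$sd)))
  z <- generate_cohort(K = 3, truth = ground_truth(noise_sd = 0),
                       population = pop0, seed = 2, n_theta = 20, n_phi = 24)
  zc <- build_cohort(z$meshes, z$outcomes, n_points = 300, seed = 2)
  expect_lt(max(abs(zc$deviations)), 1e-9)
})

test_that("single-latent cohorts give an effectively rank-one deviation matrix", {
  sds <- setNames(rep(0, 8), names(latent_population()$sd))
  sds["size_scale"] <- 0.1
  pop <- latent_population(sd = sds)
  synth <- generate_cohort(K = 10, truth = ground_truth(noise_sd = 0),
                           population = pop, seed = 6, n_theta = 28, n_phi = 36)
  coh <- build_cohort(synth$meshes, synth$outcomes, n_points = 800, seed = 6)
  sv <- svd(coh$deviations)$d
  # one varied latent: the leading direction carries nearly all the energy,
  # the remainder is correspondence noise
  expect_gt(sv[1]^2 / sum(sv^2), 0.85)
  expect_gt(sv[1] / sv[2], 3)
})

test_that("subject order does not change the mean shape", {
  fx <- small_cohort()
  synth <- fx$synth
  ord <- rev(seq_along(synth$outcomes))
  coh2 <- build_cohort(synth$meshes[ord], synth$outcomes[ord],
                       n_points = 1200, seed = 11)
  expect_equal(coh2$mean_shape, fx$cohort$mean_shape, tolerance = 1e-9)
  expect_equal(coh2$deviations[ord, ], fx$cohort$deviations, tolerance = 1e-9)
})

test_that("realignment to the mean does not worsen the total deviation norm", {
  fx <- small_cohort()
  synth <- fx$synth
  coh0 <- build_cohort(synth$meshes, synth$outcomes, n_points = 1200,
                       seed = 11, refine_passes = 0)
  coh1 <- fx$cohort  # refine_passes = 1
  expect_lte(sum(coh1$deviations^2), sum(coh0$deviations^2) * 1.01)
})
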