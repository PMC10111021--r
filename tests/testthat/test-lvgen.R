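test_that("bump-free spheroidal shell matches the closed-form volume", {
  # elongation 1 turns both surfaces into truncated spherical shells
  p <- latent_params(elongation = 1)
  m <- generate_lv_mesh(p)
  expect_true(mesh_is_closed(m))
  sv <- surface_and_volume(m)
  expect_equal(sv$volume, shell_volume_analytic(p), tolerance = 0.02)

  # the default elongated template also agrees with the analytic form
  p2 <- latent_params()
  expect_equal(surface_and_volume(generate_lv_mesh(p2))$volume,
               shell_volume_analytic(p2), tolerance = 0.02)
})

test_that("mesh generation is deterministic and monotone in size", {
  p <- latent_params(bump_amplitudes = c(2, -1, 1.5, 0), seed = 5)
  m1 <- generate_lv_mesh(p)
  m2 <- generate_lv_mesh(p)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)

  v_small <- surface_and_volume(generate_lv_mesh(latent_params(size_scale = 1.0)))$volume
  v_large <- surface_and_volume(generate_lv_mesh(latent_params(size_scale = 1.1)))$volume
  expect_gt(v_large, v_small)
})

test_that("degenerate shape parameters are rejected", {
  expect_error(latent_params(chamber_scale = 1), "chamber_scale")
  expect_error(latent_params(chamber_scale = 0), "chamber_scale")
  expect_error(latent_params(wall_thickness_mm = 0), "wall_thickness_mm")
  expect_error(latent_params(size_scale = -1), "size_scale")
  # cavity pushed below the basal plane
  expect_error(generate_lv_mesh(latent_params(chamber_scale = 0.3)),
               "degenerate")
})

test_that("voxelization recovers analytic sphere volume and errors on bad input", {
  sph <- make_icosphere(radius = 10, subdiv = 3)
  lab <- voxelize(sph, spacing_mm = 0.5)
  expect_equal(label_volume(lab), 4 / 3 * pi * 1000, tolerance = 0.03)

  expect_error(voxelize(sph, spacing_mm = -1), "positive")
  open_mesh <- lv_mesh(sph$vertices, sph$faces[-1, , drop = FALSE])
  expect_error(voxelize(open_mesh), "watertight")
  expect_error(lv_mesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3)) |>
                 voxelize(), "empty|watertight")
})

test_that("voxelize then extract_surface round-trips volume within 5%", {
  m <- generate_lv_mesh(latent_params(bump_amplitudes = c(2, 0, -1, 0)))
  lab <- voxelize(m, spacing_mm = 0.5)
  surf <- extract_surface(lab, smooth_iterations = 0)
  expect_true(mesh_is_closed(surf))
  v0 <- surface_and_volume(m)$volume
  v1 <- surface_and_volume(surf)$volume
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("cohort outcomes follow the linear generative model", {
  # noise-free: empirical outcome variance matches propagated variance
  truth <- ground_truth(noise_sd = 0)
  pop <- latent_population()
  synth <- generate_cohort(K = 66, truth = truth, population = pop, seed = 42,
                           n_theta = 24, n_phi = 32)
  v_emp <- var(synth$outcomes)
  v_theory <- sum((truth$beta * pop$sd)^2)
  # sample variance of 66 normals: chi-square band (~3 sigma)
  expect_gt(v_emp / v_theory, 0.5)
  expect_lt(v_emp / v_theory, 1.7)

  # noise-free outcome is an exact linear function of the latents
  fit <- lm.fit(cbind(1, synth$latents), synth$outcomes)
  expect_lt(max(abs(fit$residuals)), 1e-10 * sd(synth$outcomes))

  # outcome ties to the covariate table through the LVMI change definition
  expect_equal(lvmi_regression(synth$covariates$pre_lvmi,
                               synth$covariates$one_year_lvmi),
               synth$outcomes, tolerance = 1e-12)
})

test_that("cohort generation is reproducible and degenerates sensibly", {
  truth <- ground_truth()
  a <- generate_cohort(K = 4, truth = truth, seed = 9, n_theta = 20, n_phi = 24)
  b <- generate_cohort(K = 4, truth = truth, seed = 9, n_theta = 20, n_phi = 24)
  expect_identical(a$latents, b$latents)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$meshes[[3]]$vertices, b$meshes[[3]]$vertices)

  pop0 <- latent_population(sd = setNames(rep(0, 8), names(latent_population()$sd)))
  z <- generate_cohort(K = 3, truth = ground_truth(noise_sd = 0),
                       population = pop0, seed = 1, n_theta = 20, n_phi = 24)
  expect_identical(z$meshes[[1]]$vertices, z$meshes[[3]]$vertices)
  expect_equal(z$outcomes[1], z$outcomes[3])
  expect_error(generate_cohort(K = 2), "K")
})

test_that("corrupt_label carves accountable holes and islands", {
  lab <- make_sphere_label(9, pad = 4)
  n0 <- sum(lab$grid)

  ident <- corrupt_label(lab, n_holes = 0, n_islands = 0, seed = 1)
  expect_identical(ident$label$grid, lab$grid)

  holed <- corrupt_label(lab, n_holes = 5, hole_diameter_vox = 3, seed = 2)
  expect_equal(n0 - sum(holed$label$grid), holed$hole_voxels)
  expect_equal(holed$hole_voxels, 5 * nrow(se_offsets_ball(3)))
  # original untouched
  expect_equal(sum(lab$grid), n0)

  isl <- corrupt_label(lab, n_islands = 2, seed = 3)
  lab_cc <- lvssm:::components_cpp(as.vector(isl$label$grid), dim(isl$label$grid))
  expect_equal(max(lab_cc), 3L)  # sphere + 2 islands

  # a hole wider than the whole label is impossible
  thin <- lv_label(array(rep(c(0L, 1L, 0L), c(9, 9, 9)), dim = c(3, 3, 3)))
  expect_error(corrupt_label(thin, n_holes = 1, hole_diameter_vox = 9),
               "thickness|centre")
})
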