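# Synthetic LV cohort generator. The base geometry is a truncated prolate
# spheroid shell: an epicardial half-ellipsoid-with-basal-cap, an endocardial
# scaled copy, a flat basal annulus joining the two rims, plus Gaussian
# radial bumps at fixed inner-wall sites. Shapes vary along a small set of
# latent parameters and the simulated outcome (fractional one-year LVMI
# change) is a linear function of those latents plus noise.

# geometry constants shared by all subjects so that point correspondence is
# anatomically meaningful across a cohort
.lv_geom <- list(
  base_radius_mm = 25,     # epicardial equatorial semi-axis at size_scale 1
  base_frac      = 0.45,   # basal truncation plane at base_frac * long semi-axis
  bump_sigma     = 0.35,   # angular width (rad) of inner-wall bumps
  # fixed bump sites (theta from apex, phi): basal-septal ("aortic"),
  # mid-anterolateral, apical, basal-lateral
  bump_theta = c(1.90, 1.20, 0.40, 1.80),
  bump_phi   = c(0.30, 2.40, 4.00, 3.50)
)

#' Latent shape parameters of a synthetic left ventricle
#'
#' @param size_scale global scale (dimensionless, > 0).
#' @param elongation long-axis to equatorial-axis ratio (dimensionless, > 0).
#' @param chamber_scale endocardial cavity scale relative to the epicardial
#'   shell, in (0, 1).
#' @param wall_thickness_mm minimum shell thickness (mm, > 0); acts as a
#'   floor under the chamber scaling.
#' @param bump_amplitudes length-4 vector of local inner-wall deformation
#'   magnitudes (mm); positive values bulge into the cavity. Sites are fixed
#'   across a cohort.
#' @param seed integer seed recorded with the parameters.
#' @return an object of class `lv_latent_params`.
#' @export
latent_params <- function(size_scale = 1, elongation = 1.6, chamber_scale = 0.65,
                          wall_thickness_mm = 7, bump_amplitudes = c(0, 0, 0, 0),
                          seed = 1L) {
  if (size_scale <= 0) stop("size_scale must be > 0")
  if (elongation <= 0) stop("elongation must be > 0")
  if (chamber_scale <= 0 || chamber_scale >= 1)
    stop("chamber_scale must be in (0, 1)")
  if (wall_thickness_mm <= 0) stop("wall_thickness_mm must be > 0")
  if (length(bump_amplitudes) != length(.lv_geom$bump_theta))
    stop("bump_amplitudes must have length ", length(.lv_geom$bump_theta))
  structure(list(size_scale = size_scale, elongation = elongation,
                 chamber_scale = chamber_scale,
                 wall_thickness_mm = wall_thickness_mm,
                 bump_amplitudes = as.numeric(bump_amplitudes),
                 seed = as.integer(seed)),
            class = "lv_latent_params")
}

latents_as_vector <- function(p) {
  c(size_scale = p$size_scale, elongation = p$elongation,
    chamber_scale = p$chamber_scale, wall_thickness_mm = p$wall_thickness_mm,
    setNames(p$bump_amplitudes, paste0("bump_", seq_along(p$bump_amplitudes))))
}

# semi-axes and truncation height implied by latent parameters: the
# endocardial equatorial axis is the chamber-scaled epicardial axis pushed
# inward by the wall-thickness excess over the 7 mm reference (thicker wall
# = smaller cavity at fixed epicardium); the long endocardial axis follows
# the chamber scale alone
.lv_wall_ref <- 7
.lv_dims <- function(params) {
  a_epi <- .lv_geom$base_radius_mm * params$size_scale
  c_epi <- a_epi * params$elongation
  z_base <- .lv_geom$base_frac * c_epi
  a_endo <- params$chamber_scale * a_epi - (params$wall_thickness_mm - .lv_wall_ref)
  c_endo <- params$chamber_scale * c_epi
  if (a_endo <= 2 || c_endo <= z_base)
    stop("degenerate parameters: cavity collapsed or does not reach the base plane")
  list(a_epi = a_epi, c_epi = c_epi, a_endo = a_endo, c_endo = c_endo,
       z_base = z_base)
}

# one latitude ring of a truncated spheroid (theta measured from the apex,
# apex at z = -c), optionally deformed by inner-wall bumps; bump amplitude
# tapers smoothly to zero at the basal rim (theta_rim) because the fibrous
# annulus does not carry trabecular structure
.lv_ring <- function(a, c_, theta, phi, bumps = NULL, theta_rim = NULL) {
  x <- a * sin(theta) * cos(phi)
  y <- a * sin(theta) * sin(phi)
  z <- rep(-c_ * cos(theta), length(phi))
  ring <- cbind(x, y, z)
  if (!is.null(bumps)) {
    taper <- 1
    if (!is.null(theta_rim)) {
      s <- min(max((theta_rim - theta) / 0.3, 0), 1)
      taper <- s * s * (3 - 2 * s)
    }
    if (taper > 0) {
      dir <- ring / sqrt(rowSums(ring^2))
      for (s in seq_along(bumps$amp)) {
        if (bumps$amp[s] == 0) next
        sv <- c(sin(bumps$theta[s]) * cos(bumps$phi[s]),
                sin(bumps$theta[s]) * sin(bumps$phi[s]),
                -cos(bumps$theta[s]))
        ang <- acos(pmin(1, pmax(-1, as.vector(dir %*% sv))))
        ring <- ring - dir * (taper * bumps$amp[s] * exp(-0.5 * (ang / bumps$sigma)^2))
      }
    }
  }
  ring
}

#' Generate a watertight synthetic LV shell mesh
#'
#' Builds the epicardial surface, basal annulus and (bump-deformed)
#' endocardial surface as one consistently wound closed triangulation.
#' Deterministic: the mesh is a pure function of the parameters.
#'
#' @param params an [latent_params()] object.
#' @param n_theta latitude resolution of each surface.
#' @param n_phi longitude resolution.
#' @param n_cap number of interior rings across the basal annulus.
#' @return an [lv_mesh()], outward-oriented (positive signed volume).
#' @export
generate_lv_mesh <- function(params, n_theta = 56L, n_phi = 72L, n_cap = 3L) {
  stopifnot(inherits(params, "lv_latent_params"))
  d <- .lv_dims(params)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  th_b_epi <- acos(-d$z_base / d$c_epi)
  th_b_endo <- acos(-d$z_base / d$c_endo)
  bumps <- list(amp = params$bump_amplitudes, theta = .lv_geom$bump_theta,
                phi = .lv_geom$bump_phi, sigma = .lv_geom$bump_sigma)

  rows <- list()
  # epicardial surface, apex to base rim
  for (t in seq_len(n_theta))
    rows[[length(rows) + 1L]] <-
      .lv_ring(d$a_epi, d$c_epi, th_b_epi * t / n_theta, phi)
  epi_rim <- rows[[length(rows)]]
  endo_rim <- .lv_ring(d$a_endo, d$c_endo, th_b_endo, phi, bumps, th_b_endo)
  # flat basal annulus between the two rims
  for (s in seq_len(n_cap)) {
    w <- s / (n_cap + 1)
    rows[[length(rows) + 1L]] <- (1 - w) * epi_rim + w * endo_rim
  }
  # endocardial surface, base rim back down to the inner apex
  for (t in n_theta:1)
    rows[[length(rows) + 1L]] <-
      .lv_ring(d$a_endo, d$c_endo, th_b_endo * t / n_theta, phi, bumps, th_b_endo)

  apex_epi <- c(0, 0, -d$c_epi)
  apex_endo <- c(0, 0, -d$c_endo)
  mesh <- .stitch_rows(rows, apex_epi, apex_endo, n_phi)
  sv <- surface_and_volume(mesh)
  if (sv$volume < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# closed triangulation of an apex / ring stack / apex sweep
.stitch_rows <- function(rows, apex_start, apex_end, n_phi) {
  m <- length(rows)
  verts <- rbind(apex_start, do.call(rbind, rows), apex_end)
  rownames(verts) <- NULL
  ring_off <- function(r) 1L + (r - 1L) * n_phi  # first vertex of ring r, minus 1
  nxt <- c(seq_len(n_phi - 1L) + 1L, 1L)
  faces <- vector("list", m + 1L)
  j <- seq_len(n_phi)
  faces[[1L]] <- cbind(1L, ring_off(1L) + j, ring_off(1L) + nxt[j])
  for (r in seq_len(m - 1L)) {
    a <- ring_off(r) + j
    b <- ring_off(r) + nxt[j]
    c_ <- ring_off(r + 1L) + j
    d_ <- ring_off(r + 1L) + nxt[j]
    faces[[r + 1L]] <- rbind(cbind(a, c_, d_), cbind(a, d_, b))
  }
  last <- nrow(verts)
  faces[[m + 1L]] <- cbind(last, ring_off(m) + nxt[j], ring_off(m) + j)
  lv_mesh(verts, do.call(rbind, faces))
}

#' Voxelize a closed mesh into a binary label volume
#'
#' Parity-fill rasterization: voxel centres strictly inside the surface are
#' labelled 1. The grid is the mesh bounding box plus `pad_voxels` of
#' background on every side.
#'
#' @param mesh a closed [lv_mesh()].
#' @param spacing_mm length-3 (or scalar) voxel spacing in mm.
#' @param pad_voxels background padding on each side.
#' @return an [lv_label()]. A warning is raised if the rasterized shell
#'   breaks into multiple connected components (spacing too coarse).
#' @export
voxelize <- function(mesh, spacing_mm = c(1, 1, 1), pad_voxels = 2L) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("empty mesh cannot be voxelized")
  if (!mesh_is_closed(mesh)) stop("mesh is not watertight")
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  origin <- lo - pad_voxels * spacing_mm
  dims <- as.integer(ceiling((hi - origin) / spacing_mm)) + pad_voxels + 1L
  res <- voxelize_cpp(mesh$vertices, mesh$faces, origin, spacing_mm, dims)
  if (res$odd_columns > 0)
    warning(res$odd_columns, " voxel columns had unpaired surface crossings")
  grid <- array(res$grid, dim = dims)
  lab <- lv_label(grid, spacing_mm = spacing_mm, origin_mm = origin)
  ncomp <- max(components_cpp(as.vector(lab$grid), dim(lab$grid)))
  if (ncomp == 0L)
    stop("voxelization produced an empty label (spacing too coarse)")
  if (ncomp > 1L)
    warning("rasterized shell split into ", ncomp,
            " components; spacing is too coarse for the wall thickness")
  lab
}

#' Ground-truth latent-to-outcome map
#'
#' Encodes the linear generative model assumed for the simulated outcome:
#' `outcome = intercept + beta . latents + N(0, noise_sd)`.
#'
#' @param beta named weight vector over the 8 latents (outcome units per
#'   latent unit). The default drives the outcome with 3 latents — overall
#'   size, sphericity (elongation) and chamber scale — mirroring the three
#'   interpreted shape modes of the motivating study (volumetric size,
#'   chamber volume, spherical-to-ovoidal conversion).
#' @param intercept outcome intercept on the raw-latent scale. The default
#'   offsets the default beta at the latent population means so the cohort
#'   mean outcome is about -0.25, a typical 25% one-year mass regression.
#' @param noise_sd SD of additive outcome noise (>= 0).
#' @param informative_site_index which bump site carries outcome signal (for
#'   localization experiments), or NA.
#' @return an object of class `lv_truth`.
#' @export
ground_truth <- function(beta = c(size_scale = -0.5, elongation = 0.25,
                                  chamber_scale = 0.8, wall_thickness_mm = 0,
                                  bump_1 = 0, bump_2 = 0, bump_3 = 0, bump_4 = 0),
                         intercept = -0.67, noise_sd = 0.05,
                         informative_site_index = NA_integer_) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(beta) != 8L) stop("beta must have 8 entries (4 scalars + 4 bumps)")
  structure(list(beta = beta, intercept = intercept, noise_sd = noise_sd,
                 informative_site_index = informative_site_index),
            class = "lv_truth")
}

#' Cohort-level latent standard deviations (and means)
#'
#' The population model: each latent is independent normal. Defaults emulate
#' a moderately variable adult cohort around the template geometry.
#' @param sd,mean named length-8 vectors over the latents.
#' @return list with `mean` and `sd`.
#' @export
latent_population <- function(sd = c(size_scale = 0.12, elongation = 0.15,
                                     chamber_scale = 0.07, wall_thickness_mm = 1.2,
                                     bump_1 = 3, bump_2 = 3, bump_3 = 3,
                                     bump_4 = 3),
                              mean = c(size_scale = 1, elongation = 1.6,
                                       chamber_scale = 0.65, wall_thickness_mm = 7,
                                       bump_1 = 0, bump_2 = 0, bump_3 = 0,
                                       bump_4 = 0)) {
  if (length(sd) != 8L || length(mean) != 8L) stop("mean/sd must have length 8")
  if (any(sd < 0)) stop("latent sd must be >= 0")
  list(mean = mean, sd = sd)
}

#' Generate a synthetic LV cohort
#'
#' Draws K latent-parameter vectors from the population model, builds one
#' watertight mesh per subject, and simulates the outcome and the two
#' clinical covariates (preLVMI from shell mass, LVEF from chamber scale).
#'
#' @param K number of subjects (>= 3); default matches the 66-subject study
#'   scale this generator emulates.
#' @param truth an [ground_truth()] object.
#' @param population an [latent_population()] object.
#' @param seed integer seed; the cohort is a pure function of it.
#' @param n_theta,n_phi mesh resolution per subject.
#' @param voxelize_mm if non-NULL, also store label volumes at this spacing.
#' @return an object of class `lv_synth_cohort` with elements `latents`
#'   (K x 8), `meshes`, `outcomes`, `covariates` (data.frame with pre_lvmi,
#'   one_year_lvmi, lvef), `truth`, `labels` (optional), `seed`.
#' @export
generate_cohort <- function(K = 66L, truth = ground_truth(),
                            population = latent_population(), seed = 1L,
                            n_theta = 56L, n_phi = 72L, voxelize_mm = NULL) {
  if (K < 3L) stop("K must be >= 3")
  stopifnot(inherits(truth, "lv_truth"))
  if (length(truth$beta) != length(population$mean))
    stop("beta and latent population dimensions do not conform")
  set.seed(seed)
  p <- length(population$mean)
  lat <- matrix(rnorm(K * p), K, p) %*% diag(population$sd, p) +
    matrix(population$mean, K, p, byrow = TRUE)
  colnames(lat) <- names(population$mean)
  # keep every draw geometrically valid without breaking linearity for
  # realistic SDs (bounds are ~5 sigma out at the defaults)
  lat[, "chamber_scale"] <- pmin(pmax(lat[, "chamber_scale"], 0.47), 0.90)
  lat[, "size_scale"] <- pmax(lat[, "size_scale"], 0.5)
  lat[, "wall_thickness_mm"] <- pmin(pmax(lat[, "wall_thickness_mm"], 3), 11)
  lat[, "elongation"] <- pmin(pmax(lat[, "elongation"], 1.15), 2.1)

  noise <- rnorm(K, 0, truth$noise_sd)
  outcomes <- truth$intercept + as.vector(lat %*% truth$beta) + noise

  cov_noise <- cbind(rnorm(K, 0, 5), rnorm(K, 0, 4))

  meshes <- vector("list", K)
  shell_vol <- numeric(K)
  for (k in seq_len(K)) {
    par_k <- latent_params(size_scale = lat[k, 1], elongation = lat[k, 2],
                           chamber_scale = lat[k, 3], wall_thickness_mm = lat[k, 4],
                           bump_amplitudes = lat[k, 5:8], seed = seed)
    meshes[[k]] <- generate_lv_mesh(par_k, n_theta = n_theta, n_phi = n_phi)
    shell_vol[k] <- surface_and_volume(meshes[[k]])$volume
  }
  # preLVMI ~ shell mass / BSA: 1.05 g/cm^3 myocardium over ~1.9 m^2, with a
  # gain putting the template near 120 g/m^2
  pre_lvmi <- 0.00206 * shell_vol + cov_noise[, 1]
  lvef <- 60 - 150 * (lat[, "chamber_scale"] - 0.65) + cov_noise[, 2]
  covariates <- data.frame(pre_lvmi = pre_lvmi,
                           one_year_lvmi = pre_lvmi * (1 + outcomes),
                           lvef = lvef)

  labels <- NULL
  if (!is.null(voxelize_mm))
    labels <- lapply(meshes, voxelize, spacing_mm = voxelize_mm)

  structure(list(latents = lat, meshes = meshes, outcomes = outcomes,
                 covariates = covariates, truth = truth, labels = labels,
                 seed = as.integer(seed)),
            class = "lv_synth_cohort")
}

#' @export
print.lv_synth_cohort <- function(x, ...) {
  cat(sprintf("lv_synth_cohort: %d subjects, outcome mean %.3f (sd %.3f)\n",
              length(x$outcomes), mean(x$outcomes), sd(x$outcomes)))
  invisible(x)
}

#' Flatten a synthetic cohort to its per-subject table
#' @param x an `lv_synth_cohort`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return data.frame with subject_id, pre_lvmi, one_year_lvmi, lvef,
#'   outcome and latent columns.
#' @export
as.data.frame.lv_synth_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  lat <- x$latents
  colnames(lat) <- paste0("latent_", seq_len(ncol(lat)))
  data.frame(subject_id = seq_along(x$outcomes),
             pre_lvmi = x$covariates$pre_lvmi,
             one_year_lvmi = x$covariates$one_year_lvmi,
             lvef = x$covariates$lvef,
             outcome = x$outcomes, lat)
}

#' Position of a fixed inner-wall bump site
#'
#' Returns the coordinates of one of the generator's fixed bump sites on the
#' (undeformed) endocardial surface, expressed relative to the mesh vertex
#' centroid — i.e. approximately in the frame of a centred, aligned cohort
#' cloud. Used to validate anatomical localization of outcome signal.
#'
#' @param site_index bump site (1-4).
#' @param params shape parameters defining the geometry (default template).
#' @return length-3 coordinate vector (mm).
#' @export
lv_bump_site <- function(site_index = 1L, params = latent_params()) {
  if (site_index < 1L || site_index > length(.lv_geom$bump_theta))
    stop("invalid bump site index")
  d <- .lv_dims(params)
  p <- .lv_ring(d$a_endo, d$c_endo, .lv_geom$bump_theta[site_index],
                .lv_geom$bump_phi[site_index])
  ctr <- colMeans(generate_lv_mesh(params)$vertices)
  as.vector(p) - ctr
}

#' Corrupt a label volume with cavities and islands
#'
#' Test fixture generator for the clean-up stage: carves `n_holes` spherical
#' cavities strictly inside the foreground and adds `n_islands` small
#' disconnected islands in the background. The input is not modified.
#'
#' @param volume an [lv_label()].
#' @param n_holes number of interior holes.
#' @param hole_diameter_vox hole diameter in voxels (odd recommended).
#' @param n_islands number of disconnected islands to add.
#' @param seed integer seed.
#' @return a list: `label` (corrupted [lv_label()]), `hole_voxels` (voxels
#'   removed), `island_voxels` (voxels added).
#' @export
corrupt_label <- function(volume, n_holes = 0L, hole_diameter_vox = 3L,
                          n_islands = 0L, seed = 1L) {
  stopifnot(inherits(volume, "lv_label"))
  set.seed(seed)
  g <- volume$grid
  dims <- dim(g)
  r <- (hole_diameter_vox - 1) / 2
  ball <- se_offsets_ball(hole_diameter_vox)
  removed <- 0L
  if (n_holes > 0L) {
    # valid centres: erosion by the hole ball, so holes sit strictly inside
    interior <- array(morph_cpp(as.vector(g), dims, ball, FALSE), dim = dims)
    centers <- matrix(0, 0, 3)
    cand <- which(interior == 1L, arr.ind = TRUE)
    if (nrow(cand) == 0L)
      stop("hole diameter exceeds label thickness; no valid hole centre")
    for (h in seq_len(n_holes)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        ctr <- cand[sample(nrow(cand), 1L), ]
        if (nrow(centers) == 0L ||
            min(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 3,
                                               byrow = TRUE))^2))) > hole_diameter_vox + 1) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", n_holes, " disjoint holes")
      centers <- rbind(centers, ctr)
      vox <- sweep(ball, 2, ctr, "+")
      g[vox] <- 0L
      removed <- removed + nrow(vox)
    }
  }
  added <- 0L
  if (n_islands > 0L) {
    # islands must stay clear of the label: dilate by a safety margin
    margin <- array(morph_cpp(as.vector(volume$grid), dims,
                              se_offsets_cube(7L), TRUE), dim = dims)
    bg <- which(margin == 0L, arr.ind = TRUE)
    inner <- bg[bg[, 1] > 1 & bg[, 1] < dims[1] & bg[, 2] > 1 & bg[, 2] < dims[2] &
                  bg[, 3] > 1 & bg[, 3] < dims[3], , drop = FALSE]
    if (nrow(inner) < n_islands) stop("no room for islands")
    placed <- matrix(0, 0, 3)
    for (s in seq_len(n_islands)) {
      repeat {
        ctr <- inner[sample(nrow(inner), 1L), ]
        if (nrow(placed) == 0L ||
            min(sqrt(rowSums((placed - matrix(ctr, nrow(placed), 3,
                                              byrow = TRUE))^2))) > 4) break
      }
      placed <- rbind(placed, ctr)
      g[ctr[1], ctr[2], ctr[3]] <- 1L
      added <- added + 1L
    }
  }
  list(label = lv_label(g, volume$spacing_mm, volume$origin_mm),
       hole_voxels = removed, island_voxels = added)
}
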