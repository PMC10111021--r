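# Corresponded, aligned point clouds and the mean shape: down-sampling,
# centering, reference selection, fixed-scale ICP, row reordering, mean
# shape and deviation vectors.

#' Ordered point cloud
#' @param points N x 3 coordinate matrix (mm).
#' @param corresponded logical flag set after row reordering against a
#'   template.
#' @param normals optional N x 3 unit surface normals carried from the
#'   source mesh (used by normal-aware correspondence).
#' @return an object of class `lv_cloud`.
#' @export
lv_cloud <- function(points, corresponded = FALSE, normals = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix")
  if (nrow(points) == 0L) stop("empty point cloud")
  if (any(!is.finite(points))) stop("non-finite coordinates")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(points))) stop("normals must match points")
  }
  structure(list(points = points, corresponded = isTRUE(corresponded),
                 normals = normals),
            class = "lv_cloud")
}

#' @export
print.lv_cloud <- function(x, ...) {
  cat(sprintf("lv_cloud: %d points%s\n", nrow(x$points),
              if (x$corresponded) " (corresponded)" else ""))
  invisible(x)
}

#' Extract the point matrix from a cloud, mesh or matrix
#' @param x an [lv_cloud()], [lv_mesh()] or N x 3 matrix.
#' @return N x 3 numeric matrix.
#' @export
cloud_points <- function(x) {
  if (inherits(x, "lv_cloud")) x$points
  else if (inherits(x, "lv_mesh")) x$vertices
  else as.matrix(x)
}

#' Uniformly down-sample a mesh or cloud to n points
#'
#' Two deterministic, unbiased uniform strategies:
#' * `"fps"` — farthest-point sampling: starting from the vertex farthest
#'   from the centroid (a stable landmark; the seed only breaks exact ties),
#'   repeatedly adds the point farthest from the current sample. Guarantees
#'   spatial uniformity, but the selected subset responds chaotically to
#'   small shape changes, which injects sampling jitter into downstream
#'   point correspondence.
#' * `"stride"` — an evenly spaced pick along the source vertex enumeration
#'   (the `uniform_down_sample` strategy of mesh-processing toolkits).
#'   Source vertex orderings follow surface sweeps or grid scans, so the
#'   pick is spatially stratified, and it varies smoothly with the
#'   underlying surface — samples of similar shapes track each other, which
#'   is what correspondence-based shape modelling needs.
#'
#' @param x an [lv_mesh()], [lv_cloud()] or point matrix with >= n points.
#' @param n number of points to keep (default 5000).
#' @param seed integer seed (tie-breaking for "fps"; unused by "stride").
#' @param method "fps" or "stride".
#' @return an [lv_cloud()] with exactly n points (surface normals carried
#'   over when `x` is a mesh).
#' @export
downsample <- function(x, n = 5000L, seed = 1L, method = c("fps", "stride")) {
  method <- match.arg(method)
  pts <- cloud_points(x)
  nrm <- if (inherits(x, "lv_mesh")) mesh_vertex_normals(x)
         else if (inherits(x, "lv_cloud")) x$normals
  if (n <= 0L) stop("n must be positive")
  if (nrow(pts) < n) stop("source has fewer than n points")
  if (nrow(pts) == n) return(lv_cloud(pts, normals = nrm))
  if (method == "stride") {
    idx <- unique(round(seq(1, nrow(pts), length.out = n)))
    # rounding collisions are possible only when n ~ nrow(pts); top up
    while (length(idx) < n)
      idx <- sort(union(idx, setdiff(seq_len(nrow(pts)), idx)[seq_len(n - length(idx))]))
  } else {
    ctr <- colMeans(pts)
    d2 <- rowSums(sweep(pts, 2, ctr)^2)
    cand <- which(d2 >= max(d2) - 1e-12)
    set.seed(seed)
    start <- if (length(cand) == 1L) cand else sample(cand, 1L)
    idx <- fps_cpp(pts, as.integer(n), as.integer(start))
  }
  lv_cloud(pts[idx, , drop = FALSE],
           normals = if (!is.null(nrm)) nrm[idx, , drop = FALSE])
}

#' Move a cloud's centre of mass to the origin
#' @param cloud an [lv_cloud()] (or point matrix).
#' @return centred [lv_cloud()].
#' @export
center_cloud <- function(cloud) {
  pts <- cloud_points(cloud)
  lv_cloud(sweep(pts, 2, colMeans(pts), "-"),
           corresponded = inherits(cloud, "lv_cloud") && cloud$corresponded,
           normals = if (inherits(cloud, "lv_cloud")) cloud$normals)
}

#' Select the cohort reference shape
#'
#' Returns the index of the mesh whose surface area s and volume v are
#' jointly closest to the cohort averages, minimizing
#' (s - s_bar)^2 + (v - v_bar)^2. Ties break toward the lowest index.
#'
#' @param meshes list of closed [lv_mesh()] objects.
#' @return 1-based index of the reference shape.
#' @export
select_reference <- function(meshes) {
  if (length(meshes) == 0L) stop("no meshes")
  sv <- vapply(meshes, function(m) unlist(surface_and_volume(m)), numeric(2))
  s <- sv[1, ]
  v <- sv[2, ]
  crit <- (s - mean(s))^2 + (v - mean(v))^2
  unname(which.min(crit))
}

#' Rigid ICP alignment with fixed scale
#'
#' Iterative closest point: alternates nearest-neighbour correspondence from
#' `p` into `q` with the least-squares rigid transform (SVD/Procrustes
#' step). Scale is fixed at 1 to conserve ventricular size. The global error
#' is E = sum of squared residuals over the current correspondence; E is
#' non-increasing across iterations.
#'
#' @param p moving cloud ([lv_cloud()] or matrix).
#' @param q fixed cloud.
#' @param max_iters iteration cap.
#' @param tol relative change in E (mm^2) declaring convergence.
#' @param init "auto" (default) screens identity plus the four
#'   proper-rotation principal-axes pre-alignments by one-step error and
#'   starts from the best, which removes the azimuthal local minima of the
#'   near-rotationally-symmetric ventricle; "identity" starts unaligned.
#' @param trim_fraction fraction of correspondences (smallest residuals)
#'   used in each transform estimate. 1 (default) is classical ICP; values
#'   slightly below 1 give trimmed ICP, which stops localized shape
#'   differences (e.g. wall bumps) from tilting the rigid pose. E and the
#'   monotonicity guarantee always refer to the full correspondence set
#'   under trim 1; with trimming E is still reported over all points.
#' @return list with `transform` (class `lv_transform`: R, T, s = 1, E,
#'   residuals, iterations, converged, E_history) and `aligned`
#'   ([lv_cloud()], p after the transform).
#' @export
icp_align <- function(p, q, max_iters = 100L, tol = 1e-8,
                      init = c("auto", "identity"), trim_fraction = 1) {
  init <- match.arg(init)
  if (trim_fraction <= 0 || trim_fraction > 1)
    stop("trim_fraction must be in (0, 1]")
  P0 <- cloud_points(p)
  Q <- cloud_points(q)
  R_init <- diag(3)
  T_init <- c(0, 0, 0)
  if (init == "auto") {
    # candidate pre-alignments: identity plus the four proper-rotation
    # principal-axes alignments; keep the one with the lowest one-step error
    mu_p <- colMeans(P0)
    mu_q <- colMeans(Q)
    fix_det <- function(V) { if (det(V) < 0) V[, 3] <- -V[, 3]; V }
    Vp <- fix_det(eigen(cov(P0), symmetric = TRUE)$vectors)
    Vq <- fix_det(eigen(cov(Q), symmetric = TRUE)$vectors)
    signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    best_E <- sum(nn_cpp(P0, Q)$dist2)
    for (s in signs) {
      Rc <- Vq %*% diag(s) %*% t(Vp)
      Pc <- sweep(sweep(P0, 2, mu_p) %*% t(Rc), 2, mu_q, "+")
      E0 <- sum(nn_cpp(Pc, Q)$dist2)
      if (E0 < best_E) {
        best_E <- E0
        R_init <- Rc
        T_init <- as.vector(mu_q - Rc %*% mu_p)
      }
    }
  }
  Racc <- R_init
  Tacc <- T_init
  Pc <- sweep(P0 %*% t(R_init), 2, T_init, "+")
  E_hist <- numeric(0)
  E_prev <- Inf
  converged <- FALSE
  iters <- 0L
  nn <- NULL
  for (it in seq_len(max_iters)) {
    nn <- nn_cpp(Pc, Q)
    E <- sum(nn$dist2)
    E_hist <- c(E_hist, E)
    iters <- it
    if (E <= 1e-14 * nrow(P0) ||
        (is.finite(E_prev) && abs(E_prev - E) <= tol * max(E_prev, 1e-300))) {
      converged <- TRUE
      break
    }
    E_prev <- E
    keep <- seq_len(nrow(Pc))
    if (trim_fraction < 1) {
      n_keep <- max(3L, as.integer(round(trim_fraction * nrow(Pc))))
      keep <- order(nn$dist2)[seq_len(n_keep)]
    }
    Pk <- Pc[keep, , drop = FALSE]
    Qm <- Q[nn$idx[keep], , drop = FALSE]
    mu_p <- colMeans(Pk)
    mu_q <- colMeans(Qm)
    H <- crossprod(sweep(Pk, 2, mu_p), sweep(Qm, 2, mu_q))
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    Ri <- sv$v %*% D %*% t(sv$u)
    # transform fixed point: the update moves no point more than ~1e-6 mm,
    # so further iterations only flicker the correspondence
    scale_mm <- max(sqrt(rowSums(Pc^2)))
    if (max(abs(Ri - diag(3))) * scale_mm + sqrt(sum((mu_q - mu_p)^2)) < 1e-6) {
      converged <- TRUE
      break
    }
    Pc <- sweep(sweep(Pc, 2, mu_p) %*% t(Ri), 2, mu_q, "+")
    Racc <- Ri %*% Racc
    Tacc <- as.vector(Ri %*% (Tacc - mu_p)) + mu_q
  }
  nn <- nn_cpp(Pc, Q)
  E <- sum(nn$dist2)
  if (!converged)
    attr(E, "warning") <- sprintf("ICP did not converge in %d iterations (E = %g)",
                                  max_iters, E)
  transform <- structure(list(R = Racc, T = Tacc, s = 1, E = E,
                              residuals = sqrt(nn$dist2),
                              iterations = iters, converged = converged,
                              E_history = E_hist),
                         class = "lv_transform")
  nrm_p <- if (inherits(p, "lv_cloud") && !is.null(p$normals))
    p$normals %*% t(Racc)
  list(transform = transform, aligned = lv_cloud(Pc, normals = nrm_p))
}

#' Apply a rigid transform to points
#' @param transform an `lv_transform`.
#' @param x cloud or point matrix.
#' @return transformed [lv_cloud()].
#' @export
apply_transform <- function(transform, x) {
  pts <- cloud_points(x)
  nrm <- if (inherits(x, "lv_cloud") && !is.null(x$normals))
    x$normals %*% t(transform$R)
  lv_cloud(sweep(pts %*% t(transform$R), 2, transform$T, "+"), normals = nrm)
}

#' Reorder a cloud's rows to correspond with a template
#'
#' One-to-one assignment of cloud points to template rows. The default
#' ("assignment") solves the linear assignment problem on squared distances
#' to near-optimality with an auction algorithm, which spreads the
#' unavoidable density mismatch between unequal-sized shapes smoothly
#' instead of concentrating it in a few distant matches. "mutual_greedy"
#' locks mutual nearest neighbours first and matches the remaining rows
#' greedily in ascending distance order; "greedy_global" is the global
#' greedy alone. Row i of the result is the cloud point assigned to template
#' point i; every method returns a bijection.
#'
#' @param cloud an [lv_cloud()] already aligned to the template.
#' @param template an [lv_cloud()] with the same number of points.
#' @param method assignment strategy.
#' @param normal_weight mm of positional cost per unit of normal mismatch in
#'   the assignment cost (used when both clouds carry normals; 0 disables).
#' @param scale_invariant match in a size-normalized space (each cloud
#'   divided by its RMS radius) so that a pure size difference between
#'   fixed-scale clouds does not force matches to migrate; the returned
#'   coordinates are always the original, unscaled points.
#' @return reordered [lv_cloud()] with `corresponded = TRUE`.
#' @export
correspond <- function(cloud, template,
                       method = c("assignment", "mutual_greedy", "greedy_global"),
                       normal_weight = 4, scale_invariant = TRUE) {
  method <- match.arg(method)
  cp <- cloud_points(cloud)
  tp <- cloud_points(template)
  if (nrow(cp) != nrow(tp)) stop("cloud and template must have equal N")
  code <- match(method, c("mutual_greedy", "greedy_global", "assignment")) - 1L
  empty <- matrix(numeric(), 0, 3)
  cn <- if (inherits(cloud, "lv_cloud") && !is.null(cloud$normals))
    cloud$normals else empty
  tn <- if (inherits(template, "lv_cloud") && !is.null(template$normals))
    template$normals else empty
  cpm <- cp
  tpm <- tp
  if (scale_invariant) {
    # anatomy, not absolute size, defines correspondence: normalize each
    # cloud's RMS radius about its centroid for the matching metric only
    rms <- function(p) sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
    s_t <- rms(tp)
    cpm <- sweep(cp, 2, colMeans(cp)) * (s_t / rms(cp))
    tpm <- sweep(tp, 2, colMeans(tp))
  }
  perm <- match_points_cpp(tpm, cpm, code, tn, cn, normal_weight)
  lv_cloud(cp[perm, , drop = FALSE], corresponded = TRUE,
           normals = if (nrow(cn)) cn[perm, , drop = FALSE])
}

#' Pointwise mean shape of corresponded clouds
#' @param clouds non-empty list of corresponded [lv_cloud()]s of equal N.
#' @return the mean [lv_cloud()].
#' @export
mean_shape <- function(clouds) {
  if (length(clouds) == 0L) stop("empty cloud list")
  mats <- lapply(clouds, cloud_points)
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("clouds have mismatched N")
  nrms <- lapply(clouds, function(cl)
    if (inherits(cl, "lv_cloud")) cl$normals)
  mnrm <- NULL
  if (!any(vapply(nrms, is.null, logical(1)))) {
    mnrm <- Reduce(`+`, nrms) / length(nrms)
    len <- sqrt(rowSums(mnrm^2))
    len[len < 1e-12] <- 1
    mnrm <- mnrm / len
  }
  lv_cloud(Reduce(`+`, mats) / length(mats), corresponded = TRUE,
           normals = mnrm)
}

flatten_cloud <- function(x) as.vector(t(cloud_points(x)))

#' Build a corresponded cohort dataset
#'
#' Runs the full shape-model construction: down-sample each mesh to N
#' points, centre, select the reference shape, ICP-align everything to the
#' reference and reorder rows against it, compute the mean shape, then (per
#' refinement pass) realign and re-correspond every cloud to the mean and
#' recompute it. Deviation vectors are the flattened clouds minus the
#' flattened final mean.
#'
#' @param meshes list of closed [lv_mesh()], one per subject.
#' @param outcomes numeric outcome per subject.
#' @param covariates optional data.frame (pre_lvmi, lvef, ...) per subject.
#' @param n_points points per cloud (default 5000).
#' @param seed integer seed (down-sampling start).
#' @param refine_passes realignment passes against the mean (default 1).
#' @param max_iters,tol ICP controls.
#' @param match_method correspondence strategy, see [correspond()].
#' @param icp_trim trim fraction for the per-subject ICP pose estimates
#'   (default 0.9): localized wall differences then cannot tilt the pose.
#' @param downsample_method down-sampling strategy, see [downsample()];
#'   default "stride" because corresponded modelling needs sample sets that
#'   vary smoothly across subjects.
#' @return an object of class `lv_cohort`: `clouds` (list of N x 3
#'   matrices), `mean_shape` (N x 3), `deviations` (K x 3N, row-major
#'   x1 y1 z1 x2 ...), `outcomes`, `covariates`, `reference_index`,
#'   `icp_report` (per-subject error and iterations).
#' @export
build_cohort <- function(meshes, outcomes, covariates = NULL, n_points = 5000L,
                         seed = 1L, refine_passes = 1L, max_iters = 100L,
                         tol = 1e-8, match_method = "assignment",
                         downsample_method = "stride", icp_trim = 0.9) {
  K <- length(meshes)
  if (K < 2L) stop("need at least two subjects")
  if (length(outcomes) != K) stop("one outcome per subject required")
  clouds <- lapply(meshes, function(m)
    center_cloud(downsample(m, n_points, seed, method = downsample_method)))
  ref <- select_reference(meshes)
  template <- clouds[[ref]]
  report <- data.frame(subject = seq_len(K), E = NA_real_, iterations = NA_integer_)
  aligned <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- icp_align(clouds[[k]], template, max_iters = max_iters, tol = tol,
                     trim_fraction = icp_trim)
    aligned[[k]] <- correspond(fit$aligned, template, match_method)
    report$E[k] <- fit$transform$E
    report$iterations[k] <- fit$transform$iterations
  }
  mshape <- mean_shape(aligned)
  for (pass in seq_len(refine_passes)) {
    for (k in seq_len(K)) {
      fit <- icp_align(aligned[[k]], mshape, max_iters = max_iters, tol = tol,
                       trim_fraction = icp_trim)
      aligned[[k]] <- correspond(fit$aligned, mshape, match_method)
      report$E[k] <- fit$transform$E
      report$iterations[k] <- fit$transform$iterations
    }
    mshape <- mean_shape(aligned)
  }
  mean_flat <- flatten_cloud(mshape)
  dev <- t(vapply(aligned, function(cl) flatten_cloud(cl) - mean_flat,
                  numeric(3L * n_points)))
  structure(list(clouds = lapply(aligned, cloud_points),
                 mean_shape = cloud_points(mshape),
                 deviations = dev, outcomes = outcomes,
                 covariates = covariates, reference_index = ref,
                 icp_report = report, n_points = as.integer(n_points)),
            class = "lv_cohort")
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat(sprintf("lv_cohort: %d subjects x %d points (reference #%d)\n",
              nrow(x$deviations), x$n_points, x$reference_index))
  invisible(x)
}
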