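# Independent reference implementations used as oracles. These deliberately
# use the most literal formulation available (loops, normal equations,
# textbook NIPALS) and never call the package's own fast paths.

# icosphere: subdivided icosahedron projected onto a sphere
make_icosphere <- function(radius = 10, subdiv = 3) {
  t_ <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t_, 0), c(1, t_, 0), c(-1, -t_, 0), c(1, -t_, 0),
    c(0, -1, t_), c(0, 1, t_), c(0, -1, -t_), c(0, 1, -t_),
    c(t_, 0, -1), c(t_, 0, 1), c(-t_, 0, -1), c(-t_, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  lv_mesh(v, f)
}

# binary sphere label: voxel centres within radius_vox of the grid centre
make_sphere_label <- function(radius_vox = 10, pad = 3, spacing = c(1, 1, 1)) {
  n <- 2 * (radius_vox + pad) + 1
  ctr <- (n + 1) / 2
  g <- array(0L, dim = c(n, n, n))
  idx <- which(g == 0L, arr.ind = TRUE)
  d2 <- (idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2 + (idx[, 3] - ctr)^2
  g[idx[d2 <= radius_vox^2, , drop = FALSE]] <- 1L
  lv_label(g, spacing_mm = spacing)
}

# volume of a truncated spheroid (semi-axes a, a, c) below the plane z = h
vol_truncated_spheroid <- function(a, c_, h) {
  pi * a^2 * (h - h^3 / (3 * c_^2) + 2 * c_ / 3)
}

# analytic volume of the generator's shell for bump-free parameters
shell_volume_analytic <- function(params) {
  a <- 25 * params$size_scale
  c_ <- a * params$elongation
  zb <- 0.45 * c_
  a_en <- params$chamber_scale * a - (params$wall_thickness_mm - 7)
  c_en <- params$chamber_scale * c_
  vol_truncated_spheroid(a, c_, zb) - vol_truncated_spheroid(a_en, c_en, zb)
}

# brute-force nearest neighbour
nn_brute <- function(query, target) {
  idx <- integer(nrow(query))
  d2 <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- colSums((t(target) - query[i, ])^2)
    idx[i] <- which.min(dd)
    d2[i] <- dd[idx[i]]
  }
  list(idx = idx, dist2 = d2)
}

# literal NIPALS PLS1 with X deflation (textbook form)
nipals_reference <- function(X, y, A) {
  X <- scale(X, scale = FALSE)
  y <- y - mean(y)
  p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, nrow(X), A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- t(X) %*% y
    w <- w / sqrt(sum(w^2))
    t_ <- X %*% w
    tt <- sum(t_^2)
    p_ <- t(X) %*% t_ / tt
    q[a] <- sum(y * t_) / tt
    X <- X - t_ %*% t(p_)
    y <- y - q[a] * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
  }
  list(W = W, P = P, scores = Tm, q = q)
}

# explicit morphology with a cube structuring element, zero-padded
morph_reference <- function(grid, r, op) {
  d <- dim(grid)
  out <- array(0L, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    i0 <- max(1, i - r); i1 <- min(d[1], i + r)
    j0 <- max(1, j - r); j1 <- min(d[2], j + r)
    k0 <- max(1, k - r); k1 <- min(d[3], k + r)
    block <- grid[i0:i1, j0:j1, k0:k1]
    n_in_grid <- length(block)
    n_total <- (2 * r + 1)^3
    if (op == "dilate") out[i, j, k] <- as.integer(any(block == 1L))
    else out[i, j, k] <- as.integer(all(block == 1L) && n_in_grid == n_total)
  }
  out
}

# brute-force majority filter with a ball footprint, zero-padded
median_reference <- function(grid, diameter) {
  d <- dim(grid)
  r <- floor(diameter / 2)
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  off <- off[rowSums(off^2) <= (diameter / 2)^2, , drop = FALSE]
  m <- nrow(off)
  out <- array(0L, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    cnt <- 0L
    for (t in seq_len(m)) {
      ii <- i + off[t, 1]; jj <- j + off[t, 2]; kk <- k + off[t, 3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3])
        cnt <- cnt + grid[ii, jj, kk]
    }
    out[i, j, k] <- as.integer(2L * cnt > m)
  }
  out
}

# sequential nearest-neighbour-with-removal matching (greedy baseline)
greedy_removal_match <- function(tmpl, cloud) {
  n <- nrow(tmpl)
  free <- rep(TRUE, n)
  perm <- integer(n)
  for (i in seq_len(n)) {
    dd <- colSums((t(cloud) - tmpl[i, ])^2)
    dd[!free] <- Inf
    perm[i] <- which.min(dd)
    free[perm[i]] <- FALSE
  }
  perm
}

match_cost <- function(tmpl, cloud, perm) {
  sum((tmpl - cloud[perm, , drop = FALSE])^2)
}

random_rotation <- function(max_deg = 30) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}
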