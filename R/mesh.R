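#' Triangulated surface mesh
#'
#' Container for a triangulated surface in physical units (mm). Vertices are
#' a V x 3 coordinate matrix, faces an F x 3 matrix of 1-based vertex
#' indices. For closed meshes the convention is outward orientation, i.e.
#' positive signed volume.
#'
#' @param vertices numeric V x 3 matrix of coordinates (mm).
#' @param faces integer F x 3 matrix of vertex indices (1-based).
#' @return An object of class `lv_mesh`.
#' @export
lv_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices out of range")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, faces = faces), class = "lv_mesh")
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("lv_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Test whether a mesh is a closed, consistently oriented surface
#'
#' A mesh is closed iff every undirected edge is shared by exactly two faces
#' and the two incident faces traverse it in opposite directions.
#'
#' @param mesh an [lv_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  from <- as.numeric(c(f[, 1], f[, 2], f[, 3]))
  to   <- as.numeric(c(f[, 2], f[, 3], f[, 1]))
  # every directed edge must appear exactly once, and its reverse once
  # (numeric keys are exact: indices stay far below 2^26)
  nv <- nrow(mesh$vertices) + 1
  key     <- from * nv + to
  rev_key <- to * nv + from
  !anyDuplicated(key) && all(rev_key %in% key)
}

#' Surface area and enclosed volume of a closed mesh
#'
#' Area is the sum of triangle areas; volume is the divergence-theorem signed
#' volume (positive for outward-oriented closed surfaces). These are the two
#' shape summaries used to pick the cohort reference shape.
#'
#' @param mesh an [lv_mesh()]; must be closed.
#' @return A list with elements `area` (mm^2) and `volume` (mm^3).
#' @export
surface_and_volume <- function(mesh) {
  if (!mesh_is_closed(mesh))
    stop("mesh is not a closed oriented surface")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  volume <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
                a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
                a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  list(area = area, volume = volume)
}

#' Area-weighted outward vertex normals of a mesh
#' @param mesh an [lv_mesh()].
#' @return V x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])  # 2x area weighting
  nrm <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    acc <- rowsum(fn, group = f[, j], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    nrm[idx, ] <- nrm[idx, ] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-300] <- 1
  nrm / len
}

#' Binary label volume
#'
#' A 3D binary grid with physical voxel spacing and origin. Voxel (i, j, k)
#' (1-based array index) is centred at `origin + (c(i, j, k) - 1) * spacing`
#' in mm.
#'
#' @param grid 3D array containing only 0/1 (or logical).
#' @param spacing_mm positive length-3 voxel spacing (mm).
#' @param origin_mm length-3 position of the first voxel centre (mm).
#' @return An object of class `lv_label`.
#' @export
lv_label <- function(grid, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  g <- array(as.integer(grid != 0), dim = dim(grid))
  if (!all(grid %in% c(0, 1, TRUE, FALSE))) stop("grid must be binary")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  if (length(origin_mm) != 3L) stop("origin_mm must have length 3")
  structure(list(grid = g, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "lv_label")
}

#' @export
print.lv_label <- function(x, ...) {
  cat(sprintf("lv_label: %s grid, spacing (%s) mm, %d foreground voxels\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing_mm), collapse = ", "),
              sum(x$grid)))
  invisible(x)
}

label_voxel_volume <- function(label) prod(label$spacing_mm)

#' Physical volume of a label (foreground voxel count times voxel volume)
#' @param label an [lv_label()].
#' @return volume in mm^3.
#' @export
label_volume <- function(label) sum(label$grid) * label_voxel_volume(label)
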