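# Post-segmentation label clean-up and surface extraction. Fixed stage
# order: closing -> median smoothing -> largest connected component ->
# iso-surfacing -> Laplacian smoothing.

#' Structuring-element offsets: cube of given diameter
#' @param diameter_vox odd cube side in voxels.
#' @return integer m x 3 matrix of voxel offsets.
#' @export
se_offsets_cube <- function(diameter_vox = 5L) {
  if (diameter_vox %% 2L != 1L) stop("structuring-element diameter must be odd")
  r <- (diameter_vox - 1L) / 2L
  as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
}

#' Structuring-element offsets: ball of given diameter
#' @param diameter_vox ball diameter in voxels.
#' @return integer m x 3 matrix of voxel offsets with norm <= diameter/2.
#' @export
se_offsets_ball <- function(diameter_vox = 5L) {
  r <- floor(diameter_vox / 2)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= (diameter_vox / 2)^2, , drop = FALSE]
}

.check_nonempty <- function(volume) {
  stopifnot(inherits(volume, "lv_label"))
  if (sum(volume$grid) == 0L) stop("empty label volume")
  invisible(volume)
}

#' Morphological closing of a binary label
#'
#' Dilation followed by erosion with a cubic structuring element, removing
#' internal cavities smaller than the element (default 5-voxel cube).
#'
#' @param volume an [lv_label()].
#' @param cube_diameter_vox odd cube diameter in voxels.
#' @return closed [lv_label()].
#' @export
close_label <- function(volume, cube_diameter_vox = 5L) {
  .check_nonempty(volume)
  se <- se_offsets_cube(cube_diameter_vox)
  r <- (cube_diameter_vox - 1L) / 2L
  # pad by the element radius so the dilation can grow past the original
  # extent: closing then behaves as on an unbounded background, and labels
  # touching the grid boundary are not eroded away
  dims <- dim(volume$grid)
  pd <- dims + 2L * r
  padded <- array(0L, dim = pd)
  padded[r + seq_len(dims[1]), r + seq_len(dims[2]), r + seq_len(dims[3])] <-
    volume$grid
  d <- morph_cpp(as.vector(padded), pd, se, TRUE)
  e <- array(morph_cpp(d, pd, se, FALSE), dim = pd)
  out <- e[r + seq_len(dims[1]), r + seq_len(dims[2]), r + seq_len(dims[3])]
  lv_label(array(out, dim = dims), volume$spacing_mm, volume$origin_mm)
}

#' Median (majority) smoothing of a binary label
#'
#' Each voxel is replaced by the majority value within a ball-shaped
#' footprint (default 5 voxels in diameter); the boundary is zero-padded.
#'
#' @param volume an [lv_label()].
#' @param ball_diameter_vox footprint diameter in voxels.
#' @return smoothed [lv_label()].
#' @export
median_smooth <- function(volume, ball_diameter_vox = 5L) {
  .check_nonempty(volume)
  se <- se_offsets_ball(ball_diameter_vox)
  dims <- dim(volume$grid)
  m <- median_cpp(as.vector(volume$grid), dims, se)
  lv_label(array(m, dim = dims), volume$spacing_mm, volume$origin_mm)
}

#' Keep only the largest 26-connected component
#'
#' Removes disconnected islands. Ties on component size are broken toward
#' the lowest component label, i.e. the component discovered first in raster
#' scan order.
#'
#' @param volume an [lv_label()] with at least one foreground voxel.
#' @return single-component [lv_label()].
#' @export
largest_component <- function(volume) {
  .check_nonempty(volume)
  dims <- dim(volume$grid)
  lab <- components_cpp(as.vector(volume$grid), dims)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # first maximum = lowest label index
  lv_label(array(as.integer(lab == keep), dim = dims),
           volume$spacing_mm, volume$origin_mm)
}

#' Full label clean-up: closing, median smoothing, largest component
#' @param volume an [lv_label()].
#' @param cube_diameter_vox closing structuring-element diameter.
#' @param ball_diameter_vox median-filter footprint diameter.
#' @return cleaned [lv_label()].
#' @export
clean_label <- function(volume, cube_diameter_vox = 5L, ball_diameter_vox = 5L) {
  volume <- close_label(volume, cube_diameter_vox)
  volume <- median_smooth(volume, ball_diameter_vox)
  largest_component(volume)
}

#' Extract a smoothed surface mesh from a binary label
#'
#' Iso-surfaces the binary grid at level 0.5 (marching-tetrahedra variant of
#' marching cubes, watertight by construction), maps vertices to physical mm
#' via spacing and origin, then applies uniform Laplacian smoothing: each
#' iteration moves every vertex toward the mean of its connected neighbours,
#' scaled by the relaxation factor.
#'
#' @param volume an [lv_label()].
#' @param smooth_iterations number of Laplacian iterations (0 = raw
#'   iso-surface).
#' @param relaxation relaxation factor in \[0, 1\].
#' @return an [lv_mesh()] in mm. A warning is raised if the raw iso-surface
#'   is not closed.
#' @export
extract_surface <- function(volume, smooth_iterations = 20L, relaxation = 0.1) {
  .check_nonempty(volume)
  if (relaxation < 0 || relaxation > 1) stop("relaxation must be in [0, 1]")
  dims <- dim(volume$grid)
  mc <- march_tets_cpp(as.numeric(volume$grid), dims, 0.5)
  if (nrow(mc$vertices) == 0L) stop("no iso-surface found")
  verts <- sweep(sweep(mc$vertices, 2, volume$spacing_mm, "*"),
                 2, volume$origin_mm, "+")
  mesh <- lv_mesh(verts, mc$faces)
  if (!mesh_is_closed(mesh))
    warning("iso-surface is not closed; label may touch the grid boundary")
  if (smooth_iterations > 0L)
    mesh$vertices <- smooth_mesh_cpp(mesh$vertices, mesh$faces,
                                     as.integer(smooth_iterations), relaxation)
  mesh
}
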