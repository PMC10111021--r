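# Minimal readers/writers for the three interchange formats the pipeline
# touches: NRRD (binary label volumes), STL (surface meshes) and PLY (point
# clouds / meshes). Only the subsets the pipeline produces are supported.

#' Write a label volume as NRRD
#'
#' Writes an NRRD0004 file with `space directions` encoding the voxel
#' spacing and `space origin` the first voxel centre. Encoding is either
#' `raw` (unsigned char) or `ascii`.
#'
#' @param label an [lv_label()].
#' @param path output path.
#' @param encoding "raw" or "ascii".
#' @export
write_nrrd <- function(label, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(label, "lv_label"))
  d <- dim(label$grid)
  sp <- label$spacing_mm
  hdr <- c(
    "NRRD0004",
    "# generated by lvssm",
    "type: unsigned char",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            sp[1], sp[2], sp[3]),
    "kinds: domain domain domain",
    sprintf("encoding: %s", encoding),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            label$origin_mm[1], label$origin_mm[2], label$origin_mm[3])
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines("", con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.raw(as.vector(label$grid)), con)
  } else {
    writeLines(paste(as.vector(label$grid), collapse = " "), con, sep = "\n")
  }
  invisible(path)
}

#' Read a label volume from NRRD
#'
#' Supports 3D `unsigned char`/`uchar`/`int` data in `raw` or `ascii`
#' encoding with axis-aligned `space directions`.
#'
#' @param path NRRD file path.
#' @return an [lv_label()].
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0L || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) == 2L)
      fields[[trimws(kv[1])]] <- trimws(sub("^=", "", kv[2]))
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported")
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  n <- prod(sizes)
  if (identical(enc, "raw")) {
    if (!type %in% c("unsigned char", "uchar", "uint8", "uint8_t"))
      stop("unsupported raw NRRD type: ", type)
    vals <- as.integer(readBin(con, "raw", n = n))
  } else if (identical(enc, "ascii") || identical(enc, "text")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    nums <- regmatches(fields[["space directions"]],
                       gregexpr("[-0-9.eE+]+", fields[["space directions"]]))[[1]]
    m <- matrix(as.numeric(nums), nrow = 3, byrow = TRUE)
    if (any(abs(m[row(m) != col(m)]) > 1e-12))
      stop("only axis-aligned space directions supported")
    spacing <- diag(m)
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(regmatches(fields[["space origin"]],
                                    gregexpr("[-0-9.eE+]+", fields[["space origin"]]))[[1]])
  }
  lv_label(array(vals, dim = sizes), spacing_mm = spacing, origin_mm = origin)
}

#' Write a mesh as ASCII STL
#' @param mesh an [lv_mesh()].
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  cat("solid lvssm\n", file = con)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  txt <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
  writeLines(txt, con)
  cat("endsolid lvssm\n", file = con)
  invisible(path)
}

#' Read an ASCII STL mesh
#'
#' Vertices repeated across facets are merged on exact coordinate equality.
#' @param path STL file path.
#' @return an [lv_mesh()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: ", path)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  lv_mesh(verts, faces)
}

#' Write a point cloud or mesh as ASCII PLY
#' @param x an [lv_mesh()] or a point matrix / [lv_cloud()].
#' @param path output path.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "lv_mesh")) {
    v <- x$vertices
    f <- x$faces
  } else {
    v <- cloud_points(x)
    f <- matrix(integer(), 0, 3)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path PLY file path.
#' @return an [lv_mesh()] if faces are present, otherwise an [lv_cloud()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY supported: ", path)
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nfl <- grep("^element face", lines, value = TRUE)
  nf <- if (length(nfl)) as.integer(sub("element face ", "", nfl)) else 0L
  vl <- lines[(endh + 1):(endh + nv)]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[1:3])))
  if (nf > 0) {
    fl <- lines[(endh + nv + 1):(endh + nv + nf)]
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) as.integer(p[2:4]) + 1L))
    lv_mesh(v, f)
  } else {
    lv_cloud(v)
  }
}
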