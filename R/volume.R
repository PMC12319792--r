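#' 3D scalar volume
#'
#' Single-channel 3D image grid plus a 4x4 voxel-to-world affine (mm).
#' Voxel centers sit at integer 0-based indices in voxel space; the affine
#' maps those indices to world coordinates.
#'
#' @param data 3D numeric array (`H x W x D`).
#' @param affine invertible 4x4 voxel-to-world matrix; defaults to identity.
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(dim(data) < 2)) stop("each volume dimension must be >= 2")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) stop("affine is not invertible")
  structure(list(data = data, affine = affine), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %s grid, voxel size %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3), collapse = " x ")))
  invisible(x)
}

world_to_voxel <- function(points, affine) {
  points <- matrix(as.numeric(points), ncol = 3)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Trilinear sampling of a volume at world-space points
#'
#' Points are mapped to voxel space through the inverse affine and sampled
#' with standard trilinear interpolation. Points outside the grid clamp to
#' the boundary; the number of clamped points is reported in the
#' `"n_clamped"` attribute.
#'
#' @param volume a [scalar_volume()], or a pyramid level (list with a 4D
#'   `data` array `H x W x D x C` and an `affine`).
#' @param points `n x 3` matrix of world-space coordinates (mm).
#' @return `n x C` matrix of interpolated values (C = 1 for scalar volumes).
#' @export
trilinear_sample <- function(volume, points) {
  dat <- volume$data
  d <- dim(dat)
  if (length(d) == 3) d <- c(d, 1L)
  vox <- world_to_voxel(points, volume$affine)
  lo <- sweep(vox, 2, c(0, 0, 0), "<")
  hi <- sweep(vox, 2, d[1:3] - 1, ">")
  n_clamped <- sum(rowSums(lo | hi) > 0)
  out <- cpp_trilinear(as.numeric(dat), as.integer(d), vox)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Rasterize nested closed surfaces into a label volume
#'
#' Voxel centers are classified by parity inside/outside tests as
#' `0` background, `1` gray (between the surfaces), `2` white (inside the
#' inner surface). The labels partition the grid.
#'
#' @param inner,outer closed [triangle_mesh()] objects, inner nested in outer.
#' @param grid_shape integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a [scalar_volume()] with integer labels.
#' @export
rasterize_occupancy <- function(inner, outer, grid_shape, affine = diag(4)) {
  if (!is_closed_manifold(inner)) stop("inner mesh is not a closed 2-manifold")
  if (!is_closed_manifold(outer)) stop("outer mesh is not a closed 2-manifold")
  grid_shape <- as.integer(grid_shape)
  vin <- world_to_voxel(inner$vertices, affine)
  vout <- world_to_voxel(outer$vertices, affine)
  inside_in <- cpp_rasterize_parity(vin, inner$faces - 1L,
                                    grid_shape[1], grid_shape[2], grid_shape[3])
  inside_out <- cpp_rasterize_parity(vout, outer$faces - 1L,
                                     grid_shape[1], grid_shape[2], grid_shape[3])
  lab <- integer(prod(grid_shape))
  lab[inside_out == 1L] <- 1L
  lab[inside_in == 1L] <- 2L
  scalar_volume(array(lab, grid_shape), affine)
}

# ---- volume file I/O -------------------------------------------------------

#' Read a 3D volume (NIfTI-1 or MGH/.mgz)
#'
#' @param path file path; `.mgz` / `.mgh` files use the MGH reader, anything
#'   else is read as NIfTI via RNifti.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mgz", "mgh")) return(read_mgh(path))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  scalar_volume(array(as.numeric(img), dim(img)[1:3]), aff)
}

#' Write a volume as NIfTI-1
#'
#' @param volume a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# MGH format (optionally gzip-compressed as .mgz); big-endian, 284-byte header
read_mgh <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 7, size = 4, endian = "big")
  if (hdr[1] != 1L) stop("unsupported MGH version at byte offset 0: ", hdr[1])
  dims <- hdr[2:4]
  nframes <- hdr[5]
  type <- hdr[6]
  good_ras <- readBin(con, "integer", 1, size = 2, endian = "big")
  affine <- diag(4)
  if (good_ras == 1L) {
    spacing <- readBin(con, "numeric", 3, size = 4, endian = "big")
    mdc <- matrix(readBin(con, "numeric", 9, size = 4, endian = "big"), 3, 3)
    c_ras <- readBin(con, "numeric", 3, size = 4, endian = "big")
    m <- mdc %*% diag(spacing)
    affine[1:3, 1:3] <- m
    affine[1:3, 4] <- c_ras - m %*% (dims / 2)
    skip <- 284 - (28 + 2 + 60)
  } else skip <- 284 - 30
  readBin(con, "raw", skip)
  n <- prod(dims) * max(1, nframes)
  dat <- switch(as.character(type),
                "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
                "1" = as.numeric(readBin(con, "integer", n, size = 4, endian = "big")),
                "3" = readBin(con, "numeric", n, size = 4, endian = "big"),
                "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = "big")),
                stop("unsupported MGH data type: ", type))
  scalar_volume(array(dat[seq_len(prod(dims))], dims), affine)
}
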