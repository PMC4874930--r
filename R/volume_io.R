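# Scalar/label volume containers and I/O.
#
# All geometry is metric: world coordinates in mm, voxel indices 0-based in
# formulas, 1-based in R arrays. A voxel's center is origin + index * spacing
# (0-based index). Axis order is (x, y, z), x fastest, matching R array
# storage. Oblique direction cosines are rejected: graph parameters (column
# radius, node gap, recentering radius) are metric and assume axis-aligned
# grids.

#' Scalar uptake volume
#'
#' A 3-D scalar grid of tracer uptake (arbitrary activity units, typically
#' SUV) with voxel spacing and world origin in mm.
#'
#' @param data numeric 3-D array, x fastest.
#' @param spacing numeric length-3, per-axis voxel size in mm, all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return an object of class \code{scalar_volume} with fields \code{data},
#'   \code{spacing}, \code{origin}.
#' @export
scalar_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("scalar_volume: 'data' must be a 3-D array")
  if (any(dim(data) < 2L))
    stop("scalar_volume: each axis must have at least 2 voxels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("scalar_volume: 'spacing' must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("scalar_volume: 'origin' must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("scalar_volume: 'data' must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' Integer label volume
#'
#' Non-negative integer labels on the same grid as an associated
#' \code{\link{scalar_volume}}; label 0 is background.
#'
#' @param data integer 3-D array of labels.
#' @param spacing,origin grid geometry, as in \code{\link{scalar_volume}}.
#' @return an object of class \code{label_volume}.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  storage.mode(data) <- "integer"
  if (length(dim(data)) != 3L)
    stop("label_volume: 'data' must be a 3-D array")
  if (any(is.na(data)) || any(data < 0L))
    stop("label_volume: labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("label_volume: 'spacing' must be 3 strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  uptake range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.integer(x$data)))
  cat(sprintf("label_volume: %s voxels, spacing %s mm, labels {%s}\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              paste(labs, collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("unsupported volume format (expect .nii, .nii.gz or .nrrd): ", path)
}

#' Read a scalar volume from NIfTI-1 or NRRD
#'
#' Spacing and origin are taken from the file metadata; anisotropic spacing
#' is preserved. Only axis-aligned grids (diagonal direction matrix with
#' positive scales) are accepted.
#'
#' @param path file path ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.nrrd}.
#' @return a \code{\link{scalar_volume}}.
#' @export
read_volume <- function(path) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop("cannot read volume, file not found: ", path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    m <- aff[1:3, 1:3, drop = FALSE]
    if (max(abs(m - diag(diag(m)))) > 1e-4 * max(abs(m)))
      stop("read_volume: oblique direction cosines are not supported: ", path)
    spacing <- diag(m)
    if (any(spacing <= 0))
      stop("read_volume: flipped/negative axis directions are not supported: ",
           path)
    if (length(dim(img)) != 3L)
      stop("read_volume: expected a 3-D volume, got ",
           length(dim(img)), " dimensions")
    arr <- array(as.numeric(img), dim = dim(img))
    scalar_volume(arr, spacing, aff[1:3, 4])
  } else {
    v <- read_nrrd(path)
    scalar_volume(v$data, v$spacing, v$origin)
  }
}

#' Write a scalar volume to NIfTI-1 or NRRD
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param path destination path; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume") || inherits(vol, "label_volume"))
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    dat <- vol$data
    storage.mode(dat) <- if (inherits(vol, "label_volume")) "integer" else "double"
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- vol$spacing
    aff <- diag(4)
    aff[1:3, 1:3] <- diag(vol$spacing)
    aff[1:3, 4] <- vol$origin
    img <- RNifti::`qform<-`(img, value = structure(aff, code = 2L))
    img <- RNifti::`sform<-`(img, value = structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(vol$data, vol$spacing, vol$origin, path,
               integer_type = inherits(vol, "label_volume"))
  }
  invisible(path)
}

#' Read a label volume
#'
#' @param path file path (NIfTI-1 or NRRD).
#' @return a \code{\link{label_volume}}.
#' @export
read_labels <- function(path) {
  v <- read_volume(path)
  if (max(abs(v$data - round(v$data))) > 1e-6)
    stop("read_labels: file does not contain integer labels: ", path)
  label_volume(round(v$data), v$spacing, v$origin)
}

#' @rdname write_volume
#' @export
write_labels <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_volume(vol, path)
}

#' Sample uptake at world points by trilinear interpolation
#'
#' Points outside the volume's physical extent (beyond the outermost voxel
#' centers) sample 0.0, so graph columns extending past the scan edge see
#' background-like uptake rather than edge artifacts.
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param points numeric matrix (n x 3) or length-3 vector of world mm
#'   coordinates.
#' @return numeric vector of n interpolated uptake values.
#' @export
sample_uptake <- function(vol, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3L)
  dm <- dim(vol$data)
  # continuous 0-based voxel coordinates
  tx <- (points[, 1] - vol$origin[1]) / vol$spacing[1]
  ty <- (points[, 2] - vol$origin[2]) / vol$spacing[2]
  tz <- (points[, 3] - vol$origin[3]) / vol$spacing[3]
  inside <- tx >= 0 & tx <= dm[1] - 1 &
            ty >= 0 & ty <= dm[2] - 1 &
            tz >= 0 & tz <= dm[3] - 1
  out <- numeric(nrow(points))
  if (!any(inside)) return(out)
  tx <- tx[inside]; ty <- ty[inside]; tz <- tz[inside]
  x0 <- pmin(floor(tx), dm[1] - 2); fx <- tx - x0
  y0 <- pmin(floor(ty), dm[2] - 2); fy <- ty - y0
  z0 <- pmin(floor(tz), dm[3] - 2); fz <- tz - z0
  d <- vol$data
  idx <- function(ix, iy, iz) 1 + ix + dm[1] * (iy + dm[2] * iz)
  v000 <- d[idx(x0,     y0,     z0)]
  v100 <- d[idx(x0 + 1, y0,     z0)]
  v010 <- d[idx(x0,     y0 + 1, z0)]
  v110 <- d[idx(x0 + 1, y0 + 1, z0)]
  v001 <- d[idx(x0,     y0,     z0 + 1)]
  v101 <- d[idx(x0 + 1, y0,     z0 + 1)]
  v011 <- d[idx(x0,     y0 + 1, z0 + 1)]
  v111 <- d[idx(x0 + 1, y0 + 1, z0 + 1)]
  out[inside] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                fy        * ((1 - fx) * v010 + fx * v110)) +
    fz       * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
                fy        * ((1 - fx) * v011 + fx * v111))
  out
}

# world coordinates of all voxel centers along one axis
axis_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

# nearest 1-based voxel index of world points; NA outside the grid
voxel_index <- function(vol, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  dm <- dim(vol$data)
  ix <- round((points[, 1] - vol$origin[1]) / vol$spacing[1]) + 1
  iy <- round((points[, 2] - vol$origin[2]) / vol$spacing[2]) + 1
  iz <- round((points[, 3] - vol$origin[3]) / vol$spacing[3]) + 1
  bad <- ix < 1 | ix > dm[1] | iy < 1 | iy > dm[2] | iz < 1 | iz > dm[3]
  ix[bad] <- NA; iy[bad] <- NA; iz[bad] <- NA
  cbind(ix, iy, iz)
}
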