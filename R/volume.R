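#' Volumetric image container
#'
#' An `image_volume` is a 3-D scalar grid (HU for CT, arbitrary units for MR)
#' with per-axis voxel spacing and a world-space origin. The coordinate
#' convention used throughout the package is: 0-based voxel indices,
#' voxel-center world coordinates, `world = origin + index * spacing`, all
#' distances in mm, x the fastest-varying array dimension.
#'
#' @param data 3-D numeric array; all values must be finite.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin Numeric length-3, world position (mm) of the center of voxel
#'   (0, 0, 0).
#' @param modality Either `"CT"` or `"MR"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data)))
    stop("'data' contains non-finite values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' Boolean mask on the grid of a reference volume
#'
#' @param data 3-D logical array (numeric input is coerced with `!= 0`).
#' @param spacing,origin Grid geometry, as in [image_volume()].
#' @param role Free-text role label (`"metal"`, `"corrupted"`, `"body"`,
#'   `"roi"`, ...), used only for reporting.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing, origin = c(0, 0, 0), role = "roi") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (!is.logical(data)) {
    data <- array(data != 0, dim = dim(data))
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 role = as.character(role)),
            class = "mask_volume")
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.mask_volume <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume '%s'> %s voxels, %d set\n", x$role,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Test whether two volumes share a grid
#'
#' Two volumes are aligned iff shape, spacing and origin agree (spacing and
#' origin to within a 1e-6 relative tolerance, absorbing float32 NIfTI
#' headers).
#'
#' @param a,b `image_volume` or `mask_volume` objects.
#' @return Logical scalar.
#' @export
volumes_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) return(FALSE)
  tol <- 1e-6
  sp <- max(abs(a$spacing - b$spacing) / pmax(a$spacing, b$spacing))
  og <- max(abs(a$origin - b$origin) / pmax(abs(a$origin), abs(b$origin), 1))
  sp <= tol && og <= tol
}

.assert_aligned <- function(..., what = "volumes") {
  vols <- list(...)
  ref <- vols[[1L]]
  for (v in vols[-1L]) {
    if (!volumes_aligned(ref, v))
      stop(what, " are not aligned (shape/spacing/origin mismatch)")
  }
  invisible(TRUE)
}

## world <-> continuous 0-based index coordinates
.world_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
}

.index_to_world <- function(vol, idx) {
  sweep(sweep(idx, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

## Sample a 3-D array at continuous 0-based index coordinates.
## mode "trilinear" or "nearest"; points outside [0, dim-1] get `fill`.
.sample_array <- function(arr, idx, mode = "trilinear", fill = 0) {
  d <- dim(arr)
  n <- nrow(idx)
  out <- rep(as.numeric(fill), n)
  eps <- 1e-9
  inside <- idx[, 1L] >= -eps & idx[, 1L] <= d[1L] - 1 + eps &
    idx[, 2L] >= -eps & idx[, 2L] <= d[2L] - 1 + eps &
    idx[, 3L] >= -eps & idx[, 3L] <= d[3L] - 1 + eps
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  if (mode == "nearest") {
    i <- round(p) + 1
    i[, 1L] <- pmin(pmax(i[, 1L], 1), d[1L])
    i[, 2L] <- pmin(pmax(i[, 2L], 1), d[2L])
    i[, 3L] <- pmin(pmax(i[, 3L], 1), d[3L])
    out[inside] <- arr[cbind(i[, 1L], i[, 2L], i[, 3L])]
    return(out)
  }
  ## trilinear: clamp the lower corner so points exactly on the far face
  ## resolve to weight-1 on the last voxel
  f <- floor(p)
  for (a in 1:3) f[, a] <- pmin(pmax(f[, a], 0), max(d[a] - 2, 0))
  w <- p - f
  w[w < 0] <- 0
  w[w > 1] <- 1
  acc <- numeric(nrow(p))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- pmin(f[, 1L] + dx + 1, d[1L])
    iy <- pmin(f[, 2L] + dy + 1, d[2L])
    iz <- pmin(f[, 3L] + dz + 1, d[3L])
    wt <- (if (dx) w[, 1L] else 1 - w[, 1L]) *
      (if (dy) w[, 2L] else 1 - w[, 2L]) *
      (if (dz) w[, 3L] else 1 - w[, 3L])
    nz <- wt != 0
    if (any(nz))
      acc[nz] <- acc[nz] + wt[nz] * arr[cbind(ix[nz], iy[nz], iz[nz])]
  }
  out[inside] <- acc
  out
}

#' Read a volumetric image from a NIfTI file
#'
#' Spacing and origin are taken from the file's sform/qform; only axis-aligned
#' orientations with positive axis scales are supported (all files written by
#' this package satisfy that).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality `"CT"` or `"MR"`; stored on the returned volume.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("'", path, "' is ", length(dim(a)), "-D; expected a 3-D volume")
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0) ||
      max(abs(rot - diag(spacing))) > 1e-4 * max(spacing))
    stop("'", path, "' has an oblique or flipped orientation; only ",
         "axis-aligned volumes are supported")
  origin <- xf[1:3, 4]
  storage.mode(a) <- "double"
  attributes(a) <- list(dim = dim(a))
  image_volume(a, spacing = spacing, origin = origin, modality = modality)
}

#' Read a mask from a NIfTI file
#'
#' @param path Path to the mask file; voxels `!= 0` are set.
#' @param reference Optional volume the mask must be aligned with.
#' @param role Role label, see [mask_volume()].
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, reference = NULL, role = "roi") {
  v <- read_volume(path, modality = "CT")
  m <- mask_volume(v$data != 0, spacing = v$spacing, origin = v$origin,
                   role = role)
  if (!is.null(reference)) .assert_aligned(reference, m, what = "mask and reference")
  m
}

#' Write a volume or mask to a NIfTI file
#'
#' @param vol An [image_volume()] or [mask_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "mask_volume")
  a <- vol$data
  if (is_mask) {
    a <- array(as.integer(a), dim = dim(a))
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Trilinear interpolation for intensity volumes, nearest-neighbour for masks
#' (enforced). Voxels of the reference grid that fall outside the moving
#' volume's support are filled with a physically neutral value: -1000 HU for
#' CT, 0 for MR, `FALSE` for masks.
#'
#' @param moving Volume or mask to resample.
#' @param reference Volume or mask whose grid defines the output.
#' @param interpolation `"trilinear"` or `"nearest"`; ignored (nearest) for
#'   masks.
#' @param fill Out-of-support fill value; default depends on modality.
#' @return A volume/mask aligned with `reference`.
#' @export
resample_to <- function(moving, reference,
                        interpolation = c("trilinear", "nearest"),
                        fill = NULL) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(moving, "mask_volume")
  if (is_mask) interpolation <- "nearest"
  if (is.null(fill)) {
    fill <- if (is_mask) 0 else if (moving$modality == "CT") -1000 else 0
  }
  d <- dim(reference$data)
  ## reference voxel centers in world coordinates
  idx <- cbind(rep(seq_len(d[1L]) - 1, times = d[2L] * d[3L]),
               rep(rep(seq_len(d[2L]) - 1, each = d[1L]), times = d[3L]),
               rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L]))
  world <- .index_to_world(reference, idx)
  midx <- .world_to_index(moving, world)
  src <- moving$data
  if (is_mask) storage.mode(src) <- "double"
  vals <- .sample_array(src, midx, mode = interpolation, fill = fill)
  out <- array(vals, dim = d)
  if (is_mask) {
    mask_volume(out != 0, spacing = reference$spacing,
                origin = reference$origin, role = moving$role)
  } else {
    image_volume(out, spacing = reference$spacing, origin = reference$origin,
                 modality = moving$modality)
  }
}

## small morphological helpers on logical arrays (box/offset structuring)
.shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      if (o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      if (-o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

.dilate_mask <- function(a, offsets) {
  out <- a
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- out | .shift_array(a, o)
  }
  out
}

.erode_mask <- function(a, offsets) {
  out <- a
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- out & .shift_array(a, o, fill = FALSE)
  }
  out
}
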