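#' Construct an intensity volume
#'
#' A minimal container for a 3-D gray-level image: an array of intensities and
#' the voxel spacing in mm along each axis. Axial slices are the xy planes
#' (third index = slice position).
#'
#' @param grid 3-D numeric array of gray levels.
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(grid, spacing) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(grid = grid, spacing = spacing), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      "  intensity range: ", paste(format(range(x$grid)), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' Quantize a volume to discrete gray levels
#'
#' Maps intensities linearly onto integer levels `0..n_levels-1` spanning the
#' volume's intensity range, the discrete substrate the histogram machinery
#' operates on. A constant volume maps to level 0.
#'
#' @param volume an [intensity_volume()].
#' @param n_levels number of gray levels (>= 2), default 256.
#' @return An `intensity_volume` with integer-valued grid in `0..n_levels-1`.
#' @export
quantize_volume <- function(volume, n_levels = 256L) {
  stopifnot(inherits(volume, "intensity_volume"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  rng <- range(volume$grid)
  if (rng[1] == rng[2]) {
    q <- array(0L, dim(volume$grid))
  } else {
    q <- floor((volume$grid - rng[1]) / (rng[2] - rng[1]) * n_levels)
    q[q == n_levels] <- n_levels - 1L
    storage.mode(q) <- "integer"
  }
  intensity_volume(q, volume$spacing)
}

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI image (optionally gzipped) into an [intensity_volume()],
#' preserving the voxel spacing from the header. Intensities are optionally
#' quantized to `n_levels` discrete gray levels.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param n_levels if non-`NULL`, quantize to this many gray levels.
#' @return An `intensity_volume`.
#' @export
read_volume <- function(path, n_levels = NULL) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), "-D data in ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  vol <- intensity_volume(arr, spacing)
  if (!is.null(n_levels)) vol <- quantize_volume(vol, n_levels)
  vol
}

#' Write a volume (or mask) as NIfTI
#'
#' @param volume an [intensity_volume()] or a 3-D array (then `spacing` is
#'   required).
#' @param path destination `.nii` or `.nii.gz` path.
#' @param spacing voxel spacing in mm, used when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "intensity_volume")) {
    arr <- volume$grid
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing is required for a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Volume of a mask in millilitres
#'
#' Voxel count times voxel volume. The universal conversion behind TKV, TCV
#' and the phantom ground truth: `n_voxels * prod(spacing) / 1000` mL.
#'
#' @param mask logical/0-1/array label map (nonzero = inside).
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @return Volume in mL.
#' @export
mask_volume_ml <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(mask != 0) * prod(spacing) / 1000
}

check_same_grid <- function(a, b) {
  da <- if (is.array(a)) dim(a) else dim(a$grid)
  db <- if (is.array(b)) dim(b) else dim(b$grid)
  if (!identical(as.integer(da), as.integer(db)))
    stop("grid shapes do not match: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}
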