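#' Specification for a synthetic kidney phantom
#'
#' Describes a 3-D T2-weighted-like kidney phantom: two ellipsoidal kidneys of
#' moderate parenchymal intensity containing hyperintense spherical cysts, on
#' a dark background, degraded by partial-volume Gaussian blur and additive
#' noise, then quantized to discrete gray levels. The `pattern` field controls
#' the left/right cyst distribution and kidney size so the atypical
#' presentations (unilateral, lopsided, asymmetric, bilateral atrophy) can be
#' emulated alongside a typical bilateral phantom.
#'
#' Defaults describe a moderately sized adult kidney pair (semiaxes
#' 30 x 24 x 50 mm, about 151 mL each) on a 108 x 64 x 80 grid at 1.5 mm
#' isotropic spacing, with 6 cysts per kidney of radius 4-11 mm. Intensities
#' follow the T2 convention (cysts hyperintense): background 20, parenchyma
#' 100, cysts 200 gray levels, with within-tissue texture SDs of 4/6/6 and
#' post-blur noise SD 12 (contrast-to-noise of about 8 between parenchyma and
#' cyst). Partial volume is simulated by a 1.5 mm (one voxel) Gaussian blur of
#' the piecewise-constant image before noise.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing mm per axis (scalar or length 3).
#' @param kidney_semiaxes mm, either length 3 (both kidneys) or a list of two
#'   length-3 vectors (left, right).
#' @param pattern one of `"typical_bilateral"`, `"unilateral"`, `"lopsided"`,
#'   `"asymmetric"`, `"bilateral_atrophy"`.
#' @param n_cysts cysts per kidney (before pattern-specific redistribution).
#' @param cyst_radius_range mm, length 2.
#' @param parenchyma_intensity,cyst_intensity,background_intensity length-2
#'   `(mean, sd)` gray levels; the SD is within-tissue texture applied before
#'   blurring. Cyst mean must exceed parenchyma mean.
#' @param blur_sigma partial-volume blur in mm (0 disables).
#' @param noise_sd post-blur noise SD in gray levels (0 disables).
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude MRI).
#' @param n_levels gray levels after quantization (default 256).
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(108L, 64L, 80L),
                         voxel_spacing = c(1.5, 1.5, 1.5),
                         kidney_semiaxes = c(30, 24, 50),
                         pattern = "typical_bilateral",
                         n_cysts = 6L,
                         cyst_radius_range = c(4, 11),
                         parenchyma_intensity = c(100, 6),
                         cyst_intensity = c(200, 6),
                         background_intensity = c(20, 4),
                         blur_sigma = 1.5,
                         noise_sd = 12,
                         noise_model = c("gaussian", "rician"),
                         n_levels = 256L,
                         seed = 1L) {
  pattern <- match.arg(pattern, c("typical_bilateral", "unilateral",
                                  "lopsided", "asymmetric", "bilateral_atrophy"))
  noise_model <- match.arg(noise_model)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (!is.list(kidney_semiaxes))
    kidney_semiaxes <- list(kidney_semiaxes, kidney_semiaxes)
  if (cyst_intensity[1] <= parenchyma_intensity[1])
    stop("cyst intensity mean must exceed parenchyma intensity mean ",
         "(T2-weighted convention)")
  if (cyst_radius_range[1] > cyst_radius_range[2] || cyst_radius_range[1] <= 0)
    stop("invalid cyst_radius_range")
  if (cyst_radius_range[2] >= min(unlist(kidney_semiaxes)))
    stop("largest cyst radius must fit inside the kidney semiaxes")
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing = voxel_spacing,
    kidney_semiaxes = kidney_semiaxes,
    pattern = pattern,
    n_cysts = as.integer(n_cysts),
    cyst_radius_range = as.numeric(cyst_radius_range),
    parenchyma_intensity = as.numeric(parenchyma_intensity),
    cyst_intensity = as.numeric(cyst_intensity),
    background_intensity = as.numeric(background_intensity),
    blur_sigma = as.numeric(blur_sigma),
    noise_sd = as.numeric(noise_sd),
    noise_model = noise_model,
    n_levels = as.integer(n_levels),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Generate a kidney phantom with known ground truth
#'
#' Rasterizes two ellipsoidal kidneys and non-overlapping spherical cysts per
#' the spec's atypical pattern, renders the piecewise tissue intensities,
#' applies partial-volume blur and noise, quantizes the gray levels, and
#' returns the degraded volume together with the exact voxel-level ground
#' truth (kidney label map, cyst mask, true TKV/TCV in mL).
#'
#' Pattern semantics: `unilateral` places all cysts in the left kidney;
#' `lopsided` places cysts so that at least 70\% (target 80\%) of the total
#' cyst volume lies in one kidney; `asymmetric` enlarges one kidney (and its
#' cyst load) and shrinks the other; `bilateral_atrophy` shrinks both kidneys
#' and carries few, small cysts.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (an [intensity_volume()] with integer
#'   gray levels), `truth` (list: `kidney_mask` integer array with labels
#'   1 = left, 2 = right; `cyst_mask` logical array; `true_tkv`, `true_tcv` in
#'   mL; `cysts` data frame of placed cysts) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(48, 32, 40),
#'                                     voxel_spacing = 3, seed = 7))
#' ph$truth$true_tcv
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  dims <- spec$grid_shape
  sp <- spec$voxel_spacing
  extent <- dims * sp
  centre_y <- extent[2] / 2
  centre_z <- extent[3] / 2

  semi <- spec$kidney_semiaxes
  radius_range <- spec$cyst_radius_range
  n_per_kidney <- rep(spec$n_cysts, 2L)
  scale_k <- c(1, 1)
  switch(spec$pattern,
    typical_bilateral = NULL,
    unilateral = { n_per_kidney <- c(spec$n_cysts, 0L) },
    lopsided = {
      # the dominant cystic kidney is enlarged; cyst share handled below
      scale_k <- c(1.15, 0.85)
    },
    asymmetric = {
      scale_k <- c(1.15, 0.75)
      n_per_kidney <- c(ceiling(1.5 * spec$n_cysts),
                        max(1L, floor(0.5 * spec$n_cysts)))
    },
    bilateral_atrophy = {
      scale_k <- c(0.55, 0.55)
      n_per_kidney <- rep(min(spec$n_cysts, 2L), 2L)
      radius_range <- pmax(1.5 * max(sp), 0.45 * radius_range)
    }
  )
  semi <- list(semi[[1]] * scale_k[1], semi[[2]] * scale_k[2])

  # kidney centres: side by side along x with a gap
  gap <- 12
  cx <- c(extent[1] / 2 - semi[[1]][1] - gap / 2,
          extent[1] / 2 + semi[[2]][1] + gap / 2)
  centres <- list(c(cx[1], centre_y, centre_z), c(cx[2], centre_y, centre_z))

  # sample cyst radii and assign to kidneys
  total <- sum(n_per_kidney)
  if (total > 0) {
    radii <- sort(runif(total, radius_range[1], radius_range[2]),
                  decreasing = TRUE)
    if (spec$pattern == "lopsided") {
      # largest cysts into the dominant kidney until ~75% of cyst volume
      vol <- radii^3
      kidney_of <- integer(total)
      acc <- 0
      for (i in seq_len(total)) {
        if (acc < 0.75 * sum(vol)) { kidney_of[i] <- 1L; acc <- acc + vol[i] }
        else kidney_of[i] <- 2L
      }
    } else if (spec$pattern == "asymmetric") {
      # the enlarged kidney carries the large cysts, the small one the rest
      kidney_of <- rep(c(1L, 2L), n_per_kidney)
    } else {
      # round-robin by decreasing size, respecting per-kidney quotas, so both
      # kidneys share the large cysts
      quota <- n_per_kidney
      kidney_of <- integer(total)
      turn <- 1L
      for (i in seq_len(total)) {
        if (quota[turn] == 0L) turn <- 3L - turn
        kidney_of[i] <- turn
        quota[turn] <- quota[turn] - 1L
        turn <- 3L - turn
      }
    }
  } else {
    radii <- numeric(0); kidney_of <- integer(0)
  }

  # place cysts largest-first: fully inside the kidney, pairwise
  # non-overlapping; a greedy arrangement can strand a later cyst, so the
  # whole arrangement is retried from scratch on failure
  radii <- pmin(radii, 0.85 * vapply(kidney_of, function(k) min(semi[[k]]),
                                     numeric(1)))
  cysts <- NULL
  failed_at <- 0L
  for (restart in seq_len(60L)) {
    cysts <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        r = numeric(0), kidney = integer(0))
    ok <- TRUE
    for (i in seq_along(radii)) {
      k <- kidney_of[i]
      a <- semi[[k]]
      m <- pmax(a - radii[i], 0.1)      # feasible centre box
      placed <- FALSE
      for (try in seq_len(400L)) {
        c_rel <- runif(3, -m, m)
        if (sum(((abs(c_rel) + radii[i])^2) / a^2) > 0.98) next
        pos <- centres[[k]] + c_rel
        if (nrow(cysts)) {
          d <- sqrt((cysts$x - pos[1])^2 + (cysts$y - pos[2])^2 +
                    (cysts$z - pos[3])^2)
          if (any(d <= cysts$r + radii[i] + 2)) next
        }
        cysts <- rbind(cysts, data.frame(x = pos[1], y = pos[2], z = pos[3],
                                         r = radii[i], kidney = k))
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; failed_at <- i; break }
    }
    if (ok) break
    cysts <- NULL
  }
  if (is.null(cysts) && length(radii))
    stop("could not place cyst ", failed_at, " (radius ",
         round(radii[failed_at], 1), " mm) after repeated attempts")
  if (is.null(cysts))
    cysts <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        r = numeric(0), kidney = integer(0))

  # voxel-centre coordinates
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  ys <- (seq_len(dims[2]) - 0.5) * sp[2]
  zs <- (seq_len(dims[3]) - 0.5) * sp[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

  kidney_mask <- array(0L, dims)
  for (k in 1:2) {
    a <- semi[[k]]; ctr <- centres[[k]]
    inside <- ((X - ctr[1]) / a[1])^2 + ((Y - ctr[2]) / a[2])^2 +
              ((Z - ctr[3]) / a[3])^2 <= 1
    kidney_mask[inside] <- k
  }

  cyst_mask <- array(FALSE, dims)
  for (i in seq_len(nrow(cysts))) {
    ball <- (X - cysts$x[i])^2 + (Y - cysts$y[i])^2 + (Z - cysts$z[i])^2 <=
            cysts$r[i]^2
    cyst_mask <- cyst_mask | ball
  }
  cyst_mask <- cyst_mask & kidney_mask > 0

  img <- array(spec$background_intensity[1], dims)
  if (spec$background_intensity[2] > 0)
    img <- img + array(rnorm(prod(dims), 0, spec$background_intensity[2]), dims)
  n_par <- sum(kidney_mask > 0 & !cyst_mask)
  img[kidney_mask > 0 & !cyst_mask] <-
    rnorm(n_par, spec$parenchyma_intensity[1], spec$parenchyma_intensity[2])
  img[cyst_mask] <-
    rnorm(sum(cyst_mask), spec$cyst_intensity[1], spec$cyst_intensity[2])

  if (spec$blur_sigma > 0)
    img <- gaussian_blur3d(img, spec$blur_sigma / sp)

  if (spec$noise_sd > 0) {
    if (spec$noise_model == "gaussian") {
      img <- img + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
    } else {
      n1 <- array(rnorm(prod(dims), 0, spec$noise_sd), dims)
      n2 <- array(rnorm(prod(dims), 0, spec$noise_sd), dims)
      img <- sqrt((img + n1)^2 + n2^2)
    }
  }

  volume <- quantize_volume(intensity_volume(img, sp), spec$n_levels)
  truth <- list(kidney_mask = kidney_mask,
                cyst_mask = cyst_mask,
                true_tkv = mask_volume_ml(kidney_mask, sp),
                true_tcv = mask_volume_ml(cyst_mask, sp),
                cysts = cysts)
  list(volume = volume, truth = truth, spec = spec)
}

#' Ground-truth volumes from phantom masks
#'
#' @param truth the `truth` element of [generate_phantom()]'s result (or any
#'   list with `kidney_mask` and `cyst_mask` on a common grid).
#' @param spacing voxel spacing in mm.
#' @return Named numeric: `true_tkv`, `true_tcv` in mL.
#' @export
truth_volumes <- function(truth, spacing) {
  check_same_grid(truth$kidney_mask, truth$cyst_mask)
  c(true_tkv = mask_volume_ml(truth$kidney_mask, spacing),
    true_tcv = mask_volume_ml(truth$cyst_mask, spacing))
}

#' Write a phantom to disk
#'
#' Writes the intensity volume, kidney label map and cyst mask as NIfTI files
#' plus a JSON sidecar with the ground-truth volumes, seed and spec echo.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if missing).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir, gzip = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  sp <- phantom$volume$spacing
  write_volume(phantom$volume, file.path(dir, paste0("phantom", ext)))
  write_volume(phantom$truth$kidney_mask, file.path(dir, paste0("kidney_mask", ext)),
               spacing = sp)
  write_volume(phantom$truth$cyst_mask + 0L, file.path(dir, paste0("cyst_mask", ext)),
               spacing = sp)
  sidecar <- list(true_tkv = phantom$truth$true_tkv,
                  true_tcv = phantom$truth$true_tcv,
                  seed = phantom$spec$seed,
                  spec = phantom$spec[setdiff(names(phantom$spec),
                                              "kidney_semiaxes")])
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# separable periodic Gaussian blur via FFT; sigma_vox per axis (voxels)
gaussian_blur3d <- function(img, sigma_vox) {
  dims <- dim(img)
  otf <- 1
  kernels <- lapply(seq_len(3), function(ax) {
    n <- dims[ax]
    s <- sigma_vox[ax]
    if (s <= 0) return(NULL)
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # circular distances
    k <- exp(-d^2 / (2 * s^2))
    k / sum(k)
  })
  if (all(vapply(kernels, is.null, logical(1)))) return(img)
  f1 <- function(k, n) if (is.null(k)) rep(1 + 0i, n) else fft(k)
  Kx <- f1(kernels[[1]], dims[1])
  Ky <- f1(kernels[[2]], dims[2])
  Kz <- f1(kernels[[3]], dims[3])
  OTF <- array(Kx, dims) *
         array(rep(rep(Ky, each = dims[1]), times = dims[3]), dims) *
         array(rep(Kz, each = dims[1] * dims[2]), dims)
  out <- Re(fft(fft(img) * OTF, inverse = TRUE)) / prod(dims)
  out
}
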