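#' Total kidney volume from a kidney label map
#'
#' Sums voxel volume over all labeled kidneys and reports per-kidney volumes.
#'
#' @param kidney_mask integer label map (0 = background; 1, 2, ... = kidneys).
#' @param spacing voxel spacing in mm.
#' @return List with `tkv_ml` (total) and `per_kidney_ml` (named by label).
#' @export
compute_tkv <- function(kidney_mask, spacing) {
  labs <- sort(unique(kidney_mask[kidney_mask != 0]))
  if (!length(labs)) stop("kidney mask is empty")
  per <- vapply(labs, function(l) mask_volume_ml(kidney_mask == l, spacing),
                numeric(1))
  names(per) <- paste0("kidney_", labs)
  list(tkv_ml = sum(per), per_kidney_ml = per)
}

#' Height-adjust a volume
#'
#' Converts a volume in mL to a height-adjusted volume in mL/m, the scale the
#' Mayo imaging classification operates on (htTKV).
#'
#' @param volume_ml volume in mL (>= 0).
#' @param height_m patient height in metres (> 0).
#' @return Volume / height, mL/m.
#' @export
height_adjust <- function(volume_ml, height_m) {
  if (any(!is.finite(height_m)) || any(height_m <= 0))
    stop("height must be positive (metres)")
  if (any(volume_ml < 0)) stop("volume must be nonnegative")
  volume_ml / height_m
}

#' Derive residual tissue volume and volume fractions
#'
#' Residual tissue volume (RTV) is the non-cystic kidney tissue: total kidney
#' volume minus total cyst volume. Also derives the cystic percentage and the
#' three volume ratios used to characterize atypical ADPKD. Works identically
#' on raw (mL) or height-adjusted (mL/m) inputs as long as both are on the
#' same scale.
#'
#' @param tkv total kidney volume (> 0).
#' @param tcv total cyst volume, `0 <= tcv <= tkv`.
#' @return List: `tkv`, `tcv`, `rtv`, `tcv_percent`, `rtv_over_tcv` (`NA` when
#'   `tcv` is 0), `rtv_over_tkv`, `tcv_over_tkv`, `nephromegaly`.
#' @export
derive_volumetrics <- function(tkv, tcv) {
  if (!is.finite(tkv) || tkv <= 0) stop("tkv must be positive")
  if (!is.finite(tcv) || tcv < 0) stop("tcv must be nonnegative")
  if (tcv > tkv)
    stop("tcv (", tcv, ") exceeds tkv (", tkv,
         "): inconsistent cyst/kidney masks")
  rtv <- tkv - tcv
  list(tkv = tkv, tcv = tcv, rtv = rtv,
       tcv_percent = 100 * tcv / tkv,
       rtv_over_tcv = if (tcv > 0) rtv / tcv else NA_real_,
       rtv_over_tkv = rtv / tkv,
       tcv_over_tkv = tcv / tkv,
       nephromegaly = flag_nephromegaly(tkv))
}

#' Nephromegaly flag
#'
#' Kidney enlargement, defined as total kidney volume strictly greater than
#' 750 mL.
#'
#' @param tkv_ml total kidney volume in mL (>= 0).
#' @param cutoff_ml cutoff in mL (default 750).
#' @return Logical.
#' @export
flag_nephromegaly <- function(tkv_ml, cutoff_ml = 750) {
  if (any(tkv_ml < 0)) stop("tkv must be nonnegative")
  tkv_ml > cutoff_ml
}

#' Mayo Class 1 subclassification from htTKV and age
#'
#' For typical (Class 1) ADPKD the Mayo imaging classification assigns
#' subclasses 1A-1E from the estimated kidney growth rate `r` solving
#' `httkv = 150 * (1 + r)^age` (150 mL/m is the reference htTKV at birth in
#' the published classification): r < 1.5\%/yr is 1A, 1.5-3\% 1B, 3-4.5\% 1C,
#' 4.5-6\% 1D, above 6\% 1E. Boundary rates are assigned to the lower class.
#' An htTKV below the 150 mL/m intercept is clamped to class 1A and flagged.
#'
#' @param httkv height-adjusted total kidney volume, mL/m (> 0).
#' @param age_years age in years (> 0).
#' @param intercept reference htTKV (mL/m) of the growth model.
#' @param breaks class boundaries on the annual growth rate.
#' @return Character class, with attributes `growth_rate` (fraction/year) and
#'   `clamped`.
#' @export
classify_mayo1 <- function(httkv, age_years, intercept = 150,
                           breaks = c(0.015, 0.03, 0.045, 0.06)) {
  if (!is.finite(httkv) || httkv <= 0) stop("httkv must be positive")
  if (!is.finite(age_years) || age_years <= 0) stop("age must be positive")
  clamped <- httkv < intercept
  r <- if (clamped) 0 else (httkv / intercept)^(1 / age_years) - 1
  # boundary rates go to the lower class; 1e-9 guards the exact-boundary case
  # against floating-point noise in the root
  cls <- c("1A", "1B", "1C", "1D", "1E")[sum(r > breaks + 1e-9) + 1L]
  structure(cls, growth_rate = r, clamped = clamped)
}

#' Mayo imaging classification
#'
#' Dispatches between the atypical and typical branches of the Mayo
#' classification: a Class 2 imaging-pattern annotation takes precedence and
#' is subclassified 2A/2B by [mayo2_subclass()]; without a pattern, the
#' subject is classified 1A-1E from htTKV and age by [classify_mayo1()].
#'
#' @param pattern atypical imaging pattern, or `NULL` for typical disease.
#' @param httkv height-adjusted total kidney volume (mL/m); required when
#'   `pattern` is `NULL`.
#' @param age age in years; required when `pattern` is `NULL`.
#' @return Mayo class: one of 1A-1E, 2A, 2B.
#' @export
classify_mayo <- function(pattern = NULL, httkv = NULL, age = NULL) {
  if (!is.null(pattern)) return(mayo2_subclass(pattern))
  if (is.null(httkv) || is.null(age))
    stop("either an atypical pattern or both httkv and age are required")
  as.character(classify_mayo1(httkv, age))
}
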