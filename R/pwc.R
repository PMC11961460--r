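#' Gray-level histogram of a masked region
#'
#' Counts the voxel intensities inside a kidney mask over `n_levels`
#' equal-width bins spanning the masked intensity range. This histogram is
#' the substrate of the progressive weighted curve: `counts[i]` is the weight
#' w_i of the i-th gray level and `levels[i]` its representative gray value
#' (bin center).
#'
#' @param volume an [intensity_volume()].
#' @param mask label map aligned to `volume` (nonzero = kidney).
#' @param n_levels number of bins (>= 2), default 256.
#' @return An object of class `gray_histogram`: list with `counts`, `levels`,
#'   `breaks` and a `degenerate` flag (constant masked image: all counts fall
#'   in a single bin).
#' @export
build_histogram <- function(volume, mask, n_levels = 256L) {
  stopifnot(inherits(volume, "intensity_volume"))
  check_same_grid(volume$grid, mask)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  vals <- volume$grid[mask != 0]
  if (!length(vals)) stop("mask is empty")
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    h <- list(counts = length(vals), levels = rng[1],
              breaks = c(rng[1] - 0.5, rng[1] + 0.5), degenerate = TRUE)
    return(structure(h, class = "gray_histogram"))
  }
  width <- (rng[2] - rng[1]) / n_levels
  bin <- pmin(floor((vals - rng[1]) / width), n_levels - 1L)
  counts <- tabulate(bin + 1L, nbins = n_levels)
  levels <- rng[1] + (seq_len(n_levels) - 0.5) * width
  structure(list(counts = counts, levels = levels,
                 breaks = rng[1] + (0:n_levels) * width, degenerate = FALSE),
            class = "gray_histogram")
}

#' Progressive weighted curve of a gray-level histogram
#'
#' For each gray level k, the PWC value is the count-weighted average of the
#' intensity values up to the k-th level:
#' `PWC(k) = sum(w_i * x_i, i = 0..k) / sum(w_i, i = 0..k)`,
#' where the histogram counts define the weights. The curve is non-decreasing
#' and ends at the mean intensity of the masked region; its inflection points
#' are the candidate segmentation thresholds.
#'
#' Levels before the first nonzero count have no defined prefix mean; they
#' carry the first defined value.
#'
#' @param hist a [build_histogram()] result.
#' @return An object of class `pwc_curve`: list with `values`, `levels`,
#'   `defined_from` (index of the first defined value).
#' @export
compute_pwc <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  w <- hist$counts
  x <- hist$levels
  if (sum(w) == 0) stop("all-zero histogram")
  cw <- cumsum(w)
  cwx <- cumsum(w * x)
  values <- ifelse(cw > 0, cwx / pmax(cw, 1), NA_real_)
  first <- which(cw > 0)[1]
  if (first > 1) values[seq_len(first - 1)] <- values[first]
  structure(list(values = values, levels = x, counts = w,
                 defined_from = first),
            class = "pwc_curve")
}

#' Candidate thresholds from PWC inflection points
#'
#' Smooths the progressive weighted curve with a small Gaussian kernel and
#' returns the gray levels where its central second difference changes sign
#' (inflection points), in ascending order. Sign changes whose second
#' differences are both below `1e-6` of the curve's value range are treated
#' as numerically flat and ignored. When the curve carries histogram counts,
#' candidates are restricted to the central cumulative-mass range
#' (`support_trim`, 1 - `support_trim`): a threshold in the extreme tails
#' segments essentially nothing or everything, and the sparse tail bins make
#' the prefix mean (and hence its curvature) dominated by count noise.
#' Degenerate curves (constant, linear, or defined over fewer than 5 levels)
#' yield an empty vector.
#'
#' @param curve a [compute_pwc()] result.
#' @param smoothing_sigma Gaussian smoothing SD in bins (default 3; 0
#'   disables).
#' @param support_trim fraction of histogram mass excluded at each tail when
#'   locating candidates (default 0.005).
#' @return Numeric vector of candidate gray levels (possibly empty).
#' @export
find_candidate_thresholds <- function(curve, smoothing_sigma = 3,
                                      support_trim = 0.005) {
  stopifnot(inherits(curve, "pwc_curve"))
  v <- curve$values
  n <- length(v)
  if (n < 5L) return(numeric(0))
  if (smoothing_sigma > 0) v <- smooth_gaussian1d(v, smoothing_sigma)
  d2 <- v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]   # d2[j] ~ curvature at j+1
  tol <- 1e-6 * diff(range(curve$values))
  if (!is.finite(tol) || tol == 0) return(numeric(0))
  m <- length(d2)
  if (m < 2L) return(numeric(0))
  s <- sign(d2)
  flip <- which(s[-m] * s[-1] < 0 &
                pmax(abs(d2[-m]), abs(d2[-1])) >= tol)
  if (!length(flip)) return(numeric(0))
  # inflection lies between curve indices flip+1 and flip+2; report the level
  # whose curvature is closer to zero
  pick <- ifelse(abs(d2[flip]) <= abs(d2[flip + 1]), flip + 1L, flip + 2L)
  if (!is.null(curve$counts) && support_trim > 0) {
    cum <- cumsum(curve$counts) / sum(curve$counts)
    pick <- pick[cum[pick] >= support_trim & cum[pick] <= 1 - support_trim]
    if (!length(pick)) return(numeric(0))
  }
  sort(unique(curve$levels[pick]))
}

# discrete Gaussian smoothing with reflected edges
smooth_gaussian1d <- function(v, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  pad <- c(v[pmin(r:1, n)], v, v[pmax(n - (1:r) + 1, 1)])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + n)]
}

#' Threshold maximizing between-class variance
#'
#' Exhaustive single-threshold selection over a gray-level histogram
#' (maximum between-class variance). Used as the fallback when the PWC curve
#' has no usable inflection point.
#'
#' @param hist a [build_histogram()] result.
#' @return The gray level (bin center) maximizing between-class variance.
#' @export
otsu_level <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  w <- hist$counts
  x <- hist$levels
  n <- length(w)
  if (n < 2L) return(x[1])
  p <- w / sum(w)
  omega <- cumsum(p)
  mu <- cumsum(p * x)
  mu_t <- mu[n]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)   # first maximum -> lower level on ties
  x[k]
}
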