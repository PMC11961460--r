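# Independent brute-force oracles used to freeze expected values.

# quantile by explicit sort + linear interpolation at (n-1)*q
brute_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  pos <- (n - 1) * q
  lo <- floor(pos) + 1
  hi <- ceiling(pos) + 1
  frac <- pos - floor(pos)
  s[lo] + frac * (s[hi] - s[lo])
}

# OLS slope via explicit normal equations
brute_ols_slope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[2]
}

# flood-fill 3-D connected components (26- or 6-connectivity), queue-based
brute_label3d <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, dims)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        li <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# rank (Spearman) correlation from the explicit rank formula
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) /
    (sqrt(mean((rx - mean(rx))^2)) * sqrt(mean((ry - mean(ry))^2)))
}

# build a gray_histogram object directly (for hand-evaluated PWC examples)
make_hist <- function(counts, levels) {
  structure(list(counts = counts, levels = levels,
                 breaks = NULL, degenerate = FALSE),
            class = "gray_histogram")
}

# small two-mode Gaussian histogram over 0..255 gray levels
bimodal_hist <- function(mode1 = 60, mode2 = 180, sd1 = 15, sd2 = 15,
                         n1 = 5000, n2 = 2000) {
  lv <- 0:255
  counts <- round(n1 * dnorm(lv, mode1, sd1) + n2 * dnorm(lv, mode2, sd2))
  make_hist(counts, lv)
}

# a small, fast phantom for segmentation tests (2 mm spacing, 2 cysts/kidney)
tiny_phantom_spec <- function(n_cysts = 2, cyst_radius_range = c(5, 8), ...) {
  phantom_spec(grid_shape = c(56, 40, 48), voxel_spacing = 2,
               kidney_semiaxes = c(24, 18, 36), n_cysts = n_cysts,
               cyst_radius_range = cyst_radius_range, ...)
}
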