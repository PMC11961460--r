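# a 3-sphere test image: dark box with three bright, well-separated balls
three_sphere_volume <- function(dim = c(40, 40, 40), r = 5,
                                centres = list(c(10, 10, 10), c(30, 12, 12),
                                               c(20, 30, 30))) {
  grid <- array(50, dim)
  co <- arrayInd(seq_len(prod(dim)), dim)
  for (ctr in centres) {
    d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
    grid[d2 <= r^2] <- 200
  }
  intensity_volume(grid, 1)
}

test_that("thresholding extremes give no objects or the whole mask", {
  vol <- three_sphere_volume()
  mask <- array(1L, dim(vol$grid))
  expect_equal(max(apply_threshold(vol, mask, 200)), 0L)      # >= max level
  whole <- apply_threshold(vol, mask, 10, min_voxels = 1L)    # < min level
  expect_equal(max(whole), 1L)
  expect_true(all(whole[mask == 1L] == 1L))
})

test_that("three disjoint hyperintense spheres give exactly three objects", {
  vol <- three_sphere_volume()
  mask <- array(1L, dim(vol$grid))
  labs <- apply_threshold(vol, mask, 125)
  expect_equal(max(labs), 3L)
})

test_that("26-connected labeling agrees with a brute-force flood fill", {
  set.seed(7)
  for (i in 1:8) {
    m <- array(runif(6 * 6 * 6) < 0.25, c(6, 6, 6))
    mine <- label_components_26(m, min_voxels = 1L)
    ref <- brute_label3d(m, connectivity = 26)
    # same partition: component voxel sets must match
    expect_equal(max(mine), max(ref))
    if (max(ref) > 0) {
      split_mine <- split(which(mine > 0), mine[mine > 0])
      split_ref <- split(which(ref > 0), ref[ref > 0])
      canon <- function(s) unname(s[order(vapply(s, min, numeric(1)))])
      expect_equal(canon(split_mine), canon(split_ref))
    }
  }
})

test_that("a rasterized disc scores near-perfect circularity", {
  d <- c(50, 50, 3)
  grid <- array(0, d)
  co <- arrayInd(seq_len(prod(d)), d)
  disc <- (co[, 1] - 25)^2 + (co[, 2] - 25)^2 <= 20^2 & co[, 3] == 2
  grid[disc] <- 100
  vol <- intensity_volume(grid, 1)
  labs <- array(0L, d); labs[disc] <- 1L
  f <- object_features(labs, vol)
  expect_gte(f$circularity, 0.9)
  expect_equal(f$internal_sd, 0)     # constant-intensity object
})

test_that("single-voxel objects have defined degenerate features", {
  d <- c(7, 7, 7)
  grid <- array(0, d); grid[4, 4, 4] <- 10
  labs <- array(0L, d); labs[4, 4, 4] <- 1L
  f <- object_features(labs, intensity_volume(grid, 1))
  expect_equal(f$circularity, 1)
  expect_equal(f$internal_sd, 0)
})

test_that("border gradient grows with the step height of the object edge", {
  make_step <- function(h) {
    d <- c(24, 24, 24)
    grid <- array(50, d)
    co <- arrayInd(seq_len(prod(d)), d)
    ball <- (co[, 1] - 12)^2 + (co[, 2] - 12)^2 + (co[, 3] - 12)^2 <= 36
    grid[ball] <- 50 + h
    labs <- array(0L, d); labs[ball] <- 1L
    object_features(labs, intensity_volume(grid, 1))$border_gradient
  }
  g <- vapply(c(20, 60, 120), make_step, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("threshold scoring prefers compact homogeneous sharp objects", {
  expect_equal(score_threshold(data.frame(label = integer(0),
                                          n_voxels = integer(0),
                                          circularity = numeric(0),
                                          internal_sd = numeric(0),
                                          border_gradient = numeric(0))), 0)

  good <- data.frame(label = 1, n_voxels = 500, circularity = 0.95,
                     internal_sd = 4, border_gradient = 40, threshold = 1)
  ragged <- data.frame(label = 1:3, n_voxels = c(60, 40, 30),
                       circularity = c(0.2, 0.3, 0.25),
                       internal_sd = c(25, 30, 28),
                       border_gradient = c(8, 10, 9), threshold = 2)
  sc <- score_thresholds(rbind(good, ragged))
  expect_gt(sc$score[sc$threshold == 1], sc$score[sc$threshold == 2])

  # identical feature sets at two thresholds score equally
  twin <- good; twin$threshold <- 2
  sc2 <- score_thresholds(rbind(good, twin))
  expect_equal(sc2$score[1], sc2$score[2])
})

test_that("noise-free two-mode phantom is thresholded between the modes", {
  # cysts large relative to the blur so both tissue modes are well resolved
  ph <- generate_phantom(tiny_phantom_spec(
    seed = 9, noise_sd = 0, n_cysts = 1, cyst_radius_range = c(10, 12),
    parenchyma_intensity = c(100, 0), cyst_intensity = c(200, 0),
    background_intensity = c(20, 0)))
  seg <- segment_cysts(ph$volume, ph$truth$kidney_mask)
  vals <- ph$volume$grid[ph$truth$kidney_mask > 0]
  inside <- ph$truth$cyst_mask[ph$truth$kidney_mask > 0]
  plateau <- function(v) as.numeric(names(which.max(table(v))))
  expect_gt(seg$level, plateau(vals[!inside]))   # above the parenchyma mode
  expect_lt(seg$level, plateau(vals[inside]))    # below the cyst mode
  expect_false(seg$fallback)
})

test_that("cyst mask stays inside the kidney and TCV below TKV", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 14))
  seg <- segment_cysts(ph$volume, ph$truth$kidney_mask)
  expect_true(all(ph$truth$kidney_mask[seg$cyst_mask] > 0))
  tkv <- compute_tkv(ph$truth$kidney_mask, ph$volume$spacing)$tkv_ml
  expect_lte(seg$tcv_ml, tkv)
})

test_that("segmentation is invariant under affine intensity rescaling", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 16))
  seg1 <- segment_cysts(ph$volume, ph$truth$kidney_mask)
  vol2 <- intensity_volume(2 * ph$volume$grid + 10, ph$volume$spacing)
  seg2 <- segment_cysts(vol2, ph$truth$kidney_mask)
  expect_identical(seg1$cyst_mask, seg2$cyst_mask)
  expect_equal(seg2$level, 2 * seg1$level + 10, tolerance = 1e-8)
})

test_that("segmenting an empty mask is rejected", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 3))
  expect_error(segment_cysts(ph$volume, array(0L, dim(ph$volume$grid))),
               "empty")
})

test_that("cyst volume conversion is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10))
  expect_equal(compute_tcv(m, 1), 0)
  m[1:1000] <- TRUE
  expect_equal(compute_tcv(m, 1), 1.0)
  expect_equal(compute_tcv(m, c(2, 1, 1)), 2.0)
})

test_that("segmentation configuration is validated", {
  expect_error(seg_config(bins = 1), "bins")
  expect_error(seg_config(score_weights = c(0, 0, 0)), "score_weights")
  expect_error(seg_config(score_weights = c(-1, 1, 1)), "score_weights")
  expect_equal(seg_config(polarity = "dark")$polarity, "dark")
})
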