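test_that("phantom generation is deterministic given the spec", {
  a <- generate_phantom(tiny_phantom_spec(seed = 5))
  b <- generate_phantom(tiny_phantom_spec(seed = 5))
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$truth$cyst_mask, b$truth$cyst_mask)
  c <- generate_phantom(tiny_phantom_spec(seed = 6))
  expect_false(identical(a$volume$grid, c$volume$grid))
})

test_that("a cyst-free phantom has zero true cyst volume", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 2, n_cysts = 0))
  expect_equal(ph$truth$true_tcv, 0)
  expect_false(any(ph$truth$cyst_mask))
  expect_gt(ph$truth$true_tkv, 0)
})

test_that("rasterized volumes match analytic sphere and ellipsoid volumes", {
  # one spherical cyst of radius 10 mm at 1 mm spacing: 4/3*pi*10^3 = 4.19 mL
  sp <- phantom_spec(grid_shape = c(112, 46, 64), voxel_spacing = 1,
                     kidney_semiaxes = c(20, 17, 26), pattern = "unilateral",
                     n_cysts = 1, cyst_radius_range = c(10, 10), seed = 3)
  ph <- generate_phantom(sp)
  expect_equal(nrow(ph$truth$cysts), 1L)
  expect_equal(ph$truth$true_tcv, 4 / 3 * pi * 1000 / 1000, tolerance = 0.02)

  # kidney ellipsoid semiaxes (40, 25, 25) mm: 4/3*pi*40*25*25 = 104.7 mL each
  sp2 <- phantom_spec(grid_shape = c(184, 60, 60), voxel_spacing = 1,
                      kidney_semiaxes = c(40, 25, 25), n_cysts = 0, seed = 1)
  ph2 <- generate_phantom(sp2)
  analytic <- 4 / 3 * pi * 40 * 25 * 25 / 1000
  expect_equal(unname(truth_volumes(ph2$truth, 1)["true_tkv"]),
               2 * analytic, tolerance = 0.02)
})

test_that("truth volumes convert voxel counts and reject mismatched grids", {
  km <- array(0L, c(10, 10, 10))
  km[1:10, 1:10, 1:10] <- 1L          # 1000 voxels at 1 mm = 1 mL
  cm <- array(FALSE, c(10, 10, 10))
  tv <- truth_volumes(list(kidney_mask = km, cyst_mask = cm), 1)
  expect_equal(unname(tv["true_tkv"]), 1.0)
  expect_equal(unname(tv["true_tcv"]), 0)
  cm_bad <- array(FALSE, c(9, 10, 10))
  expect_error(truth_volumes(list(kidney_mask = km, cyst_mask = cm_bad), 1),
               "do not match")
})

test_that("rasterization error decreases with finer spacing", {
  err <- vapply(c(2, 1), function(h) {
    sp <- phantom_spec(grid_shape = round(c(184, 60, 60) / h),
                       voxel_spacing = h, kidney_semiaxes = c(40, 25, 25),
                       n_cysts = 0, seed = 1)
    ph <- generate_phantom(sp)
    analytic <- 2 * 4 / 3 * pi * 40 * 25 * 25 / 1000
    abs(ph$truth$true_tkv - analytic) / analytic
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("noise-free phantom histogram is bimodal at the tissue means", {
  ph <- generate_phantom(tiny_phantom_spec(
    seed = 9, noise_sd = 0, blur_sigma = 0,
    parenchyma_intensity = c(100, 0), cyst_intensity = c(200, 0),
    background_intensity = c(20, 0)))
  vals <- ph$volume$grid[ph$truth$kidney_mask > 0]
  modes <- sort(unique(vals))
  expect_length(modes, 2L)            # exactly the two tissue levels
  inside <- ph$truth$cyst_mask[ph$truth$kidney_mask > 0]
  expect_true(all(vals[inside] == modes[2]))
  expect_true(all(vals[!inside] == modes[1]))
})

test_that("atypical patterns control the left/right cyst distribution", {
  uni <- generate_phantom(tiny_phantom_spec(seed = 4, pattern = "unilateral"))
  expect_true(all(uni$truth$cysts$kidney == 1L))

  lop <- generate_phantom(phantom_spec(seed = 4, pattern = "lopsided"))
  share <- with(lop$truth$cysts, sum(r[kidney == 1]^3) / sum(r^3))
  expect_gte(share, 0.7)

  atro <- generate_phantom(phantom_spec(seed = 4, pattern = "bilateral_atrophy"))
  full <- generate_phantom(phantom_spec(seed = 4))
  expect_lt(atro$truth$true_tkv, 0.5 * full$truth$true_tkv)
})

test_that("cysts are pairwise disjoint and contained in the kidney", {
  for (seed in c(3, 8, 13)) {
    ph <- generate_phantom(tiny_phantom_spec(seed = seed))
    cy <- ph$truth$cysts
    if (nrow(cy) > 1) {
      d <- as.matrix(dist(cy[, c("x", "y", "z")]))
      sep <- outer(cy$r, cy$r, "+")
      expect_true(all(d[upper.tri(d)] > sep[upper.tri(sep)]))
    }
    expect_true(all(ph$truth$kidney_mask[ph$truth$cyst_mask] > 0))
    expect_lte(ph$truth$true_tcv, ph$truth$true_tkv)
  }
})

test_that("an unplaceable cyst arrangement fails with the cyst index", {
  sp <- phantom_spec(grid_shape = c(40, 30, 30), voxel_spacing = 2,
                     kidney_semiaxes = c(13, 12, 13), n_cysts = 4,
                     cyst_radius_range = c(10, 10), seed = 1)
  expect_error(generate_phantom(sp), "could not place cyst")
})

test_that("Rician noise produces a valid, distinct magnitude image", {
  g <- generate_phantom(tiny_phantom_spec(seed = 7))
  r <- generate_phantom(tiny_phantom_spec(seed = 7, noise_model = "rician"))
  expect_false(identical(g$volume$grid, r$volume$grid))
  expect_true(all(r$volume$grid >= 0))
  expect_identical(g$truth$cyst_mask, r$truth$cyst_mask)  # same geometry
})

test_that("phantom spec validation enforces the T2 convention and geometry", {
  expect_error(phantom_spec(cyst_intensity = c(90, 5)), "exceed")
  expect_error(phantom_spec(cyst_radius_range = c(30, 30)), "fit inside")
  expect_error(phantom_spec(voxel_spacing = -1), "positive")
})

test_that("phantoms round-trip to NIfTI with a truth sidecar", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 12))
  dir <- tempfile()
  write_phantom(ph, dir)
  vol <- read_volume(file.path(dir, "phantom.nii.gz"))
  expect_equal(vol$grid, ph$volume$grid, ignore_attr = TRUE)
  expect_equal(vol$spacing, ph$volume$spacing)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$true_tcv, ph$truth$true_tcv)
  expect_equal(truth$seed, 12L)
})
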