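grid_from <- function(arr, vs = c(5, 5, 5), channel = "insulin", ...) {
  voxel_grid(setNames(list(arr), channel), voxel_size_um = vs, ...)
}

test_that("segmentation params enforce their invariants", {
  expect_error(segmentation_params("x", background_diameter_um = 5,
                                   smoothing_um = 10), "must exceed")
  expect_error(segmentation_params("x", background_diameter_um = -1),
               "positive")
  expect_error(segmentation_params("x", 10, connectivity = 18), "6 or 26")
  p <- islet_params("1.3x")
  expect_equal(p$smoothing_um, 10)
  expect_equal(p$background_diameter_um, 250)
  expect_equal(islet_params("4x")$smoothing_um, 3.25)
  expect_error(islet_params("12x"), "no islet preset")
  np <- nerve_params()
  expect_equal(np$background_diameter_um, 12.2)
  expect_equal(np$smoothing_um, 3.25)
})

test_that("local-contrast threshold removes constant signal, keeps spheres", {
  # all-zero and spatially uniform volumes yield empty masks
  z <- array(0, c(24, 24, 24))
  p <- segmentation_params("insulin", background_diameter_um = 40,
                           smoothing_um = 5)
  expect_equal(sum(local_contrast_threshold(grid_from(z), p)), 0)
  u <- array(100, c(24, 24, 24))
  expect_equal(sum(local_contrast_threshold(grid_from(u), p)), 0)
  # background window below one voxel errors
  expect_error(local_contrast_threshold(
    grid_from(u), segmentation_params("insulin", background_diameter_um = 6,
                                      smoothing_um = 1)),
    "background window")

  # rasterized sphere (radius 5 voxels) on flat background 100 at 1000:
  # oracle = the true sphere; Dice must reach 0.90 (spec uses a 64-cube)
  d <- c(64L, 64L, 64L)
  co <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(co, 2, c(32, 32, 32))^2)
  sphere <- array(r2 <= 25, d)
  img <- array(100, d)
  img[sphere] <- 1000
  g <- voxel_grid(list(insulin = img), voxel_size_um = c(1, 1, 1))
  p <- segmentation_params("insulin", background_diameter_um = 30,
                           smoothing_um = 2)
  m <- local_contrast_threshold(g, p)
  expect_gte(dice_coefficient(m, sphere), 0.90)
})

test_that("otsu threshold separates a two-level mixture and handles degeneracy", {
  x <- c(rep(10, 900), rep(200, 100))
  t <- otsu_threshold(x)
  expect_gt(t, 10)
  expect_lt(t, 200)
  expect_equal(otsu_threshold(rep(3, 50)), 3) # constant: strict > empties mask
})

test_that("raising an absolute threshold never increases foreground", {
  set.seed(11)
  img <- array(runif(20^3) * 100, c(20, 20, 20))
  img[5:10, 5:10, 5:10] <- 500
  g <- grid_from(img, vs = c(2, 2, 2))
  prev <- Inf
  for (thr in c(20, 50, 100, 200, 400)) {
    p <- segmentation_params("insulin", background_diameter_um = 30,
                             smoothing_um = 0, intensity_threshold = thr)
    v <- sum(local_contrast_threshold(g, p))
    expect_lte(v, prev)
    prev <- v
  }
})

test_that("connected components: volumes, connectivity, conservation", {
  d <- c(12L, 12L, 12L)
  m <- array(FALSE, d)
  m[2:4, 2:4, 2:4] <- TRUE       # 27 voxels
  m[8:10, 8:10, 8:10] <- TRUE    # disjoint 27 voxels
  cc <- connected_components(m, c(2, 2, 2))
  expect_equal(n_objects(cc), 2)
  expect_equal(cc$table$volume_um3, c(216, 216)) # 27 * 8
  expect_equal(sum(cc$table$voxels), sum(m))     # conservation

  # cubes touching only at a corner: one object at 26-, two at 6-connectivity
  m2 <- array(FALSE, d)
  m2[2:4, 2:4, 2:4] <- TRUE
  m2[5:7, 5:7, 5:7] <- TRUE
  expect_equal(n_objects(connected_components(m2, c(1, 1, 1), 26)), 1)
  expect_equal(n_objects(connected_components(m2, c(1, 1, 1), 6)), 2)

  # empty mask, and non-binary rejection
  expect_equal(n_objects(connected_components(array(FALSE, d), c(1, 1, 1))), 0)
  expect_error(connected_components(array(2, d), c(1, 1, 1)), "binary")

  # min-volume filter removes speckles but conserves before filtering
  m3 <- m
  m3[12, 12, 12] <- TRUE
  cc3 <- connected_components(m3, c(2, 2, 2), min_object_volume_um3 = 100)
  expect_equal(n_objects(cc3), 2)
  cc3all <- connected_components(m3, c(2, 2, 2))
  expect_equal(sum(cc3all$table$voxels), sum(m3))
})

test_that("segment_islets recovers phantom islets with matched centroids", {
  ph <- small_phantom(seed = 1, noise = FALSE)
  islets <- segment_islets(ph$grid)
  truth <- ph$truth$islets
  expect_equal(n_objects(islets), nrow(truth))
  # greedy centroid matching: each measured centroid within 2 voxels (10 um)
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((islets$table$centroid_z_um - truth$center_z_um[i])^2 +
               (islets$table$centroid_y_um - truth$center_y_um[i])^2 +
               (islets$table$centroid_x_um - truth$center_x_um[i])^2)
    expect_lt(min(dd), 10)
  }
  # islets separated by construction are never merged
  expect_gte(n_objects(islets), sum(truth$volume_um3 > 500))
  # empty insulin channel yields no objects
  empty <- voxel_grid(list(insulin = array(0, c(16, 16, 16))),
                      magnification = "1.3x")
  expect_equal(n_objects(segment_islets(empty)), 0)
})

test_that("segment_nerves recovers a thin tube and drops speckle noise", {
  d <- c(24L, 48L, 48L)
  vs <- c(2, 2, 2)
  nerve <- array(0L, d)
  p0 <- matrix(c(24, 10, 6), 1)
  p1 <- matrix(c(24, 86, 90), 1)
  islet3d:::cpp_raster_capsules(nerve, d, vs, p0, p1, 3, 1L, integer(0))
  truth_vol <- sum(nerve) * prod(vs)
  img <- array(100, d)
  img[nerve > 0] <- 800
  set.seed(3)
  # bright single-voxel speckles (8 um^3 each, below the 50 um^3 filter)
  for (i in 1:5) {
    at <- c(sample(3:8, 1), sample(3:44, 1), sample(3:44, 1)) # off-tube z
    img[at[1], at[2], at[3]] <- 3000
  }
  g <- voxel_grid(list(nf200 = img), voxel_size_um = vs)
  nv <- segment_nerves(g, min_object_volume_um3 = 50)
  expect_equal(n_objects(nv), 1) # speckles removed, tube kept
  expect_lt(abs(sum(nv$table$volume_um3) - truth_vol) / truth_vol, 0.30)
  nv_all <- segment_nerves(g, min_object_volume_um3 = 0)
  expect_gt(n_objects(nv_all), 1) # speckles present before the filter
  expect_equal(n_objects(segment_nerves(
    voxel_grid(list(nf200 = array(0, d)), voxel_size_um = vs))), 0)
})

test_that("TH beta-cell filter removes only small intra-islet insulin overlaps", {
  d <- c(16L, 16L, 16L)
  vs <- c(4, 4, 4)                        # 64 um^3 per voxel
  islet <- array(FALSE, d)
  islet[4:12, 4:12, 4:12] <- TRUE
  insulin <- islet
  nerve <- array(FALSE, d)
  nerve[6, 6, 6] <- TRUE                  # 64 um^3, inside islet + insulin
  nerve[2, 2, 2] <- TRUE                  # 64 um^3, outside the islet
  nerve[9:11, 9:11, 9]  <- TRUE           # 9 voxels = 576 um^3, inside islet
  objs <- connected_components(nerve, vs)
  filtered <- filter_th_beta_cells(objs, islet, insulin)
  expect_equal(n_objects(filtered), 2)
  # removed object is the small intra-islet one
  kept_vols <- sort(filtered$table$volume_um3)
  expect_equal(kept_vols, c(64, 576))
  # no removed object was >= 120 um^3 or outside islets (invariant)
  removed <- setdiff(objs$table$id, NA)
  rem_ids <- attr(filtered, "removed_ids")
  expect_true(all(objs$table$volume_um3[rem_ids] < 120))
  expect_error(filter_th_beta_cells(objs, islet[1:8, , ], insulin),
               "shape mismatch")
})

test_that("segmentation Dice degrades monotonically with noise", {
  cfg <- small_config()
  dices <- vapply(c(0, 25, 60), function(sd) {
    cfg2 <- phantom_config_override(cfg, list(
      noise = list(enabled = sd > 0, gaussian_sd = sd)))
    ph <- generate_phantom(cfg2, seed = 5, noise = sd > 0)
    isl <- segment_islets(ph$grid)
    dice_coefficient(object_mask(isl), ph$truth$islet_labels > 0L)
  }, 0)
  expect_gte(dices[1], 0.95)
  expect_true(all(diff(dices) <= 0.005)) # non-increasing within jitter
})
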