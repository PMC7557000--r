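test_that("presets carry their calibration anchors", {
  c57 <- phantom_preset("mouse_c57_default")
  expect_equal(c57$islets$volume_fraction, 0.0131)
  expect_equal(c57$islets$innervated_count_fraction, 0.061)
  expect_equal(c57$islets$innervated_volume_share, 0.43)
  expect_equal(c57$ganglia$density_per_mm3, 21.5)
  expect_equal(c57$ganglia$mean_volume_um3, 83467)
  expect_equal(c57$ganglia$islet_gap_mean_um, 47.3)
  expect_equal(c57$cells$beta_contact_fraction, 0.094)
  expect_equal(phantom_preset("mouse_c57_th")$islets$innervated_count_fraction,
               0.277)
  nod <- phantom_preset("nod_diabetic")
  expect_equal(beta_scale_vs_control(nod), 0.10)
  expect_equal(beta_scale_vs_control(phantom_preset("stz_d15")), 0.40)
  hc <- phantom_preset("human_control")
  expect_gte(hc$islets$volume_fraction, 0.0047)
  expect_lte(hc$islets$volume_fraction, 0.022)
  expect_error(phantom_preset("bogus"), "unknown preset")
  expect_error(phantom_config(islets = list(volume_fraction = 2)), "\\[0, 1\\]")
  expect_error(phantom_config(bogus_field = 1), "unknown phantom_config")
})

test_that("same config and seed give bit-identical volumes", {
  cfg <- small_config()
  a <- generate_phantom(cfg, seed = 3, noise = TRUE)
  b <- generate_phantom(cfg, seed = 3, noise = TRUE)
  expect_identical(a$grid$channels, b$grid$channels)
  expect_identical(a$truth$islets, b$truth$islets)
  c <- generate_phantom(cfg, seed = 4, noise = TRUE)
  expect_false(identical(a$grid$channels$insulin, c$grid$channels$insulin))
})

test_that("noise-free foreground sits exactly at the configured intensity", {
  ph <- small_phantom(seed = 1, noise = FALSE)
  ints <- ph$config$intensity
  ins <- ph$grid$channels$insulin
  expect_setequal(unique(as.vector(ins)), c(ints$background, ints$islet))
  expect_true(all(ins[ph$truth$islet_labels > 0L] == ints$islet))
})

test_that("truth tables are exactly consistent with truth label grids", {
  ph <- small_phantom(seed = 1, noise = FALSE)
  vox <- voxel_volume_um3(ph$grid)
  lab <- ph$truth$islet_labels
  for (i in ph$truth$islets$islet_id)
    expect_equal(ph$truth$islets$volume_rasterized_um3[i], sum(lab == i) * vox)
  glab <- ph$truth$ganglion_labels
  for (i in ph$truth$ganglia$ganglion_id)
    expect_equal(ph$truth$ganglia$volume_rasterized_um3[i],
                 sum(glab == i) * vox)
  # intra-islet nerve volume re-countable from the grids
  nm <- ph$truth$nerve_mask
  for (i in ph$truth$islets$islet_id)
    expect_equal(ph$truth$islets$intra_islet_nerve_volume_um3[i],
                 sum(nm & lab == i) * vox)
})

test_that("volume sampler reproduces the target bin mixture", {
  cfg <- phantom_preset("mouse_c57_default")
  v <- sample_islet_volumes(cfg, 10000, seed = 7)
  vd <- volume_distribution(v)
  targets <- c(3.13, 39.29, 36.58, 20.0)
  for (i in 1:4) expect_lt(abs(vd$percent[i] - targets[i]), 2)
  # mixture moments: closed-form component means are finite and ordered
  mix <- fit_volume_mixture(cfg$islets$bin_edges, cfg$islets$bin_weights,
                            cfg$islets$volume_range_um3)
  expect_true(all(diff(mix$mean) > 0))
  expect_true(all(mix$mean > mix$lo & mix$mean < mix$hi))
})

test_that("two-population innervation calibration implies the size ratio", {
  f <- 0.061
  s <- 0.43
  r <- s * (1 - f) / (f * (1 - s))
  expect_gte(r, 10) # consistent with the 10-fold size claim
  expect_equal(r, 11.614, tolerance = 1e-3)
  set.seed(12)
  v <- sample_islet_volumes(phantom_preset("mouse_c57_default"), 3000)
  inn <- islet3d:::designate_innervated(v, f, s)
  expect_equal(sum(inn), round(f * 3000))
  expect_lt(abs(sum(v[inn]) / sum(v) - s), 0.01)
  expect_false(any(islet3d:::designate_innervated(v, 0, 0)))
})

test_that("zero islets and zero innervation degenerate cleanly", {
  cfg <- small_config(islets = list(volume_fraction = 0))
  spec <- sample_islets(cfg, seed = 1)
  expect_equal(nrow(spec), 0)
  # zero innervated fraction: no nerve voxel inside any islet
  cfg2 <- small_config(islets = list(innervated_count_fraction = 0))
  ph <- generate_phantom(cfg2, seed = 6, noise = FALSE)
  expect_equal(sum(ph$truth$nerve_mask & ph$truth$islet_labels > 0L), 0)
  expect_true(all(ph$truth$islets$min_nerve_distance_um > 0, na.rm = TRUE))
})

test_that("capsule rasterization volume approaches pi r^2 L", {
  d <- c(18L, 18L, 224L)
  vs <- c(0.5, 0.5, 0.5)
  m <- array(0L, d)
  islet3d:::cpp_raster_capsules(m, d, vs, matrix(c(4.5, 4.5, 6), 1),
                                matrix(c(4.5, 4.5, 106), 1), 3, 1L,
                                integer(0))
  # long straight tube: voxel volume within 10% of pi r^2 L
  expected <- pi * 9 * 100
  expect_lt(abs(sum(m) * prod(vs) - expected) / expected, 0.10)
})

test_that("nerve tree honours islet clearance and density-ratio budget", {
  ph <- small_phantom(seed = 1, noise = FALSE)
  segs <- ph$truth$nerve_segments
  expect_true(all(c("chord", "trunk") %in% segs$kind) ||
              sum(ph$truth$islets$innervated) == 0)
  # only designated islets are touched by nerve voxels
  touched <- unique(ph$truth$islet_labels[ph$truth$nerve_mask &
                                          ph$truth$islet_labels > 0L])
  designated <- ph$truth$islets$islet_id[ph$truth$islets$innervated]
  expect_true(all(touched %in% designated))
  # realized endocrine:exocrine density ratio from the truth grids
  vi <- sum(ph$truth$islets$volume_rasterized_um3)
  vt <- ph$truth$tissue_volume_mm3 * 1e9
  endo <- ph$truth$endocrine_nerve_volume_um3 / vi
  exo <- ph$truth$exocrine_nerve_volume_um3 / (vt - vi)
  if (sum(ph$truth$islets$innervated) > 0) expect_gte(endo / exo, 6)
})

test_that("ganglion placement follows density, volume and gap targets", {
  cfg <- small_config(ganglia = list(density_per_mm3 = 300, sdlog = 0.25))
  set.seed(21)
  spec <- sample_islets(cfg)
  gang <- place_ganglia(cfg, spec)
  expect_gt(nrow(gang), 5)
  expect_lt(abs(mean(gang$volume_um3) - 83467) / 83467, 0.15)
  expect_true(all(gang$target_gap_um >= cfg$ganglia$min_gap_um))
  cfg0 <- small_config(ganglia = list(density_per_mm3 = 0))
  set.seed(22)
  spec0 <- sample_islets(cfg0)
  expect_equal(nrow(place_ganglia(cfg0, spec0)), 0)
})

test_that("cell phantom truth is voxel-consistent and calibrated", {
  cp <- generate_cell_phantom("mouse_c57_default", seed = 3, noise = FALSE)
  tc <- cp$truth$cells
  # contacts recomputed from grids equal the stored flags by construction;
  # designated and realized contacts agree for nearly every cell
  agree <- mean(tc$designated_contact == tc$contacts_nerve)
  expect_gte(agree, 0.98)
  # nerve stubs never overlap a non-designated cell
  lab <- cp$truth$cell_labels
  touched <- unique(lab[cp$truth$nerve_mask & lab > 0L])
  expect_true(all(tc$designated_contact[touched]))
  # beta fraction near target
  expect_lt(abs(mean(tc$cell_type == "beta") - 0.8), 0.06)
})
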