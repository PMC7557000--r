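test_that("voxel grids validate their invariants", {
  a <- array(runif(2 * 3 * 4), c(2, 3, 4))
  g <- voxel_grid(list(insulin = a, nf200 = a * 2), voxel_size_um = c(5, 5, 5))
  expect_identical(dim(g), dim(a))
  expect_equal(voxel_volume_um3(g), 125)
  expect_error(voxel_grid(list(a)), "named")
  expect_error(voxel_grid(list(insulin = a, nf200 = array(0, c(2, 3, 5)))),
               "identical shape")
  expect_error(voxel_grid(list(insulin = a), voxel_size_um = c(5, -1, 5)),
               "positive")
  expect_error(voxel_grid(list(insulin = a)), "missing voxel size")
  # magnification presets carry the acquisition pitches (z, y, x)
  g4 <- voxel_grid(list(insulin = a), magnification = "4x")
  expect_equal(g4$voxel_size_um, c(5, 1.63, 1.63))
  expect_equal(voxel_grid(list(insulin = a),
                          magnification = "1.3x")$voxel_size_um, c(5, 5, 5))
  expect_error(voxel_grid(list(insulin = a), voxel_size_um = c(5, 5, 5),
                          region_mask = array(0L, c(1, 1, 1))), "same shape")
})

test_that("TIFF round trip preserves shape, channel order and voxel size", {
  set.seed(7)
  a <- array(runif(32 * 64 * 64) * 900, c(32, 64, 64))
  b <- array(runif(32 * 64 * 64) * 300, c(32, 64, 64))
  g <- voxel_grid(list(insulin = a, nf200 = b), voxel_size_um = c(5, 5, 5))
  path <- file.path(tempdir(), "roundtrip.tif")
  write_volume(g, path)
  r <- read_volume(path)
  expect_identical(names(r$channels), c("insulin", "nf200"))
  expect_identical(dim(r), dim(g))
  expect_equal(r$voxel_size_um, g$voxel_size_um)
  # float32 storage: intensities to single precision
  expect_lt(max(abs(r$channels$insulin - a)), 1e-3 * max(a))
  # explicit voxel size overrides metadata
  r2 <- read_volume(path, voxel_size_um = c(2, 1.63, 1.63))
  expect_equal(r2$voxel_size_um, c(2, 1.63, 1.63))
  # plain TIFF with neither metadata nor explicit size errors
  plain <- file.path(tempdir(), "plain.tif")
  tiff::writeTIFF(lapply(1:4, function(i) matrix(runif(16), 4, 4)), plain)
  expect_error(read_volume(plain), "missing voxel size")
  expect_s3_class(read_volume(plain, voxel_size_um = c(5, 5, 5)), "voxel_grid")
  expect_error(read_volume(plain, channel_names = c("a", "b", "c")),
               "channel-count mismatch")
  expect_error(read_volume(file.path(tempdir(), "nope.tif")), "no such file")
})

test_that("maximum projection is the elementwise max over z", {
  z <- array(0, c(4, 3, 5))
  g <- voxel_grid(list(insulin = z), voxel_size_um = c(5, 5, 5))
  expect_equal(max_projection(g, "insulin"), matrix(0, 3, 5))
  z[3, 1, 2] <- 7
  g <- voxel_grid(list(insulin = z), voxel_size_um = c(5, 5, 5))
  mp <- max_projection(g, "insulin")
  expect_equal(mp[1, 2], 7)
  expect_equal(sum(mp), 7)
  # ramp along z equals the top slice; projection dominates every slice
  ramp <- array(rep(1:6, each = 1, times = 20), c(6, 4, 5))
  for (k in 1:6) ramp[k, , ] <- k * matrix(runif(20), 4, 5)
  g <- voxel_grid(list(insulin = ramp), voxel_size_um = c(5, 5, 5))
  mp <- max_projection(g, "insulin")
  oracle <- apply(ramp, c(2, 3), max)
  expect_equal(mp, oracle)
  for (k in 1:6) expect_true(all(mp >= ramp[k, , ]))
  expect_error(max_projection(g, "bogus"), "unknown channel")
})

test_that("write_results emits deterministic CSVs and a manifest", {
  tabs <- list(per_islet = data.frame(id = 1:3, volume_um3 = c(1, 2.5, 3)),
               per_group = data.frame(group = "a", mean = 1.23456789))
  d1 <- file.path(tempdir(), "out1")
  d2 <- file.path(tempdir(), "out2")
  f1 <- write_results(tabs, d1)
  f2 <- write_results(tabs, d2)
  expect_setequal(f1, c("per_islet.csv", "per_group.csv"))
  m <- read.csv(file.path(d1, "manifest.csv"))
  expect_setequal(m$file, f1)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e5),
                     readBin(file.path(d2, f), "raw", 1e5))
  # empty result: manifest with zero data files, no error
  d3 <- file.path(tempdir(), "out3")
  f3 <- write_results(list(), d3)
  expect_length(f3, 0)
  expect_true(file.exists(file.path(d3, "manifest.csv")))
})
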