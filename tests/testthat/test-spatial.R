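test_that("distance field reproduces hand geometry, isotropic and not", {
  d <- c(8L, 8L, 8L)
  m <- array(FALSE, d)
  m[1, 1, 1] <- TRUE
  df <- distance_field(m, c(1, 1, 1))
  expect_equal(df[1, 1, 1], 0)
  expect_equal(df[1, 4, 5], 5) # 3-4-5 triangle
  # anisotropic: 2 voxels along z at 5 um pitch = 10 um
  df5 <- distance_field(m, c(5, 1, 1))
  expect_equal(df5[3, 1, 1], 10)
  expect_error(distance_field(array(FALSE, d), c(1, 1, 1)), "empty mask")
})

test_that("distance field equals the brute-force oracle on small grids", {
  set.seed(42)
  for (rep in 1:6) {
    d <- sample(3:16, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.08, d)
    if (!any(m)) m[1] <- TRUE
    vs <- sample(c(1, 1.63, 2, 5), 3, replace = TRUE)
    expect_equal(distance_field(m, vs), brute_force_edt(m, vs),
                 tolerance = 1e-12)
  }
})

test_that("dilating the nerve mask never increases islet distances", {
  ph <- small_phantom(seed = 1, noise = FALSE)
  islets <- segment_islets(ph$grid)
  nerve <- ph$truth$nerve_mask
  rec1 <- islet_nerve_distances(islets, nerve)
  grown <- array(islet3d:::cpp_edt3d(as.integer(nerve), as.integer(dim(nerve)),
                                     c(1, 1, 1)) <= 1, dim(nerve))
  rec2 <- islet_nerve_distances(islets, grown)
  expect_true(all(rec2$min_nerve_distance_um <=
                  rec1$min_nerve_distance_um + 1e-9))
})

test_that("islet nerve distances implement the touching/near semantics", {
  d <- c(12L, 20L, 20L)
  vs <- c(5, 5, 5)
  islet <- array(FALSE, d)
  islet[4:6, 4:6, 4:6] <- TRUE
  islets <- connected_components(islet, vs)
  # sharing one voxel: innervated, distance exactly 0
  nerve <- array(FALSE, d)
  nerve[6, 6, 6] <- TRUE
  rec <- islet_nerve_distances(islets, nerve)
  expect_true(rec$innervated)
  expect_equal(rec$min_nerve_distance_um, 0)
  expect_true(rec$near_nerve)
  expect_equal(rec$intra_islet_nerve_volume_um3, 125)
  # distant nerve voxel (brute-force pairwise oracle): neither flag set
  nerve2 <- array(FALSE, d)
  nerve2[6, 6, 19] <- TRUE # 13 voxels * 5 um = 65 um from the islet face
  rec2 <- islet_nerve_distances(islets, nerve2)
  idx <- which(islet, arr.ind = TRUE)
  nidx <- which(nerve2, arr.ind = TRUE)
  brute <- min(sqrt(((idx[, 1] - nidx[1]) * 5)^2 +
                    ((idx[, 2] - nidx[2]) * 5)^2 +
                    ((idx[, 3] - nidx[3]) * 5)^2))
  expect_equal(rec2$min_nerve_distance_um, brute)
  expect_false(rec2$innervated)
  expect_false(rec2$near_nerve)
  # empty nerve mask: undefined distances, explicitly not innervated
  rec3 <- islet_nerve_distances(islets, array(FALSE, d))
  expect_true(is.na(rec3$min_nerve_distance_um))
  expect_false(rec3$innervated)
  expect_equal(rec3$intra_islet_nerve_volume_um3, 0)
})

test_that("intra-islet nerve volume counts shared voxels exactly", {
  d <- c(30L, 30L, 30L)
  vs <- c(5, 5, 5)
  islet <- array(FALSE, d)
  islet[5:26, 5:26, 5:26] <- TRUE # 22^3 > 10,000 voxels
  islets <- connected_components(islet, vs)
  nerve <- array(FALSE, d)
  nerve[15, 15, 3:27] <- TRUE # tube crossing: 22 voxels shared
  nerve[15, 15, 1:2] <- TRUE
  rec <- islet_nerve_distances(islets, nerve)
  expect_equal(rec$intra_islet_nerve_volume_um3, 22 * 125)
  # conservation: intra <= total nerve volume and <= islet volume
  expect_lte(rec$intra_islet_nerve_volume_um3, sum(nerve) * 125)
  expect_lte(rec$intra_islet_nerve_volume_um3, rec$volume_um3)
})

test_that("innervation classifier partitions and sums to 100", {
  rec <- data.frame(islet_id = 1:100, volume_um3 = runif(100, 1e3, 1e5),
                    region = rep(c(1L, 2L), 50),
                    min_nerve_distance_um = c(rep(0, 6), runif(94, 2, 80)))
  rec$innervated <- rec$min_nerve_distance_um == 0
  rec$near_nerve <- rec$min_nerve_distance_um < 1.6
  cls <- classify_innervation(rec)
  tot <- cls[cls$scope == "total", ]
  expect_equal(tot$pct_innervated, 6.0)
  expect_equal(tot$pct_innervated + tot$pct_not_innervated, 100)
  expect_equal(tot$pct_near_nerve + tot$pct_beyond_cutoff, 100)
  expect_setequal(cls$scope, c("total", "duodenal", "splenic"))
  all_inn <- rec
  all_inn$innervated <- TRUE
  all_inn$near_nerve <- TRUE
  expect_equal(classify_innervation(all_inn)$pct_innervated[1], 100)
  expect_error(classify_innervation(rec[0, ]), "no islet records")
})

test_that("ganglion metrics: density arithmetic and islet distances", {
  d <- c(20L, 40L, 40L)
  vs <- c(5, 5, 5) # tissue 20*40*40*125 um^3 = 0.004 mm^3
  tissue <- array(TRUE, d)
  glab <- array(FALSE, d)
  glab[3:5, 3:5, 3:5] <- TRUE
  glab[12:14, 30:32, 30:32] <- TRUE
  ganglia <- connected_components(glab, vs)
  islet <- array(FALSE, d)
  islet[3:5, 3:5, 3:5] <- TRUE # overlaps ganglion 1
  gm <- ganglion_metrics(ganglia, islet, tissue, vs)
  expect_equal(gm$density_per_mm3, 2 / 0.004)
  expect_equal(sort(gm$records$distance_to_nearest_islet_um)[1], 0)
  # second ganglion: nearest-face distance via brute oracle
  gi <- which(glab & !islet, arr.ind = TRUE)
  ii <- which(islet, arr.ind = TRUE)
  brute <- min(apply(gi, 1, function(p)
    min(sqrt(colSums((t(ii) - p)^2)) * 5)))
  expect_equal(max(gm$records$distance_to_nearest_islet_um), brute)
  expect_error(ganglion_metrics(ganglia, islet, array(FALSE, d), vs),
               "empty tissue")
  # no islets: distances undefined
  gm2 <- ganglion_metrics(ganglia, array(FALSE, d), tissue, vs)
  expect_true(all(is.na(gm2$records$distance_to_nearest_islet_um)))
})

test_that("ganglion detector accepts blobs and rejects tubes", {
  cfg <- small_config()
  ph <- generate_phantom(cfg, seed = 2, noise = FALSE)
  gg <- detect_ganglia(ph$grid)
  expect_equal(n_objects(gg), nrow(ph$truth$ganglia))
  # on the nerve channel the fiber tree must not be classified as a ganglion
  gg_nerve <- detect_ganglia(ph$grid, channel = "nf200")
  expect_equal(n_objects(gg_nerve), 0)
})

test_that("cell contacts: shared-voxel rule and per-islet percentages", {
  d <- c(10L, 30L, 30L)
  vs <- c(5, 1.67, 1.67)
  cells <- array(0L, d)
  for (i in 1:10) cells[5, 3 * i + c(-1, 0), 10:12] <- i
  cellobj <- islet3d:::connected_components_from_labels(cells, vs)
  nerve <- array(FALSE, d)
  nerve[5, 3 * (1:3), 11] <- TRUE # overlaps cells 1..3
  cc <- cell_nerve_contacts(cellobj, nerve)
  expect_equal(sum(cc$records$contacts_nerve), 3)
  expect_equal(cc$percent_contacting$percent_contacting, 30)
  # no nerve voxels: zero percent
  cc0 <- cell_nerve_contacts(cellobj, array(FALSE, d))
  expect_equal(cc0$percent_contacting$percent_contacting, 0)
  expect_error(cell_nerve_contacts(list(), nerve), "no cells")
})

test_that("watershed cell segmentation splits touching-but-gapped cells", {
  cp <- generate_cell_phantom("mouse_c57_default", seed = 9, noise = FALSE)
  beta <- segment_cells(cp$grid, "insulin")
  truth_n <- sum(cp$truth$cells$cell_type == "beta")
  expect_gt(n_objects(beta), 0.9 * truth_n)
  expect_lte(n_objects(beta), 1.05 * truth_n)
})
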