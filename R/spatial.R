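#' Anisotropy-aware Euclidean distance field
#'
#' Exact Euclidean distance (um) from every voxel center to the nearest
#' foreground voxel center of `target_mask`, computed with the separable
#' lower-envelope algorithm using the physical voxel pitch per axis.
#' Distances are center-to-center, not meshed-surface distances; the
#' discretization error is bounded by one voxel pitch.
#'
#' @param target_mask logical 3D array with at least one foreground voxel.
#' @param voxel_size_um numeric `(z, y, x)` in um.
#' @return numeric 3D array of distances; 0 on foreground.
#' @export
distance_field <- function(target_mask, voxel_size_um) {
  if (!any(target_mask))
    stop("empty mask: no target present, distances are undefined",
         call. = FALSE)
  d <- dim(target_mask)
  out <- cpp_edt3d(as.integer(target_mask), as.integer(d),
                   as.numeric(voxel_size_um))
  dim(out) <- d
  out
}

#' Per-islet nerve distances and innervation flags
#'
#' For each islet the minimum of the nerve distance field over its voxels is
#' reported. An islet is `innervated` when that minimum is 0, i.e. it shares
#' at least one voxel with the nerve foreground (distance 0 = islet touching
#' nerve). `near_nerve` applies the secondary cutoff (`< distance_cutoff_um`,
#' default 1.6 um, about one xy voxel at 4x). The intra-islet nerve volume is
#' the volume of nerve-and-islet voxels.
#'
#' With an empty nerve mask all distances are `NA` (undefined, not an
#' infinite sentinel) and every islet is non-innervated.
#'
#' @param islets a `labeled_objects` from [segment_islets()].
#' @param nerve_mask logical array of nerve foreground.
#' @param voxel_size_um numeric `(z, y, x)` in um.
#' @param distance_cutoff_um secondary near-nerve cutoff.
#' @return data.frame of islet records (one row per islet).
#' @export
islet_nerve_distances <- function(islets, nerve_mask,
                                  voxel_size_um = islets$voxel_size_um,
                                  distance_cutoff_um = 1.6) {
  stopifnot(inherits(islets, "labeled_objects"))
  lab <- islets$labels
  if (!identical(dim(lab), dim(nerve_mask)))
    stop("shape mismatch between islet labels and nerve mask")
  tab <- islets$table
  n <- nrow(tab)
  rec <- data.frame(islet_id = tab$id,
                    volume_um3 = tab$volume_um3,
                    region = tab$region)
  for (cl in grep("^intensity_sum_", names(tab), value = TRUE))
    rec[[cl]] <- tab[[cl]]
  if (n == 0L) {
    rec$min_nerve_distance_um <- numeric(0)
    rec$innervated <- logical(0)
    rec$near_nerve <- logical(0)
    rec$intra_islet_nerve_volume_um3 <- numeric(0)
    return(rec)
  }
  vox_vol <- prod(voxel_size_um)
  if (!any(nerve_mask)) {
    rec$min_nerve_distance_um <- NA_real_
    rec$innervated <- FALSE
    rec$near_nerve <- NA
    rec$intra_islet_nerve_volume_um3 <- 0
    return(rec)
  }
  dfield <- distance_field(nerve_mask, voxel_size_um)
  rec$min_nerve_distance_um <- cpp_tab_min(lab, as.numeric(dfield), n)
  rec$innervated <- rec$min_nerve_distance_um == 0
  rec$near_nerve <- rec$min_nerve_distance_um < distance_cutoff_um
  rec$intra_islet_nerve_volume_um3 <-
    cpp_tab_sum(lab, as.numeric(nerve_mask), n) * vox_vol
  rec
}

#' Innervation partition summary
#'
#' Counts and percentages of innervated (distance 0) versus non-innervated
#' islets and of the near/far distance bins, overall and per region.
#'
#' @param records islet records from [islet_nerve_distances()].
#' @param distance_cutoff_um cutoff used for the near/far bins (reported
#'   alongside; the `near_nerve` flags in `records` are taken as-is).
#' @return data.frame with one row per scope (`total`, `duodenal`,
#'   `splenic`).
#' @export
classify_innervation <- function(records, distance_cutoff_um = 1.6) {
  if (nrow(records) == 0L) stop("no islet records to classify")
  one <- function(r, scope) {
    n <- nrow(r)
    ninn <- sum(r$innervated)
    nnear <- sum(r$near_nerve)
    data.frame(scope = scope,
               n_islets = n,
               n_innervated = ninn,
               pct_innervated = 100 * ninn / n,
               pct_not_innervated = 100 * (n - ninn) / n,
               pct_near_nerve = 100 * nnear / n,
               pct_beyond_cutoff = 100 * (n - nnear) / n,
               distance_cutoff_um = distance_cutoff_um)
  }
  out <- one(records, "total")
  for (rg in c(1L, 2L)) {
    sub <- records[!is.na(records$region) & records$region == rg, , drop = FALSE]
    if (nrow(sub) > 0L)
      out <- rbind(out, one(sub, c("duodenal", "splenic")[rg]))
  }
  rownames(out) <- NULL
  out
}

#' Detect intrapancreatic ganglia in a neural channel
#'
#' Ganglia (clusters of neuronal cell bodies) are compact, roughly
#' spheroidal objects, unlike tubular fibers. Detection segments the stated
#' channel with a wide background window (so that cell-body blobs survive
#' the local-contrast subtraction intact) and classifies components as
#' ganglia when their volume lies within `volume_range_um3` and their
#' voxelized sphericity is at least `sphericity_min`. Externally supplied
#' ganglion label grids can bypass this via [ganglion_metrics()].
#'
#' @param grid a `voxel_grid`.
#' @param channel channel containing ganglion staining.
#' @param volume_range_um3 acceptance window, default `[20000, 400000]`.
#' @param sphericity_min minimum sphericity (pi^(1/3) (6V)^(2/3) / A with a
#'   voxelized surface-area estimate, which undershoots the ideal sphere at
#'   about 0.67), default 0.4.
#' @param params optional explicit `segmentation_params` override.
#' @return a `labeled_objects` of ganglia.
#' @export
detect_ganglia <- function(grid, channel = "ganglion",
                           volume_range_um3 = c(20000, 400000),
                           sphericity_min = 0.4, params = NULL) {
  if (is.null(params))
    params <- segmentation_params(channel = channel,
                                  background_diameter_um = 150,
                                  smoothing_um = 3.25)
  mask <- local_contrast_threshold(grid, params)
  obj <- connected_components(mask, grid$voxel_size_um,
                              connectivity = params$connectivity,
                              intensity_channels = grid$channels,
                              region_mask = grid$region_mask)
  tab <- obj$table
  if (nrow(tab) == 0L) return(obj)
  sph <- sphericity(tab$volume_um3, tab$surface_area_um2)
  keep <- which(tab$volume_um3 >= volume_range_um3[1L] &
                tab$volume_um3 <= volume_range_um3[2L] &
                sph >= sphericity_min)
  subset_objects(obj, keep)
}

sphericity <- function(volume, area) pi^(1 / 3) * (6 * volume)^(2 / 3) / area

subset_objects <- function(objects, keep) {
  n <- nrow(objects$table)
  remap <- integer(n + 1L)
  remap[keep + 1L] <- seq_along(keep)
  lab <- remap[objects$labels + 1L]
  dim(lab) <- dim(objects$labels)
  tab <- objects$table[keep, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new_labeled_objects(lab, tab, objects$voxel_size_um, objects$connectivity)
}

#' Ganglion morphometry and density
#'
#' Density is the ganglion count per cubic millimetre of tissue
#' (1 mm^3 = 1e9 um^3); per ganglion the volume and the minimum Euclidean
#' distance from its voxels to the nearest islet voxel are reported
#' (0 when overlapping an islet; `NA` when no islets exist).
#'
#' @param ganglia a `labeled_objects` (from [detect_ganglia()] or an
#'   externally supplied label grid wrapped via [connected_components()]).
#' @param islet_mask logical array of islet foreground.
#' @param tissue_mask logical array of tissue foreground (volume > 0).
#' @param voxel_size_um numeric `(z, y, x)` in um.
#' @return list with `records` (data.frame: ganglion_id, volume_um3,
#'   centroid, distance_to_nearest_islet_um, region) and
#'   `density_per_mm3`.
#' @export
ganglion_metrics <- function(ganglia, islet_mask, tissue_mask,
                             voxel_size_um = ganglia$voxel_size_um) {
  stopifnot(inherits(ganglia, "labeled_objects"))
  if (!any(tissue_mask)) stop("empty tissue mask: density undefined")
  tissue_mm3 <- sum(tissue_mask) * prod(voxel_size_um) / 1e9
  tab <- ganglia$table
  n <- nrow(tab)
  dist_islet <- if (n == 0L) numeric(0)
  else if (!any(islet_mask)) rep(NA_real_, n)
  else {
    dfield <- distance_field(islet_mask, voxel_size_um)
    cpp_tab_min(ganglia$labels, as.numeric(dfield), n)
  }
  records <- data.frame(ganglion_id = tab$id,
                        volume_um3 = tab$volume_um3,
                        centroid_z_um = tab$centroid_z_um,
                        centroid_y_um = tab$centroid_y_um,
                        centroid_x_um = tab$centroid_x_um,
                        distance_to_nearest_islet_um = dist_islet,
                        region = tab$region)
  list(records = records, density_per_mm3 = n / tissue_mm3,
       tissue_volume_mm3 = tissue_mm3)
}

#' Segment individual endocrine cells at high resolution
#'
#' Cells are detected by thresholding the stated channel, then splitting
#' touching cells with an intensity-depth watershed: seeds are local maxima
#' of the interior depth map (distance to background) pruned to a minimum
#' physical separation of about one cell diameter, and masked voxels are
#' assigned to their geodesically nearest seed. Adjacent cells that cannot
#' be split are counted as one object.
#'
#' @param grid a `voxel_grid` at high resolution (12x or confocal10x).
#' @param channel cell channel (insulin for beta, glucagon for alpha cells).
#' @param min_seed_separation_um minimum seed spacing, default 8 um
#'   (approximate endocrine cell diameter).
#' @param intensity_threshold `"auto_otsu"` or absolute.
#' @param min_cell_volume_um3 drop fragments below this volume.
#' @return a `labeled_objects` of cells.
#' @export
segment_cells <- function(grid, channel, min_seed_separation_um = 8,
                          intensity_threshold = "auto_otsu",
                          min_cell_volume_um3 = 30) {
  img <- get_channel(grid, channel)
  vs <- grid$voxel_size_um
  thr <- if (identical(intensity_threshold, "auto_otsu"))
    otsu_threshold(img) else intensity_threshold
  mask <- img > thr
  if (!any(mask))
    return(new_labeled_objects(array(0L, dim(img)),
                               empty_object_table(grid$channels), vs, 6L))
  d <- dim(mask)
  depth <- cpp_edt3d(as.integer(!mask), as.integer(d), as.numeric(vs))
  idx <- cpp_local_maxima(depth, as.integer(d), as.integer(mask))
  # greedy pruning by decreasing depth with a physical minimum separation
  ord <- idx[order(depth[idx], decreasing = TRUE)]
  co <- arrayInd(ord, d)
  pos <- sweep(co, 2L, vs, `*`)
  chosen <- integer(0)
  for (i in seq_along(ord)) {
    if (length(chosen) > 0L) {
      dd <- sqrt(colSums((t(pos[chosen, , drop = FALSE]) - pos[i, ])^2))
      if (min(dd) < min_seed_separation_um) next
    }
    chosen <- c(chosen, i)
  }
  seeds <- array(0L, d)
  seeds[ord[chosen]] <- seq_along(chosen)
  lab <- cpp_grow_labels(as.integer(seeds), as.integer(mask), as.integer(d),
                         as.numeric(vs))
  dim(lab) <- d
  connected_components_from_labels(lab, vs, grid)
}

# build a labeled_objects from an existing label grid (labels need not be
# contiguous; re-tabulated exactly like connected_components)
connected_components_from_labels <- function(lab, voxel_size_um, grid = NULL,
                                             min_object_volume_um3 = 0) {
  d <- dim(lab)
  n <- max(lab, 0L)
  channels <- if (!is.null(grid)) grid$channels else NULL
  region_mask <- if (!is.null(grid)) grid$region_mask else NULL
  if (n == 0L)
    return(new_labeled_objects(lab, empty_object_table(channels),
                               voxel_size_um, 6L))
  counts <- cpp_tab_count(lab, n)
  keep <- which(counts > 0L & counts * prod(voxel_size_um) >= min_object_volume_um3)
  remap <- integer(n + 1L)
  remap[keep + 1L] <- seq_along(keep)
  lab <- remap[lab + 1L]
  dim(lab) <- d
  n <- length(keep)
  counts <- counts[keep]
  cent <- cpp_tab_centroid(lab, as.integer(d), as.numeric(voxel_size_um), n)
  surf <- cpp_tab_surface(lab, as.integer(d), as.numeric(voxel_size_um), n)
  tab <- data.frame(id = seq_len(n), voxels = counts,
                    volume_um3 = counts * prod(voxel_size_um),
                    centroid_z_um = cent[, 1L], centroid_y_um = cent[, 2L],
                    centroid_x_um = cent[, 3L],
                    surface_area_um2 = surf$area,
                    touches_border = surf$touches_border)
  if (!is.null(channels))
    for (ch in names(channels)) {
      s <- cpp_tab_sum(lab, as.numeric(channels[[ch]]), n)
      tab[[paste0("intensity_sum_", ch)]] <- s
      tab[[paste0("intensity_mean_", ch)]] <- s / counts
    }
  tab$region <- if (!is.null(region_mask)) {
    r1 <- cpp_tab_sum(lab, as.numeric(region_mask == 1L), n)
    r2 <- cpp_tab_sum(lab, as.numeric(region_mask == 2L), n)
    ifelse(r1 >= r2, 1L, 2L)
  } else NA_integer_
  new_labeled_objects(lab, tab, voxel_size_um, 6L)
}

#' Endocrine cell / nerve contacts
#'
#' A cell contacts a nerve if and only if its minimum distance to the nerve
#' foreground is 0, i.e. cell and nerve share at least one voxel. Reports
#' per-cell records and the percentage of contacting cells per islet and
#' cell type. The number of contacts per cell is deliberately not counted.
#'
#' @param cells a `labeled_objects` of segmented cells (or a named list of
#'   them, e.g. `list(beta = ..., alpha = ...)`).
#' @param nerve_mask logical array of nerve foreground.
#' @param islet_labels optional islet label array for assigning cells to
#'   islets (by their centroid voxel); cells outside any islet are flagged
#'   orphan (islet 0).
#' @return list with `records` (cell_id, cell_type, islet_id,
#'   contacts_nerve) and `percent_contacting` (per islet and type).
#' @export
cell_nerve_contacts <- function(cells, nerve_mask, islet_labels = NULL) {
  if (inherits(cells, "labeled_objects")) cells <- list(beta = cells)
  recs <- list()
  for (ty in names(cells)) {
    obj <- cells[[ty]]
    n <- nrow(obj$table)
    if (n == 0L) next
    if (!identical(dim(obj$labels), dim(nerve_mask)))
      stop("shape mismatch between cell labels and nerve mask")
    overlap <- cpp_tab_sum(obj$labels, as.numeric(nerve_mask), n)
    islet_id <- if (!is.null(islet_labels)) {
      ci <- round(cbind(obj$table$centroid_z_um, obj$table$centroid_y_um,
                        obj$table$centroid_x_um) /
                    rep(obj$voxel_size_um, each = n) + 0.5)
      ci[ci < 1L] <- 1L
      for (a in 1:3) ci[ci[, a] > dim(islet_labels)[a], a] <- dim(islet_labels)[a]
      islet_labels[ci]
    } else 1L
    recs[[ty]] <- data.frame(cell_id = obj$table$id, cell_type = ty,
                             islet_id = as.integer(islet_id),
                             contacts_nerve = overlap > 0)
  }
  if (length(recs) == 0L) stop("no cells segmented")
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  agg <- aggregate(contacts_nerve ~ cell_type + islet_id, data = records,
                   FUN = function(x) 100 * mean(x))
  names(agg)[names(agg) == "contacts_nerve"] <- "percent_contacting"
  ncell <- aggregate(cell_id ~ cell_type + islet_id, data = records,
                     FUN = length)
  agg$n_cells <- ncell$cell_id
  list(records = records, percent_contacting = agg)
}
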