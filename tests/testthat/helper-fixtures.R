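# Shared fixtures, built once per test run and memoized. Full-size phantom
# runs are expensive; everything that can use a small grid does.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

small_config <- function(...) {
  phantom_config(dim = c(z = 48L, y = 160L, x = 160L), ...)
}

small_phantom <- function(seed = 1, noise = FALSE) {
  memo(sprintf("small_%d_%d", seed, noise),
       generate_phantom(small_config(), seed = seed, noise = noise))
}

# the calibrated full-size C57BL/6 condition: 512 x 512 x 128 at 5 um,
# noise disabled, seed 42; segmented once and reused
full_run_a <- function() {
  memo("run_a", {
    ph <- generate_phantom("mouse_c57_default", seed = 42, noise = FALSE)
    islets <- segment_islets(ph$grid)
    nerves <- segment_nerves(ph$grid)
    records <- islet_nerve_distances(islets, object_mask(nerves))
    tissue <- ph$grid$region_mask > 0L
    summary <- region_summary(records, object_mask(nerves), tissue,
                              ph$grid$voxel_size_um,
                              region_mask = ph$grid$region_mask,
                              tissue_mean_intensity =
                                mean(ph$grid$channels$insulin[tissue]))
    res <- list(
      truth_islets = ph$truth$islets,
      truth_mask = ph$truth$islet_labels > 0L,
      islet_mask = object_mask(islets),
      tissue_volume_mm3 = ph$truth$tissue_volume_mm3,
      records = records, summary = summary,
      comparison = innervated_comparison(records),
      innervation = classify_innervation(records))
    res$dice <- dice_coefficient(res$islet_mask, res$truth_mask)
    rm(ph, islets, nerves)
    gc(verbose = FALSE)
    res
  })
}

# pooled ganglion measurements over the protocol seeds 1..5
ganglion_pool <- function(seeds = 1:5) {
  memo(paste0("gang_", paste(seeds, collapse = "")), {
    dens <- numeric(0)
    vols <- numeric(0)
    dists <- numeric(0)
    for (s in seeds) {
      ph <- generate_phantom("mouse_c57_default", seed = s, noise = FALSE)
      islets <- segment_islets(ph$grid)
      gang <- detect_ganglia(ph$grid)
      gm <- ganglion_metrics(gang, object_mask(islets),
                             ph$grid$region_mask > 0L)
      dens <- c(dens, gm$density_per_mm3)
      vols <- c(vols, gm$records$volume_um3)
      dists <- c(dists, gm$records$distance_to_nearest_islet_um)
      rm(ph, islets, gang, gm)
      gc(verbose = FALSE)
    }
    list(mean_density = mean(dens), mean_volume = mean(vols),
         mean_distance = mean(dists), n = length(vols))
  })
}

# pooled beta-cell contact percentage over the cell-mode protocol seeds
contact_pool <- function(seeds = 1:5) {
  memo("contacts", {
    n_beta <- 0L
    n_contact <- 0L
    for (s in seeds) {
      cp <- generate_cell_phantom("mouse_c57_default", seed = s, noise = FALSE)
      beta <- segment_cells(cp$grid, "insulin")
      nf <- cp$grid$channels$nf200
      nerve_mask <- nf > otsu_threshold(nf)
      cc <- cell_nerve_contacts(list(beta = beta), nerve_mask)
      rb <- cc$records[cc$records$cell_type == "beta", ]
      n_beta <- n_beta + nrow(rb)
      n_contact <- n_contact + sum(rb$contacts_nerve)
    }
    list(percent = 100 * n_contact / n_beta, n_beta = n_beta)
  })
}

# brute-force all-pairs nearest-neighbour distance oracle (physical units)
brute_force_edt <- function(mask, voxel_size_um) {
  d <- dim(mask)
  idx <- which(mask)
  stopifnot(length(idx) > 0)
  fg <- arrayInd(idx, d)
  out <- array(Inf, d)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(nrow(all_idx))) {
    dz <- (all_idx[v, 1] - fg[, 1]) * voxel_size_um[1]
    dy <- (all_idx[v, 2] - fg[, 2]) * voxel_size_um[2]
    dx <- (all_idx[v, 3] - fg[, 3]) * voxel_size_um[3]
    out[v] <- sqrt(min(dz^2 + dy^2 + dx^2))
  }
  out
}
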