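#' Phantom configuration
#'
#' A `phantom_config` fully determines a synthetic multi-channel pancreas
#' volume: grid geometry, an ellipsoidal tissue slab split into duodenal and
#' splenic halves, an islet model (total volume fraction, a truncated
#' lognormal mixture over the standard volume bins, ellipsoid axis ratios),
#' an innervation model (count fraction of innervated islets, their share of
#' total islet volume, tube radii, tortuosity, endocrine:exocrine density
#' ratio), a ganglion model (density per mm^3, lognormal volume, gap
#' distribution from islets), a high-resolution cell model, per-channel
#' intensities and a Poisson+Gaussian noise model. The same config plus the
#' same seed reproduces the volume bit for bit.
#'
#' @param ... overrides of the default fields (nested lists are merged).
#' @return a validated `phantom_config`.
#' @export
phantom_config <- function(...) {
  cfg <- default_phantom_config()
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stop(sprintf("unknown phantom_config field '%s'", nm))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  validate_phantom_config(cfg)
}

#' Override fields of an existing phantom configuration
#' @param config a `phantom_config`.
#' @param overrides named list; nested lists are merged field-wise.
#' @return the modified, re-validated `phantom_config`.
#' @export
phantom_config_override <- function(config, overrides) {
  stopifnot(inherits(config, "phantom_config"))
  for (nm in names(overrides)) {
    if (!nm %in% names(config))
      stop(sprintf("unknown phantom_config field '%s'", nm))
    config[[nm]] <- if (is.list(config[[nm]]) && is.list(overrides[[nm]]))
      modifyList(config[[nm]], overrides[[nm]]) else overrides[[nm]]
  }
  validate_phantom_config(config)
}

default_phantom_config <- function() {
  list(
    name = "custom",
    dim = c(z = 128L, y = 512L, x = 512L),
    voxel_size_um = c(5, 5, 5),
    magnification = "1.3x",
    tissue = list(xy_fraction = 0.46, z_margin_voxels = 4L),
    islets = list(
      volume_fraction = 0.0131,
      bin_edges = c(1000, 50000, 500000),
      bin_weights = c(0.0313, 0.3929, 0.3658, 0.20),
      volume_range_um3 = c(300, 8.18e6),
      axis_ratio_max = 1.8,
      largest_islet_diameter_um = 250,
      min_gap_um = 15,
      innervated_count_fraction = 0.061,
      innervated_volume_share = 0.43),
    nerves = list(
      radius_range_um = c(2, 3.5),
      step_um = 10,
      tortuosity = 0.35,
      islet_clearance_um = 20,
      chords_per_innervated_islet = 3L,
      chord_overshoot_um = 25,
      # target > 6; the generative value leaves headroom for the volume the
      # capsule end-caps add at polyline joints when trunks are rasterized
      endo_exo_density_ratio = 7,
      fiber_length_range_um = c(400, 1200)),
    ganglia = list(
      density_per_mm3 = 21.5,
      mean_volume_um3 = 83467,
      sdlog = 0.30,
      islet_gap_mean_um = 47.3,
      islet_gap_sd_um = 20,
      min_gap_um = 8,
      axis_ratio_max = 1.4),
    cells = list(
      grid_dim = c(z = 32L, y = 120L, x = 120L),
      islet_semi_axes_um = c(50, 70, 70),
      diameter_um = 8,
      min_separation_um = 8.8,
      beta_fraction = 0.80,
      beta_contact_fraction = 0.094,
      alpha_contact_fraction = 0.45,
      nerve_stub_radius_um = 1.5,
      placement_attempts = 4000L),
    channels = list(islet = "insulin", nerve = "nf200",
                    ganglion = "ganglion"),
    intensity = list(background = 100, islet = 1000, nerve = 800,
                     ganglion = 800, alpha_cell = 900),
    noise = list(enabled = TRUE, poisson_scale = 1, gaussian_sd = 15)
  )
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$dim) == 3L, all(cfg$dim >= 8L),
            length(cfg$voxel_size_um) == 3L, all(cfg$voxel_size_um > 0))
  isl <- cfg$islets
  if (isl$volume_fraction < 0 || isl$volume_fraction > 1)
    stop("islet volume fraction must be in [0, 1]")
  # published abundance percentages can carry rounding (summing to ~99%);
  # renormalize within a 5% slack, reject anything worse
  sw <- sum(isl$bin_weights)
  if (abs(sw - 1) > 0.05) stop("islet bin weights must sum to ~1")
  cfg$islets$bin_weights <- isl$bin_weights / sw
  for (f in c(isl$innervated_count_fraction, isl$innervated_volume_share,
              cfg$cells$beta_contact_fraction, cfg$cells$alpha_contact_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (cfg$ganglia$density_per_mm3 < 0) stop("ganglion density must be >= 0")
  structure(cfg, class = "phantom_config")
}

#' Calibrated phantom presets
#'
#' Named configurations whose generative targets are the study conditions of
#' the corresponding experimental groups: `mouse_c57_default` (beta-cell
#' volume 1.31% of tissue, 6.1% of islets innervated carrying 43% of islet
#' volume, endocrine:exocrine nerve density ratio above 6, bin weights
#' 3.13/39.29/36.58/20.0%, ganglia at 21.5 per mm^3 with mean volume
#' 83,467 um^3 at 47.3 um from islets, 9.4% of beta cells contacting
#' nerves), `mouse_c57_th` (sympathetic channel, 27.7% islet contact
#' fraction), `nod_nondiabetic` / `nod_diabetic` (beta volume reduced to 10%
#' of the nondiabetic level, small-islet shift, ganglia farther from
#' islets), `stz_d5` / `stz_d15` (beta volume 40% of control by day 15,
#' ganglion volume reduced about 30%), `human_control` / `human_t2d`
#' (beta fraction within the reported donor ranges, sparser innervated
#' islets, larger ganglia).
#'
#' @param name preset name.
#' @return a `phantom_config`.
#' @export
phantom_preset <- function(name) {
  presets <- list(
    mouse_c57_default = list(),
    mouse_c57_th = list(
      channels = list(nerve = "th"),
      islets = list(innervated_count_fraction = 0.277,
                    innervated_volume_share = 0.75)),
    nod_nondiabetic = list(
      islets = list(innervated_count_fraction = 0.146,
                    innervated_volume_share = 0.60)),
    nod_diabetic = list(
      islets = list(volume_fraction = 0.0131 * 0.10,
                    bin_weights = c(0.08, 0.57, 0.27, 0.08),
                    innervated_count_fraction = 0.098,
                    innervated_volume_share = 0.60),
      ganglia = list(density_per_mm3 = 28.2, mean_volume_um3 = 59348,
                     islet_gap_mean_um = 171.7, islet_gap_sd_um = 40)),
    stz_d5 = list(
      islets = list(volume_fraction = 0.0131 * 0.60,
                    innervated_count_fraction = 0.08,
                    innervated_volume_share = 0.54)),
    stz_d15 = list(
      islets = list(volume_fraction = 0.0131 * 0.40,
                    innervated_count_fraction = 0.10,
                    innervated_volume_share = 0.54),
      ganglia = list(mean_volume_um3 = 58427)),
    human_control = list(
      islets = list(volume_fraction = 0.013,
                    innervated_count_fraction = 0.009,
                    innervated_volume_share = 0.15),
      ganglia = list(mean_volume_um3 = 300000),
      cells = list(beta_contact_fraction = 0.0415)),
    human_t2d = list(
      islets = list(volume_fraction = 0.0091,
                    innervated_count_fraction = 0.044,
                    innervated_volume_share = 0.25),
      ganglia = list(mean_volume_um3 = 300000),
      cells = list(beta_contact_fraction = 0.0607))
  )
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s' (have: %s)", name,
                 paste(names(presets), collapse = ", ")))
  cfg <- do.call(phantom_config, presets[[name]])
  cfg$name <- name
  cfg
}

# Additional scalar anchors exposed for convenience/readability
#' Scale of beta-cell volume relative to the matching non-diabetic preset
#' @param config a `phantom_config` from [phantom_preset()].
#' @return scalar (1 for non-diabetic presets).
#' @export
beta_scale_vs_control <- function(config) {
  config$islets$volume_fraction / 0.0131
}

## ---- volume mixture -------------------------------------------------------

#' Deterministic lognormal-mixture calibration to bin weights
#'
#' One truncated lognormal component per volume bin: the log-mean is the
#' bin's log-midpoint, the log-sd spans a quarter of the bin's log-width,
#' and the mixture weights equal the target bin weights, so the expected
#' bin occupancy reproduces the targets exactly while volumes within a bin
#' stay lognormal. Closed-form truncated moments are used for the mixture
#' mean.
#'
#' @param bin_edges interior bin edges (um^3).
#' @param bin_weights target weights, summing to 1.
#' @param volume_range_um3 support `(lo, hi)` closing the first/last bin.
#' @return data.frame of components: lo, hi, meanlog, sdlog, weight, mean.
#' @export
fit_volume_mixture <- function(bin_edges, bin_weights, volume_range_um3) {
  lo <- c(volume_range_um3[1L], bin_edges)
  hi <- c(bin_edges, volume_range_um3[2L])
  meanlog <- (log(lo) + log(hi)) / 2
  sdlog <- (log(hi) - log(lo)) / 4
  mean_trunc <- function(mu, s, a, b) {
    za <- (log(a) - mu) / s
    zb <- (log(b) - mu) / s
    p <- pnorm(zb) - pnorm(za)
    exp(mu + s^2 / 2) * (pnorm(zb - s) - pnorm(za - s)) / p
  }
  data.frame(lo = lo, hi = hi, meanlog = meanlog, sdlog = sdlog,
             weight = bin_weights,
             mean = mapply(mean_trunc, meanlog, sdlog, lo, hi))
}

sample_truncated_lognormal <- function(n, meanlog, sdlog, lo, hi) {
  pa <- plnorm(lo, meanlog, sdlog)
  pb <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, pa, pb), meanlog, sdlog)
}

#' Sample islet volumes from the calibrated mixture
#' @param config a `phantom_config`.
#' @param n number of volumes.
#' @param seed optional RNG seed.
#' @return numeric volumes (um^3).
#' @export
sample_islet_volumes <- function(config, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mix <- fit_volume_mixture(config$islets$bin_edges, config$islets$bin_weights,
                            config$islets$volume_range_um3)
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  sample_truncated_lognormal(n, mix$meanlog[comp], mix$sdlog[comp],
                             mix$lo[comp], mix$hi[comp])
}

## ---- tissue geometry ------------------------------------------------------

tissue_geometry <- function(config) {
  d <- config$dim
  vs <- config$voxel_size_um
  ext <- d * vs
  cy <- ext[2L] / 2
  cx <- ext[3L] / 2
  ay <- config$tissue$xy_fraction * ext[2L]
  ax <- config$tissue$xy_fraction * ext[3L]
  zlo <- config$tissue$z_margin_voxels * vs[1L]
  zhi <- ext[1L] - zlo
  inside <- function(p, margin = 0) {
    # p: matrix (n x 3) of (z, y, x) um
    ok_z <- p[, 1L] > zlo + margin & p[, 2L] < Inf & p[, 1L] < zhi - margin
    e <- ((p[, 2L] - cy) / pmax(ay - margin, 1))^2 +
         ((p[, 3L] - cx) / pmax(ax - margin, 1))^2
    ok_z & e <= 1
  }
  list(center = c(ext[1L] / 2, cy, cx), ext = ext, ay = ay, ax = ax,
       zlo = zlo, zhi = zhi, inside = inside)
}

tissue_region_mask <- function(config) {
  d <- as.integer(config$dim)
  vs <- config$voxel_size_um
  geo <- tissue_geometry(config)
  y <- (seq_len(d[2L]) - 0.5) * vs[2L]
  x <- (seq_len(d[3L]) - 0.5) * vs[3L]
  e <- outer(((y - geo$center[2L]) / geo$ay)^2,
             ((x - geo$center[3L]) / geo$ax)^2, `+`) <= 1
  region_xy <- matrix(0L, d[2L], d[3L])
  region_xy[e] <- ifelse(col(e)[e] * vs[3L] <= geo$center[3L], 1L, 2L)
  z <- (seq_len(d[1L]) - 0.5) * vs[1L]
  zin <- z > geo$zlo & z < geo$zhi
  mask <- array(0L, d)
  for (k in which(zin)) mask[k, , ] <- region_xy
  mask
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

ellipsoid_semi_axes <- function(volume, axis_ratio_max) {
  r0 <- (3 * volume / (4 * pi))^(1 / 3)
  q <- runif(2L, 1, axis_ratio_max)
  semi <- r0 * c(1, q) / prod(c(1, q))^(1 / 3)
  sample(semi) # random axis assignment
}

# distance-from-center to ellipsoid surface along unit direction u
ray_exit <- function(u, rot, semi) 1 / sqrt(sum((rot %*% u / semi)^2))

## ---- islet sampling & placement ------------------------------------------

#' Sample islet specifications
#'
#' Draws islet volumes from the calibrated mixture and designates the
#' innervated subpopulation so that both the count fraction `f` and the
#' volume share `s` targets are met jointly (implying a mean-volume ratio
#' `r = s (1 - f) / (f (1 - s))` between innervated and non-innervated
#' islets): a size-biased initial draw followed by deterministic swap
#' refinement toward the target share. With `place = TRUE` (the default
#' when `n` is not given) ellipsoid geometry is drawn and centers are
#' placed uniformly in tissue under non-overlap rejection; the islet count
#' is then chosen by drawing volumes until the target total volume is
#' reached (the last islet is shrunk or dropped to land on the target).
#'
#' @param config a `phantom_config`.
#' @param n optional number of islets (pure sampling, no placement).
#' @param seed optional RNG seed.
#' @param place place islets in tissue and draw geometry.
#' @return data.frame of islet specs: volume_um3, innervated, and (when
#'   placed) center/semi-axis columns plus a `rotations` attribute.
#' @export
sample_islets <- function(config, n = NULL, seed = NULL, place = is.null(n)) {
  if (!is.null(seed)) set.seed(seed)
  geo <- tissue_geometry(config)
  isl <- config$islets
  tissue_vol <- tissue_volume_um3(config)
  target_total <- isl$volume_fraction * tissue_vol

  if (is.null(n)) {
    # sequential draw to the target total volume; the last islet is shrunk
    # (or dropped, if that would leave a sub-minimal fragment) to land on
    # the target exactly
    vols <- numeric(0)
    total <- 0
    max_n <- 100000L
    while (total < target_total && length(vols) < max_n) {
      v <- sample_islet_volumes(config, 1L)
      vols <- c(vols, v)
      total <- total + v
    }
    if (total > target_total && length(vols) > 0L) {
      overshoot <- total - target_total
      last <- vols[length(vols)] - overshoot
      if (last >= isl$volume_range_um3[1L]) {
        vols[length(vols)] <- last
      } else {
        vols <- vols[-length(vols)]
      }
    }
    if (length(vols) == 0L)
      return(data.frame(volume_um3 = numeric(0), innervated = logical(0)))
  } else {
    if (n == 0L)
      return(data.frame(volume_um3 = numeric(0), innervated = logical(0)))
    vols <- sample_islet_volumes(config, n)
  }

  innervated <- designate_innervated(vols, isl$innervated_count_fraction,
                                     isl$innervated_volume_share)
  spec <- data.frame(islet_id = seq_along(vols), volume_um3 = vols,
                     innervated = innervated)
  if (!place) return(spec)

  nn <- nrow(spec)
  semi <- t(vapply(spec$volume_um3, ellipsoid_semi_axes, numeric(3L),
                   axis_ratio_max = isl$axis_ratio_max))
  rots <- lapply(seq_len(nn), function(i) random_rotation())
  ord <- order(spec$volume_um3, decreasing = TRUE) # pack large islets first
  centers <- matrix(NA_real_, nn, 3L)
  maxsemi <- apply(semi, 1L, max)
  placed <- integer(0)
  for (i in ord) {
    margin <- maxsemi[i] + 10
    done <- FALSE
    for (try in seq_len(400L)) {
      p <- c(runif(1L, geo$zlo, geo$zhi),
             runif(1L, geo$center[2L] - geo$ay, geo$center[2L] + geo$ay),
             runif(1L, geo$center[3L] - geo$ax, geo$center[3L] + geo$ax))
      if (!geo$inside(matrix(p, 1L), margin)) next
      if (length(placed) > 0L) {
        dd <- sqrt(colSums((t(centers[placed, , drop = FALSE]) - p)^2))
        if (any(dd < maxsemi[placed] + maxsemi[i] + isl$min_gap_um)) next
      }
      centers[i, ] <- p
      placed <- c(placed, i)
      done <- TRUE
      break
    }
    if (!done)
      stop("infeasible islet placement: rejection budget exceeded; ",
           "reduce volume fraction or grid occupancy")
  }
  spec$center_z_um <- centers[, 1L]
  spec$center_y_um <- centers[, 2L]
  spec$center_x_um <- centers[, 3L]
  spec$semi_z_um <- semi[, 1L]
  spec$semi_y_um <- semi[, 2L]
  spec$semi_x_um <- semi[, 3L]
  attr(spec, "rotations") <- rots
  spec
}

#' Tissue volume of a phantom configuration in um^3
#' @param config a `phantom_config`.
#' @export
tissue_volume_um3 <- function(config) {
  # exact voxel count of the rasterized slab
  sum(tissue_region_mask(config) > 0L) * prod(config$voxel_size_um)
}

designate_innervated <- function(vols, count_fraction, volume_share) {
  n <- length(vols)
  if (count_fraction <= 0 || n == 0L) return(rep(FALSE, n))
  # conservative (floor) rounding: count granularity and partial detection
  # of sub-resolution islets inflate the realized count fraction, which
  # would otherwise drag the implied mean-volume ratio s(1-f)/(f(1-s))
  # below the intended order-of-magnitude separation
  k <- max(1L, floor(count_fraction * n))
  k <- min(k, n)
  total <- sum(vols)
  target <- volume_share * total
  sel <- sample.int(n, k, prob = vols / total)
  in_sel <- rep(FALSE, n)
  in_sel[sel] <- TRUE
  cur <- sum(vols[sel])
  best <- abs(cur - target)
  for (iter in seq_len(6000L)) {
    if (best / total < 5e-4) break
    # batch of candidate single swaps; take the best improvement
    is <- sel[sample.int(k, min(8L, k), replace = TRUE)]
    js <- sample.int(n, 8L, replace = TRUE)
    improved <- FALSE
    for (b in seq_along(is)) {
      if (in_sel[js[b]]) next
      err <- abs(cur - vols[is[b]] + vols[js[b]] - target)
      if (err < best) {
        cur <- cur - vols[is[b]] + vols[js[b]]
        in_sel[is[b]] <- FALSE
        in_sel[js[b]] <- TRUE
        sel[which(sel == is[b])[1L]] <- js[b]
        best <- err
        improved <- TRUE
        break
      }
    }
    if (!improved && iter > 3000L && best / total < 0.005) break
  }
  out <- rep(FALSE, n)
  out[sel] <- TRUE
  out
}

## ---- nerves ---------------------------------------------------------------

# minimum scaled clearance of point(s) p (n x 3) to islet i surface proxy
islet_clear <- function(p, center, rot, semi, clearance) {
  q <- (p - matrix(center, nrow(p), 3L, byrow = TRUE)) %*% t(rot)
  s <- sqrt((q[, 1L] / (semi[1L] + clearance))^2 +
            (q[, 2L] / (semi[2L] + clearance))^2 +
            (q[, 3L] / (semi[3L] + clearance))^2)
  s >= 1
}

points_clear_of_islets <- function(p, spec, rots, clearance, skip = 0L) {
  if (nrow(spec) == 0L) return(rep(TRUE, nrow(p)))
  ok <- rep(TRUE, nrow(p))
  for (i in seq_len(nrow(spec))) {
    if (i == skip) next
    ok <- ok & islet_clear(p, c(spec$center_z_um[i], spec$center_y_um[i],
                                spec$center_x_um[i]),
                           rots[[i]],
                           c(spec$semi_z_um[i], spec$semi_y_um[i],
                             spec$semi_x_um[i]), clearance)
    if (!any(ok)) break
  }
  ok
}

#' Draw the nerve tree of a phantom
#'
#' For every innervated-designated islet a configurable number of straight
#' fiber chords is routed through the islet (guaranteeing voxel contact),
#' each kept clear of all other islets. Exocrine (trunk) fibers are smooth
#' random polylines through tissue with a physical clearance from every
#' islet; their total volume is budgeted so that the realized
#' endocrine:exocrine nerve density ratio matches the configured target.
#'
#' @param config a `phantom_config`.
#' @param islet_spec placed islet specs from [sample_islets()].
#' @param seed optional RNG seed.
#' @param islet_labels optional rasterized islet label grid; when supplied
#'   the endocrine (intra-islet) chord volume entering the exocrine budget
#'   is measured on the voxel grid rather than from the capsule formula —
#'   at coarse pitch the analytic volume of a handful of thin chords is too
#'   noisy to budget against.
#' @return data.frame of capsule segments (z0..x1, radius_um, kind,
#'   islet_id).
#' @export
draw_nerves <- function(config, islet_spec, seed = NULL, islet_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- tissue_geometry(config)
  nv <- config$nerves
  rots <- attr(islet_spec, "rotations")
  segs <- list()
  endo_vol <- 0
  chord_exo_vol <- 0

  inn_idx <- which(islet_spec$innervated)
  for (i in inn_idx) {
    ctr <- c(islet_spec$center_z_um[i], islet_spec$center_y_um[i],
             islet_spec$center_x_um[i])
    semi <- c(islet_spec$semi_z_um[i], islet_spec$semi_y_um[i],
              islet_spec$semi_x_um[i])
    for (ch in seq_len(nv$chords_per_innervated_islet)) {
      placedOK <- FALSE
      for (try in seq_len(60L)) {
        u <- rnorm(3L)
        u <- u / sqrt(sum(u^2))
        texit <- ray_exit(u, rots[[i]], semi)
        over <- nv$chord_overshoot_um
        p0 <- ctr - (texit + over) * u
        p1 <- ctr + (texit + over) * u
        if (!all(geo$inside(rbind(p0, p1), 5))) next
        ts <- seq(-(texit + over), texit + over, by = 5)
        pts <- matrix(ctr, length(ts), 3L, byrow = TRUE) + outer(ts, u)
        if (!all(points_clear_of_islets(pts, islet_spec, rots,
                                        nv$islet_clearance_um, skip = i)))
          next
        r <- runif(1L, nv$radius_range_um[1L], nv$radius_range_um[2L])
        segs[[length(segs) + 1L]] <- data.frame(
          z0 = p0[1L], y0 = p0[2L], x0 = p0[3L],
          z1 = p1[1L], y1 = p1[2L], x1 = p1[3L],
          radius_um = r, kind = "chord", islet_id = islet_spec$islet_id[i])
        endo_vol <- endo_vol + pi * r^2 * 2 * texit
        chord_exo_vol <- chord_exo_vol + pi * r^2 * 2 * over
        placedOK <- TRUE
        break
      }
      if (!placedOK && ch == 1L)
        stop("infeasible nerve routing: could not thread a chord through ",
             "islet ", islet_spec$islet_id[i])
    }
  }

  # measure chord volumes on the voxel grid when the islet raster is known
  if (!is.null(islet_labels) && length(segs) > 0L) {
    chords <- do.call(rbind, segs)
    scratch <- array(0L, dim(islet_labels))
    cpp_raster_capsules(scratch, as.integer(dim(islet_labels)),
                        as.numeric(config$voxel_size_um),
                        as.matrix(chords[, c("z0", "y0", "x0")]),
                        as.matrix(chords[, c("z1", "y1", "x1")]),
                        chords$radius_um, rep(1L, nrow(chords)), integer(0))
    vox <- prod(config$voxel_size_um)
    endo_vol <- sum(scratch > 0L & islet_labels > 0L) * vox
    chord_exo_vol <- sum(scratch > 0L & islet_labels == 0L) * vox
    rm(scratch)
  }

  # exocrine budget from the density-ratio target
  islet_vol <- if (!is.null(islet_labels))
    sum(islet_labels > 0L) * prod(config$voxel_size_um)
  else sum(islet_spec$volume_um3)
  tissue_vol <- tissue_volume_um3(config)
  exo_tissue <- tissue_vol - islet_vol
  exo_budget <- if (endo_vol > 0 && islet_vol > 0)
    (endo_vol / islet_vol) * exo_tissue / nv$endo_exo_density_ratio -
      chord_exo_vol
  else 0.0003 * exo_tissue # sparse background innervation, no islet contact
  exo_vol <- 0
  guard <- 0L
  while (exo_vol < exo_budget && guard < 2000L) {
    guard <- guard + 1L
    r <- runif(1L, nv$radius_range_um[1L], nv$radius_range_um[2L])
    target_len <- runif(1L, nv$fiber_length_range_um[1L],
                        nv$fiber_length_range_um[2L])
    # random start with clearance
    p <- NULL
    for (try in seq_len(200L)) {
      cand <- c(runif(1L, geo$zlo + 10, geo$zhi - 10),
                runif(1L, geo$center[2L] - geo$ay, geo$center[2L] + geo$ay),
                runif(1L, geo$center[3L] - geo$ax, geo$center[3L] + geo$ax))
      if (geo$inside(matrix(cand, 1L), 10) &&
          points_clear_of_islets(matrix(cand, 1L), islet_spec, rots,
                                 nv$islet_clearance_um)) {
        p <- cand
        break
      }
    }
    if (is.null(p)) break
    u <- rnorm(3L)
    u <- u / sqrt(sum(u^2))
    len <- 0
    while (len < target_len && exo_vol < exo_budget) {
      stepped <- FALSE
      for (try in seq_len(15L)) {
        u2 <- u + nv$tortuosity * rnorm(3L)
        u2 <- u2 / sqrt(sum(u2^2))
        q <- p + nv$step_um * u2
        if (geo$inside(matrix(q, 1L), 10) &&
            points_clear_of_islets(matrix(q, 1L), islet_spec, rots,
                                   nv$islet_clearance_um)) {
          segs[[length(segs) + 1L]] <- data.frame(
            z0 = p[1L], y0 = p[2L], x0 = p[3L],
            z1 = q[1L], y1 = q[2L], x1 = q[3L],
            radius_um = r, kind = "trunk", islet_id = NA_integer_)
          exo_vol <- exo_vol + pi * r^2 * nv$step_um
          p <- q
          u <- u2
          len <- len + nv$step_um
          stepped <- TRUE
          break
        }
      }
      if (!stepped) break
    }
  }
  if (length(segs) == 0L)
    return(data.frame(z0 = numeric(0), y0 = numeric(0), x0 = numeric(0),
                      z1 = numeric(0), y1 = numeric(0), x1 = numeric(0),
                      radius_um = numeric(0), kind = character(0),
                      islet_id = integer(0)))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "endocrine_volume_analytic_um3") <- endo_vol
  attr(out, "exocrine_volume_analytic_um3") <- exo_vol + chord_exo_vol
  out
}

## ---- ganglia --------------------------------------------------------------

#' Place intrapancreatic ganglia
#'
#' A Poisson-distributed count at the configured density; lognormal volumes
#' around the target mean; each ganglion is placed just outside a randomly
#' chosen islet so that its surface-to-islet gap follows a gamma
#' distribution with the configured mean and sd (truncated at the minimum
#' gap), with rejection against overlap with any islet, other ganglia, or
#' the tissue boundary.
#'
#' @param config a `phantom_config`.
#' @param islet_spec placed islet specs.
#' @param seed optional RNG seed.
#' @return data.frame of ganglion specs with a `rotations` attribute.
#' @export
place_ganglia <- function(config, islet_spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- config$ganglia
  geo <- tissue_geometry(config)
  rots_islet <- attr(islet_spec, "rotations")
  tissue_mm3 <- tissue_volume_um3(config) / 1e9
  n <- rpois(1L, g$density_per_mm3 * tissue_mm3)
  empty <- data.frame(ganglion_id = integer(0), volume_um3 = numeric(0),
                      center_z_um = numeric(0), center_y_um = numeric(0),
                      center_x_um = numeric(0), semi_z_um = numeric(0),
                      semi_y_um = numeric(0), semi_x_um = numeric(0),
                      target_gap_um = numeric(0))
  if (n == 0L || nrow(islet_spec) == 0L) return(empty)
  shape <- (g$islet_gap_mean_um / g$islet_gap_sd_um)^2
  rate <- g$islet_gap_mean_um / g$islet_gap_sd_um^2
  # anchor ganglia next to substantial islets (sub-voxel-scale insulin
  # specks are not meaningful neighbours and are unresolvable downstream)
  anchors <- which(islet_spec$volume_um3 >= 2000)
  if (length(anchors) == 0L) anchors <- seq_len(nrow(islet_spec))
  specs <- list()
  rots <- list()
  for (i in seq_len(n)) {
    vol <- rlnorm(1L, log(g$mean_volume_um3) - g$sdlog^2 / 2, g$sdlog)
    semi <- ellipsoid_semi_axes(vol, g$axis_ratio_max)
    rot <- random_rotation()
    done <- FALSE
    for (try in seq_len(200L)) {
      gap <- rgamma(1L, shape, rate)
      if (gap < g$min_gap_um) next
      j <- anchors[sample.int(length(anchors), 1L)]
      u <- rnorm(3L)
      u <- u / sqrt(sum(u^2))
      ctr_j <- c(islet_spec$center_z_um[j], islet_spec$center_y_um[j],
                 islet_spec$center_x_um[j])
      semi_j <- c(islet_spec$semi_z_um[j], islet_spec$semi_y_um[j],
                  islet_spec$semi_x_um[j])
      texit <- ray_exit(u, rots_islet[[j]], semi_j)
      s_u <- ray_exit(u, rot, semi) # ganglion extent along the ray
      ctr <- ctr_j + (texit + gap + s_u) * u
      if (!geo$inside(matrix(ctr, 1L), max(semi) + 5)) next
      # no other islet closer than the intended gap (conservative bound)
      if (nrow(islet_spec) > 1L) {
        others <- setdiff(seq_len(nrow(islet_spec)), j)
        dd <- sqrt((islet_spec$center_z_um[others] - ctr[1L])^2 +
                   (islet_spec$center_y_um[others] - ctr[2L])^2 +
                   (islet_spec$center_x_um[others] - ctr[3L])^2)
        omax <- pmax(islet_spec$semi_z_um, islet_spec$semi_y_um,
                     islet_spec$semi_x_um)[others]
        if (any(dd < omax + max(semi) + gap)) next
      }
      if (length(specs) > 0L) {
        prev <- do.call(rbind, lapply(specs, function(s)
          c(s$center_z_um, s$center_y_um, s$center_x_um)))
        pmaxsemi <- vapply(specs, function(s)
          max(s$semi_z_um, s$semi_y_um, s$semi_x_um), 0)
        dd <- sqrt(colSums((t(prev) - ctr)^2))
        if (any(dd < pmaxsemi + max(semi) + 5)) next
      }
      specs[[length(specs) + 1L]] <- data.frame(
        ganglion_id = length(specs) + 1L, volume_um3 = vol,
        center_z_um = ctr[1L], center_y_um = ctr[2L], center_x_um = ctr[3L],
        semi_z_um = semi[1L], semi_y_um = semi[2L], semi_x_um = semi[3L],
        target_gap_um = gap)
      rots[[length(rots) + 1L]] <- rot
      done <- TRUE
      break
    }
    # a ganglion that cannot be placed is dropped (density slightly under
    # target in pathologically crowded configs)
  }
  if (length(specs) == 0L) return(empty)
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  attr(out, "rotations") <- rots
  out
}

## ---- rendering ------------------------------------------------------------

rotations_matrix <- function(rots) {
  if (length(rots) == 0L) return(matrix(0, 0L, 3L))
  do.call(rbind, rots)
}

apply_noise <- function(img, noise) {
  if (!isTRUE(noise$enabled)) return(img)
  d <- dim(img)
  ps <- max(noise$poisson_scale, 1e-9)
  out <- rpois(length(img), as.numeric(img) / ps) * ps
  if (noise$gaussian_sd > 0)
    out <- out + rnorm(length(out), 0, noise$gaussian_sd)
  out <- pmax(out, 0)
  dim(out) <- d
  out
}

#' Generate a ground-truthed synthetic pancreas volume
#'
#' Runs the full generative model — tissue slab, islets, nerve tree,
#' ganglia — rasterizes the channels with the configured intensities,
#' applies Poisson-then-Gaussian noise (unless disabled), and returns both
#' the image grid and the complete ground truth (label grids plus truth
#' tables recomputed from those grids, so truth is exactly voxel-consistent).
#' Deterministic: the same config and seed give bit-identical volumes.
#'
#' @param config a `phantom_config` or preset name.
#' @param seed integer seed for all randomness.
#' @param noise override the config noise switch (`TRUE`/`FALSE`).
#' @return an `islet_phantom`: list with `grid` (a [voxel_grid()] with
#'   region mask), `truth` (islet/nerve/ganglion label grids and tables,
#'   realized nerve volumes), `config`, `seed`.
#' @export
generate_phantom <- function(config, seed = 1L, noise = NULL) {
  if (is.character(config)) config <- phantom_preset(config)
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(noise)) config$noise$enabled <- isTRUE(noise)
  set.seed(seed)
  d <- as.integer(config$dim)
  vs <- as.numeric(config$voxel_size_um)
  vox_vol <- prod(vs)

  region <- tissue_region_mask(config)
  islet_spec <- sample_islets(config)
  islet_lab <- array(0L, d)
  if (nrow(islet_spec) > 0L)
    cpp_raster_ellipsoids(islet_lab, d, vs,
                          as.matrix(islet_spec[, c("center_z_um", "center_y_um",
                                                   "center_x_um")]),
                          as.matrix(islet_spec[, c("semi_z_um", "semi_y_um",
                                                   "semi_x_um")]),
                          rotations_matrix(attr(islet_spec, "rotations")),
                          as.integer(islet_spec$islet_id))
  nerve_segs <- draw_nerves(config, islet_spec, islet_labels = islet_lab)
  ganglion_spec <- place_ganglia(config, islet_spec)
  nerve_mask <- array(0L, d)
  if (nrow(nerve_segs) > 0L)
    cpp_raster_capsules(nerve_mask, d, vs,
                        as.matrix(nerve_segs[, c("z0", "y0", "x0")]),
                        as.matrix(nerve_segs[, c("z1", "y1", "x1")]),
                        nerve_segs$radius_um,
                        rep(1L, nrow(nerve_segs)), integer(0))
  ganglion_lab <- array(0L, d)
  if (nrow(ganglion_spec) > 0L)
    cpp_raster_ellipsoids(ganglion_lab, d, vs,
                          as.matrix(ganglion_spec[, c("center_z_um",
                                                      "center_y_um",
                                                      "center_x_um")]),
                          as.matrix(ganglion_spec[, c("semi_z_um", "semi_y_um",
                                                      "semi_x_um")]),
                          rotations_matrix(attr(ganglion_spec, "rotations")),
                          as.integer(ganglion_spec$ganglion_id))

  ints <- config$intensity
  mk_channel <- function(fg_mask, fg) {
    ch <- array(ints$background, d)
    ch[fg_mask] <- fg
    apply_noise(ch, config$noise)
  }
  channels <- list()
  channels[[config$channels$islet]] <- mk_channel(islet_lab > 0L, ints$islet)
  channels[[config$channels$nerve]] <- mk_channel(nerve_mask > 0L, ints$nerve)
  channels[[config$channels$ganglion]] <-
    mk_channel(ganglion_lab > 0L, ints$ganglion)

  grid <- voxel_grid(channels, voxel_size_um = vs,
                     magnification = config$magnification,
                     region_mask = region)

  # truth tables, recomputed from the rasterized grids
  n_islet <- nrow(islet_spec)
  islet_truth <- islet_spec
  if (n_islet > 0L) {
    counts <- cpp_tab_count(islet_lab, n_islet)
    islet_truth$voxels <- counts
    islet_truth$volume_rasterized_um3 <- counts * vox_vol
    islet_truth$intra_islet_nerve_volume_um3 <-
      cpp_tab_sum(islet_lab, as.numeric(nerve_mask), n_islet) * vox_vol
    if (any(nerve_mask > 0L)) {
      dfield <- cpp_edt3d(nerve_mask, d, vs)
      islet_truth$min_nerve_distance_um <-
        cpp_tab_min(islet_lab, dfield, n_islet)
    } else islet_truth$min_nerve_distance_um <- NA_real_
    r1 <- cpp_tab_sum(islet_lab, as.numeric(region == 1L), n_islet)
    r2 <- cpp_tab_sum(islet_lab, as.numeric(region == 2L), n_islet)
    islet_truth$region <- ifelse(r1 >= r2, 1L, 2L)
  }
  n_gang <- nrow(ganglion_spec)
  ganglion_truth <- ganglion_spec
  if (n_gang > 0L) {
    counts <- cpp_tab_count(ganglion_lab, n_gang)
    ganglion_truth$voxels <- counts
    ganglion_truth$volume_rasterized_um3 <- counts * vox_vol
    if (any(islet_lab > 0L)) {
      difield <- cpp_edt3d(as.integer(islet_lab > 0L), d, vs)
      ganglion_truth$distance_to_nearest_islet_um <-
        cpp_tab_min(ganglion_lab, difield, n_gang)
    } else ganglion_truth$distance_to_nearest_islet_um <- NA_real_
  }
  intra_total <- if (n_islet > 0L)
    sum(islet_truth$intra_islet_nerve_volume_um3) else 0
  nerve_total <- sum(nerve_mask > 0L) * vox_vol

  structure(list(
    grid = grid,
    truth = list(islet_labels = islet_lab, nerve_mask = nerve_mask > 0L,
                 ganglion_labels = ganglion_lab,
                 islets = islet_truth, ganglia = ganglion_truth,
                 nerve_segments = nerve_segs,
                 endocrine_nerve_volume_um3 = intra_total,
                 exocrine_nerve_volume_um3 = nerve_total - intra_total,
                 tissue_volume_mm3 = sum(region > 0L) * vox_vol / 1e9),
    config = config, seed = seed), class = "islet_phantom")
}

#' @export
print.islet_phantom <- function(x, ...) {
  cat(sprintf(
    "<islet_phantom> '%s' seed %d: %d islets (%d innervated), %d ganglia, %.3g mm^3 tissue\n",
    x$config$name, x$seed, nrow(x$truth$islets),
    sum(x$truth$islets$innervated), nrow(x$truth$ganglia),
    x$truth$tissue_volume_mm3))
  invisible(x)
}
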