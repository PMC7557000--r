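#' Generate a high-resolution single-islet cell phantom
#'
#' Emulates a confocal acquisition of one islet at cellular resolution:
#' beta and alpha cells are packed into an islet ellipsoid by dart throwing
#' with a minimum center separation (leaving sub-voxel gaps so that cells
#' are individually resolvable, mirroring the real acquisition's partial
#' separability), a configured fraction of each cell type is designated as
#' nerve-contacting and receives a short nerve terminal threading from its
#' interior outward (clipped so it never enters another cell), and one
#' exocrine trunk fiber runs outside the islet. Truth contact flags are
#' recomputed from the rasterized grids, so the truth table is exactly
#' voxel-consistent.
#'
#' @param config a `phantom_config` (the `cells`, `intensity` and `noise`
#'   sections are used) or preset name.
#' @param seed RNG seed.
#' @param noise override the config noise switch.
#' @return a `cell_phantom`: list with `grid` (channels insulin, glucagon,
#'   nf200 at confocal pitch), `truth` (cell label grid, per-cell table
#'   with type and contact flags, nerve mask), `config`, `seed`.
#' @export
generate_cell_phantom <- function(config, seed = 1L, noise = NULL) {
  if (is.character(config)) config <- phantom_preset(config)
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(noise)) config$noise$enabled <- isTRUE(noise)
  set.seed(seed)
  cc <- config$cells
  d <- as.integer(cc$grid_dim)
  vs <- as.numeric(magnification_voxel_sizes()[["confocal10x"]])
  ext <- d * vs
  ctr <- ext / 2
  semi <- as.numeric(cc$islet_semi_axes_um)
  r_cell <- cc$diameter_um / 2

  # dart-throwing cell placement inside the islet ellipsoid
  centers <- matrix(NA_real_, 0L, 3L)
  for (a in seq_len(cc$placement_attempts)) {
    p <- ctr + (2 * runif(3L) - 1) * semi
    s <- sum(((p - ctr) / (semi - r_cell))^2)
    if (s > 1) next
    if (nrow(centers) > 0L) {
      dd <- sqrt(colSums((t(centers) - p)^2))
      if (min(dd) < cc$min_separation_um) next
    }
    centers <- rbind(centers, p)
  }
  n <- nrow(centers)
  if (n == 0L) stop("cell placement produced no cells; enlarge the islet")
  type <- ifelse(runif(n) < cc$beta_fraction, "beta", "alpha")

  designate <- function(ty, frac) {
    idx <- which(type == ty)
    k <- round(frac * length(idx))
    sel <- rep(FALSE, n)
    if (k > 0L) sel[sample(idx, k)] <- TRUE
    sel
  }
  designated <- designate("beta", cc$beta_contact_fraction) |
                designate("alpha", cc$alpha_contact_fraction)

  # rasterize cells (spheres) as label grids per type share one labeling
  cell_lab <- array(0L, d)
  eye3 <- diag(3)
  cpp_raster_ellipsoids(cell_lab, d, vs, centers,
                        matrix(r_cell, n, 3L),
                        do.call(rbind, replicate(n, eye3, simplify = FALSE)),
                        seq_len(n))

  # nerve terminals: for each designated cell an in-plane stub from the cell
  # interior outward, z snapped to the nearest voxel plane so the capsule
  # always crosses voxel centers; clipped against every other cell
  nerve_mask <- array(0L, d)
  for (i in which(designated)) {
    zp <- (round(centers[i, 1L] / vs[1L] - 0.5) + 0.5) * vs[1L]
    u <- rnorm(2L)
    u <- u / sqrt(sum(u^2))
    p0 <- c(zp, centers[i, 2L], centers[i, 3L])
    p1 <- c(zp, centers[i, 2L] + (r_cell + 5) * u[1L],
            centers[i, 3L] + (r_cell + 5) * u[2L])
    forbid <- cell_lab
    forbid[forbid == i] <- 0L
    cpp_raster_capsules(nerve_mask, d, vs, matrix(p0, 1L), matrix(p1, 1L),
                        cc$nerve_stub_radius_um, 1L, forbid)
  }
  # one trunk fiber outside the islet, clear of all cells
  trunk_y <- max(8, ctr[2L] - semi[2L] - 12)
  cpp_raster_capsules(nerve_mask, d, vs,
                      matrix(c(ctr[1L], trunk_y, 5), 1L),
                      matrix(c(ctr[1L], trunk_y, ext[3L] - 5), 1L),
                      2, 1L, cell_lab)

  ints <- config$intensity
  beta_mask <- cell_lab > 0L
  beta_mask[beta_mask] <- type[cell_lab[cell_lab > 0L]] == "beta"
  alpha_mask <- cell_lab > 0L & !beta_mask
  mk <- function(fg_mask, fg) {
    ch <- array(ints$background, d)
    ch[fg_mask] <- fg
    apply_noise(ch, config$noise)
  }
  channels <- list(insulin = mk(beta_mask, ints$islet),
                   glucagon = mk(alpha_mask, ints$alpha_cell),
                   nf200 = mk(nerve_mask > 0L, ints$nerve))
  grid <- voxel_grid(channels, voxel_size_um = vs,
                     magnification = "confocal10x")

  counts <- cpp_tab_count(cell_lab, n)
  overlap <- cpp_tab_sum(cell_lab, as.numeric(nerve_mask), n)
  truth_cells <- data.frame(cell_id = seq_len(n), cell_type = type,
                            islet_id = 1L,
                            center_z_um = centers[, 1L],
                            center_y_um = centers[, 2L],
                            center_x_um = centers[, 3L],
                            voxels = counts,
                            designated_contact = designated,
                            contacts_nerve = overlap > 0)
  structure(list(grid = grid,
                 truth = list(cell_labels = cell_lab,
                              nerve_mask = nerve_mask > 0L,
                              cells = truth_cells,
                              islet_center_um = ctr,
                              islet_semi_axes_um = semi),
                 config = config, seed = seed),
            class = "cell_phantom")
}

#' @export
print.cell_phantom <- function(x, ...) {
  tc <- x$truth$cells
  cat(sprintf(
    "<cell_phantom> seed %d: %d cells (%d beta, %d alpha), %d contacting nerves\n",
    x$seed, nrow(tc), sum(tc$cell_type == "beta"),
    sum(tc$cell_type == "alpha"), sum(tc$contacts_nerve)))
  invisible(x)
}
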