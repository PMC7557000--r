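#' Multi-channel 3D image volume with voxel metadata
#'
#' A `voxel_grid` bundles one or more co-registered 3D scalar channels
#' (arrays in `(z, y, x)` order), the per-axis voxel size in micrometres,
#' a magnification tag, and an optional region mask (0 = outside tissue,
#' 1 = duodenal, 2 = splenic). All physical quantities downstream are in
#' um / um^3; densities per mm^3 use 1 mm^3 = 1e9 um^3.
#'
#' @param channels named list of 3D numeric arrays, identical dimensions.
#' @param voxel_size_um numeric length 3, `(z, y, x)` voxel pitch in um.
#' @param magnification one of `"1.3x"`, `"4x"`, `"12x"`, `"confocal10x"`,
#'   `"custom"`. For the named tags the voxel size defaults to the
#'   acquisition pitch of that magnification.
#' @param region_mask optional integer array, same shape as the channels.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(channels, voxel_size_um = NULL,
                       magnification = "custom", region_mask = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be a non-empty named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array in (z, y, x) order")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channel grids must share an identical shape")
  if (any(vapply(channels, function(a) any(a < 0, na.rm = TRUE), TRUE)))
    stop("channel intensities must be non-negative")
  magnification <- match.arg(magnification,
                             c(names(magnification_voxel_sizes()), "custom"))
  if (is.null(voxel_size_um)) {
    if (magnification == "custom")
      stop("missing voxel size: supply `voxel_size_um` or a known magnification")
    voxel_size_um <- magnification_voxel_sizes()[[magnification]]
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 3 strictly positive values (z, y, x)")
  if (!is.null(region_mask)) {
    if (!identical(dim(region_mask), dims[[1L]]))
      stop("`region_mask` must have the same shape as the channels")
    storage.mode(region_mask) <- "integer"
  }
  structure(list(channels = channels,
                 voxel_size_um = voxel_size_um,
                 magnification = magnification,
                 region_mask = region_mask),
            class = "voxel_grid")
}

#' Acquisition voxel sizes by magnification
#'
#' Light-sheet pitches: 5 x 5 x 5 um at 1.3x, 1.63 x 1.63 x 5 um (xy, z) at
#' 4x, 0.602 x 0.602 x 2 um at 12x; confocal 10x is 1.67 x 1.67 x 5 um.
#' Returned in `(z, y, x)` order.
#'
#' @return named list of numeric length-3 vectors.
#' @export
magnification_voxel_sizes <- function() {
  list("1.3x"        = c(5, 5, 5),
       "4x"          = c(5, 1.63, 1.63),
       "12x"         = c(2, 0.602, 0.602),
       "confocal10x" = c(5, 1.67, 1.67))
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), %d channel(s): %s\n",
              d[1L], d[2L], d[3L], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size (z,y,x): %s um, magnification %s%s\n",
              paste(signif(x$voxel_size_um, 4), collapse = " x "),
              x$magnification,
              if (is.null(x$region_mask)) "" else ", region mask present"))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$channels[[1L]])

#' Voxel volume in cubic micrometres
#' @param grid a `voxel_grid` or a numeric length-3 voxel size.
#' @return scalar um^3 per voxel.
#' @export
voxel_volume_um3 <- function(grid) {
  v <- if (inherits(grid, "voxel_grid")) grid$voxel_size_um else as.numeric(grid)
  prod(v)
}

get_channel <- function(grid, channel) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!channel %in% names(grid$channels))
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(names(grid$channels), collapse = ", ")))
  grid$channels[[channel]]
}

ome_xml_description <- function(d, nchan, channel_names, voxel_size_um, scale) {
  chans <- paste0(sprintf(
    '<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
    seq_len(nchan) - 1L, channel_names), collapse = "")
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT" ',
    'Type="float" SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1" ',
    'PhysicalSizeX="%.10g" PhysicalSizeY="%.10g" PhysicalSizeZ="%.10g" ',
    'PhysicalSizeXUnit="um" PhysicalSizeYUnit="um" PhysicalSizeZUnit="um">',
    '%s<TiffData/></Pixels></Image>',
    '<StructuredAnnotations><XMLAnnotation ID="Annotation:0">',
    '<Value><IntensityScale>%.10g</IntensityScale></Value>',
    '</XMLAnnotation></StructuredAnnotations></OME>'),
    d[3L], d[2L], d[1L], nchan,
    voxel_size_um[3L], voxel_size_um[2L], voxel_size_um[1L], chans, scale)
}

companion_path <- function(path) paste0(path, ".ome.xml")

#' Write a volume as a TIFF stack with an OME companion file
#'
#' Channels are stored plane-interleaved (all z of channel 1, then channel
#' 2, ...; dimension order XYZCT) as 32-bit float, jointly rescaled to
#' `[0, 1]`. The scale factor, physical voxel sizes and channel names are
#' written to an OME-XML companion file (`<path>.ome.xml`) so that
#' [read_volume()] round-trips shape, channel order and voxel size.
#'
#' @param grid a `voxel_grid`.
#' @param path output file path (`.tif` suggested).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid)
  mx <- max(vapply(grid$channels, max, 0), 1e-12)
  desc <- ome_xml_description(d, length(grid$channels), names(grid$channels),
                              grid$voxel_size_um, mx)
  planes <- vector("list", d[1L] * length(grid$channels))
  i <- 0L
  for (ch in grid$channels)
    for (z in seq_len(d[1L])) {
      i <- i + 1L
      planes[[i]] <- ch[z, , ] / mx
    }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "LZW",
                  reduce = FALSE)
  writeLines(desc, companion_path(path))
  invisible(path)
}

parse_ome_description <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num <- function(a) suppressWarnings(as.numeric(xml2::xml_attr(px, a)))
  sizes <- c(num("SizeZ"), num("SizeY"), num("SizeX"), num("SizeC"))
  vox <- c(num("PhysicalSizeZ"), num("PhysicalSizeY"), num("PhysicalSizeX"))
  chn <- xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  sc <- xml2::xml_find_first(doc, ".//IntensityScale")
  scale <- if (inherits(sc, "xml_missing")) NA_real_ else
    as.numeric(xml2::xml_text(sc))
  list(dim = sizes[1:3], n_channels = sizes[4L], voxel_size_um = vox,
       channel_names = chn, scale = scale)
}

#' Read a TIFF / OME-TIFF stack into a `voxel_grid`
#'
#' OME-XML metadata (physical voxel sizes, channel names, channel count) is
#' honoured when present, read either from an embedded ImageDescription tag
#' or from a `<path>.ome.xml` companion file; an explicit `voxel_size_um`
#' always overrides the metadata. A plain TIFF with neither metadata nor an
#' explicit voxel size is an error. Planes are assumed plane-interleaved by
#' channel (all z of channel 1 first) and `channel_names` fixes the count.
#'
#' @param path path to a TIFF file.
#' @param channel_names optional character vector naming (and ordering) the
#'   channels; overrides names found in metadata.
#' @param voxel_size_um optional numeric length 3 `(z, y, x)` in um.
#' @return a `voxel_grid`.
#' @export
read_volume <- function(path, channel_names = NULL, voxel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e) stop(sprintf(
                       "unreadable TIFF '%s': %s", path, conditionMessage(e))))
  if (!is.list(planes)) planes <- list(planes)
  desc <- attr(planes[[1L]], "description")
  if (is.null(desc) && file.exists(companion_path(path)))
    desc <- paste(readLines(companion_path(path), warn = FALSE), collapse = "")
  meta <- if (!is.null(desc)) parse_ome_description(desc) else NULL

  nplanes <- length(planes)
  nchan <- if (!is.null(channel_names)) length(channel_names)
           else if (!is.null(meta)) meta$n_channels else 1L
  if (nplanes %% nchan != 0L)
    stop(sprintf("channel-count mismatch: %d planes not divisible by %d channels",
                 nplanes, nchan))
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(meta) && length(meta$channel_names) == nchan &&
                         !anyNA(meta$channel_names)) meta$channel_names
                     else paste0("channel", seq_len(nchan))
  }
  if (is.null(voxel_size_um)) {
    if (!is.null(meta) && !anyNA(meta$voxel_size_um))
      voxel_size_um <- meta$voxel_size_um
    else
      stop("missing voxel size: no OME metadata and no explicit `voxel_size_um`")
  }
  scale <- if (!is.null(meta) && is.finite(meta$scale)) meta$scale else 1
  nz <- nplanes %/% nchan
  dyx <- dim(planes[[1L]])
  channels <- vector("list", nchan)
  for (c in seq_len(nchan)) {
    arr <- array(0, c(nz, dyx[1L], dyx[2L]))
    for (z in seq_len(nz)) arr[z, , ] <- planes[[(c - 1L) * nz + z]] * scale
    channels[[c]] <- arr
  }
  names(channels) <- channel_names
  voxel_grid(channels, voxel_size_um = voxel_size_um)
}

#' Maximum-intensity projection along z
#'
#' QC rendering helper: the per-pixel maximum over all z slices of one
#' channel.
#'
#' @param grid a `voxel_grid`.
#' @param channel channel name.
#' @return 2D matrix `(y, x)`.
#' @export
max_projection <- function(grid, channel) {
  a <- get_channel(grid, channel)
  out <- a[1L, , ]
  nz <- dim(a)[1L]
  if (nz > 1L) for (z in 2:nz) out <- pmax(out, a[z, , ])
  out
}
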