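#' Single-channel volumetric image stack
#'
#' A `ChannelStack` holds one fluorescence channel of a confocal z-stack as a
#' 3D intensity array together with its physical calibration. Voxels are
#' indexed `(z, y, x)`; all physical quantities are in micrometres. The
#' physical stage position of frame `n` (0-based) is `z0 + n * dz`.
#'
#' @param voxels numeric 3D array, dimensions `(nz, ny, nx)`, non-negative.
#' @param dx,dy,dz voxel pitch in um, all `> 0`.
#' @param z0 stage position of frame 0 in um.
#' @param channel_id excitation-wavelength label in nm, e.g. `"488"`. Treated
#'   as an opaque channel name throughout.
#'
#' @return an object of class `ChannelStack`.
#' @export
channel_stack <- function(voxels, dx, dy, dz, z0 = 0, channel_id = "0") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array indexed (z, y, x)")
  if (any(dim(voxels) < 1L)) stop("every stack dimension must be >= 1")
  if (!all(is.finite(c(dx, dy, dz))) || dx <= 0 || dy <= 0 || dz <= 0)
    stop("voxel pitch dx, dy, dz must be positive and finite")
  if (any(voxels < 0)) stop("voxel intensities must be non-negative")
  structure(
    list(voxels = voxels, dx = dx, dy = dy, dz = dz, z0 = z0,
         channel_id = as.character(channel_id)),
    class = "ChannelStack")
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "ChannelStack '%s': %d frames x %d x %d voxels, pitch (%g, %g, %g) um, z0 = %g um\n",
    x$channel_id, d[1], d[2], d[3], x$dz, x$dy, x$dx, x$z0))
  invisible(x)
}

#' Physical z position of each frame of a stack
#'
#' @param stack a `ChannelStack`.
#' @return numeric vector, `z0 + (0:(nz-1)) * dz`, strictly increasing.
#' @export
frame_positions <- function(stack) {
  stopifnot(inherits(stack, "ChannelStack"))
  stack$z0 + (seq_len(dim(stack$voxels)[1]) - 1) * stack$dz
}

#' Multi-channel stack sharing one voxel grid
#'
#' All channels of a `MultiChannelStack` were acquired over the same stage
#' positions and therefore share grid dimensions and voxel pitch. One channel
#' is designated the reference: all aberration shifts and corrections are
#' expressed relative to it.
#'
#' @param channels list of [channel_stack()] objects with distinct
#'   `channel_id`s, identical dimensions and identical pitch.
#' @param reference_channel `channel_id` of the reference channel.
#' @param z_orientation either `"deeper"` (physical z grows into the sample,
#'   upright microscope) or `"shallower"` (inverted). Metadata only; recorded
#'   so that the sign of "higher in the sample" stays interpretable.
#'
#' @return an object of class `MultiChannelStack`.
#' @export
multi_channel_stack <- function(channels, reference_channel,
                                z_orientation = c("deeper", "shallower")) {
  z_orientation <- match.arg(z_orientation)
  if (!length(channels)) stop("at least one channel required")
  if (!all(vapply(channels, inherits, logical(1), "ChannelStack")))
    stop("channels must all be ChannelStack objects")
  ids <- vapply(channels, function(ch) ch$channel_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate channel_id among channels")
  names(channels) <- ids
  ref <- as.character(reference_channel)
  if (!ref %in% ids)
    stop("reference_channel '", ref, "' not among channels: ",
         paste(ids, collapse = ", "))
  d0 <- dim(channels[[1]]$voxels)
  p0 <- c(channels[[1]]$dx, channels[[1]]$dy, channels[[1]]$dz,
          channels[[1]]$z0)
  for (ch in channels) {
    if (!identical(dim(ch$voxels), d0))
      stop("all channels must share identical grid dimensions")
    if (!isTRUE(all.equal(c(ch$dx, ch$dy, ch$dz, ch$z0), p0)))
      stop("all channels must share identical voxel pitch and z0")
  }
  structure(list(channels = channels, reference_channel = ref,
                 z_orientation = z_orientation),
            class = "MultiChannelStack")
}

#' @export
print.MultiChannelStack <- function(x, ...) {
  d <- dim(x$channels[[1]]$voxels)
  cat(sprintf("MultiChannelStack: %d channel(s) [%s], reference '%s', %d x %d x %d (z,y,x)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$reference_channel, d[1], d[2], d[3]))
  invisible(x)
}

#' Channel ids of a multi-channel stack
#' @param stack a `MultiChannelStack`.
#' @return character vector of channel ids in acquisition order.
#' @export
channel_ids <- function(stack) names(stack$channels)

#' Rectangular region of interest expected to hold one object
#'
#' Voxel coordinates are 0-based and half-open on every axis: a ROI with
#' `x_min = 5, x_max = 13` covers voxel columns 5..12 (width 8), matching the
#' convention used when ImageJ rectangle ROIs are converted on read. Omitted z
#' bounds (`NA`) mean the full z range of whatever stack the ROI is applied
#' to. Each ROI is intended to contain exactly one bead or one isolated
#' guide-star neurite spanning its full z extent.
#'
#' @param x_min,x_max,y_min,y_max,z_min,z_max 0-based half-open voxel bounds.
#' @param label free-text identifier.
#' @return an object of class `BeadROI`.
#' @export
bead_roi <- function(x_min, x_max, y_min, y_max,
                     z_min = NA_integer_, z_max = NA_integer_,
                     label = "") {
  b <- c(x_min, x_max, y_min, y_max)
  if (any(!is.finite(b)) || any(b != round(b)))
    stop("ROI bounds must be integers")
  if (x_min >= x_max || y_min >= y_max)
    stop("empty ROI: need x_min < x_max and y_min < y_max")
  if (x_min < 0 || y_min < 0) stop("ROI bounds must be >= 0")
  zb <- c(z_min, z_max)
  if (xor(is.na(z_min), is.na(z_max)))
    stop("z_min and z_max must both be given or both omitted")
  if (!is.na(z_min)) {
    if (any(zb != round(zb)) || z_min < 0 || z_min >= z_max)
      stop("empty or invalid z bounds")
  }
  structure(list(label = as.character(label),
                 x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 z_min = if (is.na(z_min)) NA_integer_ else as.integer(z_min),
                 z_max = if (is.na(z_max)) NA_integer_ else as.integer(z_max)),
            class = "BeadROI")
}

#' @export
print.BeadROI <- function(x, ...) {
  ztxt <- if (is.na(x$z_min)) "full z" else sprintf("z [%d,%d)", x$z_min, x$z_max)
  cat(sprintf("BeadROI '%s': x [%d,%d), y [%d,%d), %s\n",
              x$label, x$x_min, x$x_max, x$y_min, x$y_max, ztxt))
  invisible(x)
}

# Resolve a ROI against a stack: returns 1-based inclusive index ranges for
# subsetting R arrays, filling omitted z bounds with the full range.
roi_indices <- function(roi, stack) {
  d <- dim(stack$voxels)  # (nz, ny, nx)
  z_min <- if (is.na(roi$z_min)) 0L else roi$z_min
  z_max <- if (is.na(roi$z_max)) d[1] else roi$z_max
  if (roi$x_max > d[3] || roi$y_max > d[2] || z_max > d[1])
    stop("ROI '", roi$label, "' exceeds grid bounds")
  if (z_min >= z_max) stop("ROI '", roi$label, "' empty along z")
  list(z = (z_min + 1L):z_max, y = (roi$y_min + 1L):roi$y_max,
       x = (roi$x_min + 1L):roi$x_max, z_min = z_min)
}

## ---- acquisition config (sidecar) -----------------------------------------

#' Read an acquisition sidecar config
#'
#' Vendor TIFFs rarely carry trustworthy stage metadata, so the voxel pitch,
#' stage origin, channel wavelengths, reference channel and z orientation are
#' taken from a YAML sidecar, which is the normative source. Required fields:
#' `dx`, `dy`, `dz`, `channels`; optional: `z0` (default 0),
#' `reference_channel` (default first channel), `z_orientation` (default
#' `"deeper"`), `channel_order` (`"interleaved"`, the ImageJ hyperstack page
#' order, or `"blocks"`, all frames of channel 1 then channel 2, ...).
#'
#' @param path YAML file path, or a named list with the same fields.
#' @return validated config list.
#' @export
read_acquisition_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  for (f in c("dx", "dy", "dz"))
    if (is.null(cfg[[f]]))
      stop("acquisition config is missing required field '", f,
           "'; voxel pitch is never defaulted")
  if (is.null(cfg$channels) || !length(cfg$channels))
    stop("acquisition config must list channel wavelengths under 'channels'")
  cfg$channels <- as.character(unlist(cfg$channels))
  if (is.null(cfg$z0)) cfg$z0 <- 0
  if (is.null(cfg$reference_channel)) cfg$reference_channel <- cfg$channels[1]
  cfg$reference_channel <- as.character(cfg$reference_channel)
  if (is.null(cfg$z_orientation)) cfg$z_orientation <- "deeper"
  if (!cfg$z_orientation %in% c("deeper", "shallower"))
    stop("z_orientation must be 'deeper' or 'shallower'")
  if (is.null(cfg$channel_order)) cfg$channel_order <- "interleaved"
  if (!cfg$channel_order %in% c("interleaved", "blocks"))
    stop("channel_order must be 'interleaved' or 'blocks'")
  if (!cfg$reference_channel %in% cfg$channels)
    stop("reference_channel not among declared channels")
  cfg
}

#' Write an acquisition sidecar config
#' @param cfg config list as returned by [read_acquisition_config()].
#' @param path output YAML path.
#' @export
write_acquisition_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## ---- TIFF I/O --------------------------------------------------------------

#' Read a multi-channel z-stack from a multi-page TIFF
#'
#' Pages are de-interleaved into per-channel stacks according to the sidecar
#' config: `channel_order = "interleaved"` expects the ImageJ hyperstack page
#' order (channel varies fastest within each frame), `"blocks"` expects all
#' frames of the first channel followed by all frames of the second, and so
#' on. The page count must be an exact multiple of the declared channel
#' count; mismatches are an error, never guessed around.
#'
#' @param path multi-page TIFF file.
#' @param config sidecar config: YAML path or list
#'   (see [read_acquisition_config()]).
#' @return a [multi_channel_stack()].
#' @export
read_stack <- function(path, config) {
  cfg <- read_acquisition_config(config)
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(cfg$channels)
  n_pages <- length(pages)
  if (n_pages %% n_ch != 0L)
    stop("TIFF has ", n_pages, " pages, not a multiple of the ", n_ch,
         " channels declared in the config")
  nz <- n_pages %/% n_ch
  dim_yx <- dim(pages[[1]])[1:2]
  channels <- vector("list", n_ch)
  for (c_i in seq_len(n_ch)) {
    vox <- array(0, dim = c(nz, dim_yx[1], dim_yx[2]))
    for (z_i in seq_len(nz)) {
      p_i <- if (cfg$channel_order == "interleaved")
        (z_i - 1L) * n_ch + c_i else (c_i - 1L) * nz + z_i
      pg <- pages[[p_i]]
      if (!identical(dim(pg)[1:2], dim_yx))
        stop("TIFF pages have inconsistent dimensions")
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # grayscale written as RGB
      vox[z_i, , ] <- pg
    }
    channels[[c_i]] <- channel_stack(vox, dx = cfg$dx, dy = cfg$dy,
                                     dz = cfg$dz, z0 = cfg$z0,
                                     channel_id = cfg$channels[c_i])
  }
  multi_channel_stack(channels, cfg$reference_channel,
                      z_orientation = cfg$z_orientation)
}

#' Write a multi-channel stack as a 16-bit multi-page TIFF
#'
#' Pages are written in ImageJ hyperstack order (channel fastest), one
#' grayscale 16-bit page per channel per frame. Intensities must be integers
#' in `[0, 65535]`; the stack's physical calibration is not embedded in the
#' TIFF and must travel in the sidecar config.
#'
#' @param stack a `MultiChannelStack`.
#' @param path output file path.
#' @param config_path optional: also write the matching sidecar YAML here.
#' @export
write_stack <- function(stack, path, config_path = NULL) {
  stopifnot(inherits(stack, "MultiChannelStack"))
  if (!is.character(path) || !nzchar(path)) stop("empty output path")
  rng <- range(vapply(stack$channels,
                      function(ch) range(ch$voxels), numeric(2)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop("intensities must lie in [0, 65535] for 16-bit TIFF output")
  nz <- dim(stack$channels[[1]]$voxels)[1]
  pages <- vector("list", nz * length(stack$channels))
  k <- 1L
  for (z_i in seq_len(nz)) {
    for (ch in stack$channels) {
      pages[[k]] <- round(ch$voxels[z_i, , ]) / 65535  # writeTIFF wants [0,1]
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(config_path)) {
    ch1 <- stack$channels[[1]]
    write_acquisition_config(list(
      dx = ch1$dx, dy = ch1$dy, dz = ch1$dz, z0 = ch1$z0,
      channels = as.list(names(stack$channels)),
      reference_channel = stack$reference_channel,
      z_orientation = stack$z_orientation,
      channel_order = "interleaved"), config_path)
  }
  invisible(path)
}

## ---- ROI I/O ---------------------------------------------------------------

#' Read bead/guide-star ROIs from CSV or ImageJ .roi/.zip
#'
#' The CSV dialect has header columns
#' `label,x_min,x_max,y_min,y_max[,z_min,z_max]` with 0-based half-open voxel
#' bounds; omitted z bounds mean the full z range. ImageJ `.roi` files (and
#' `.zip` archives of them) are accepted for rectangle ROIs only and are
#' converted to the same half-open convention (`x_min = left`,
#' `x_max = left + width`).
#'
#' @param path `.csv`, `.roi` or `.zip` file.
#' @return list of [bead_roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = read_rois_csv(path),
    roi = list(read_imagej_roi(path)),
    zip = {
      exdir <- tempfile("rois")
      files <- utils::unzip(path, exdir = exdir)
      on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
      files <- sort(files[tolower(tools::file_ext(files)) == "roi"])
      if (!length(files)) stop("zip archive contains no .roi files")
      lapply(files, read_imagej_roi)
    },
    stop("unsupported ROI file type: .", ext))
}

read_rois_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns ", paste(need, collapse = ","))
  has_z <- all(c("z_min", "z_max") %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    bead_roi(r$x_min, r$x_max, r$y_min, r$y_max,
             z_min = if (has_z) r$z_min else NA_integer_,
             z_max = if (has_z) r$z_max else NA_integer_,
             label = r$label)
  })
}

# ImageJ .roi binary layout: magic "Iout", version (short, offset 4), roi
# type (byte, offset 6; 1 = rectangle), then top/left/bottom/right as
# big-endian shorts at offsets 8/10/12/14.
read_imagej_roi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 64L)
  if (length(raw) < 16L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ .roi file: ", path)
  roi_type <- as.integer(raw[7])
  if (roi_type != 1L)
    stop("only rectangle ImageJ ROIs are supported (got type ", roi_type,
         ") in ", path)
  be_short <- function(i) as.integer(raw[i]) * 256L + as.integer(raw[i + 1L])
  top <- be_short(9L); left <- be_short(11L)
  bottom <- be_short(13L); right <- be_short(15L)
  bead_roi(x_min = left, x_max = right, y_min = top, y_max = bottom,
           label = tools::file_path_sans_ext(basename(path)))
}

#' Write ROIs to the CSV dialect
#' @param rois list of `BeadROI`.
#' @param path output CSV path.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, x_min = r$x_min, x_max = r$x_max,
               y_min = r$y_min, y_max = r$y_max,
               z_min = r$z_min, z_max = r$z_max)))
  if (is.null(df))
    df <- data.frame(label = character(), x_min = integer(),
                     x_max = integer(), y_min = integer(),
                     y_max = integer(), z_min = integer(),
                     z_max = integer())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
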