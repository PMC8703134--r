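#' Specification of a synthetic bead / guide-star phantom
#'
#' Describes a multi-channel volume of point-like fluorescent objects with a
#' known, depth-linear axial chromatic aberration injected per channel, so
#' that detection, measurement, model fitting and correction can all be
#' exercised against exact ground truth. Defaults emulate a cleared
#' bead-slab calibration acquisition: a deep (2 mm) two-channel volume of
#' 4 um multi-fluorophore beads whose non-reference channel is axially
#' shifted by `dz(d) = 0.004 * d - 18` um plus per-bead jitter.
#'
#' Beads are rendered as anisotropic 3D Gaussians (axial sigma elongated by
#' `axial_sigma_factor`, mimicking the confocal PSF): centroid arithmetic is
#' identical to hard spheres but the sub-voxel truth position is exact.
#'
#' @param shape grid `(nz, ny, nx)` in voxels.
#' @param pitch voxel pitch `(dz, dy, dx)` in um.
#' @param z0 stage position of frame 0 (um).
#' @param channels channel ids; the first is the reference.
#' @param slopes,intercepts named per-channel axial-shift law `a`, `b`
#'   (reference must be 0).
#' @param lateral_dx,lateral_dy named per-channel lateral offsets (um).
#' @param n_objects number of beads (or guide stars).
#' @param bead_sigma lateral Gaussian sigma (um); a 4 um bead is
#'   approximated by sigma = 2 um.
#' @param axial_sigma_factor axial elongation of the PSF (default 3).
#' @param peak peak intensity per object (counts).
#' @param background constant offset (counts) so read noise does not clip.
#' @param noise_sd Gaussian read-noise sigma (counts).
#' @param poisson also apply Poisson (shot) noise.
#' @param jitter_sd per-bead, per-channel deviation from the linear shift
#'   law, `epsilon ~ N(0, jitter_sd^2)` um.
#' @param seed mandatory RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return a `PhantomSpec` list.
#' @export
phantom_spec <- function(shape = c(1000L, 256L, 256L),
                         pitch = c(2, 2, 2),
                         z0 = 0,
                         channels = c("473", "559"),
                         slopes = c("473" = 0, "559" = 0.004),
                         intercepts = c("473" = 0, "559" = -18),
                         lateral_dx = NULL, lateral_dy = NULL,
                         n_objects = 50L,
                         bead_sigma = 2, axial_sigma_factor = 3,
                         peak = 10000, background = 100,
                         noise_sd = 50, poisson = FALSE,
                         jitter_sd = 0.5,
                         seed = NULL) {
  if (is.null(seed)) stop("phantom seed is mandatory")
  channels <- as.character(channels)
  zero <- stats::setNames(rep(0, length(channels)), channels)
  fill <- function(v) {
    if (is.null(v)) return(zero)
    out <- zero; out[names(v)] <- v; out[channels]
  }
  slopes <- fill(slopes); intercepts <- fill(intercepts)
  lateral_dx <- fill(lateral_dx); lateral_dy <- fill(lateral_dy)
  ref <- channels[1]
  if (slopes[ref] != 0 || intercepts[ref] != 0 ||
      lateral_dx[ref] != 0 || lateral_dy[ref] != 0)
    stop("reference channel truth must be identically zero")
  structure(list(
    shape = as.integer(shape), pitch = as.numeric(pitch), z0 = z0,
    channels = channels, reference_channel = ref,
    slopes = slopes, intercepts = intercepts,
    lateral_dx = lateral_dx, lateral_dy = lateral_dy,
    n_objects = as.integer(n_objects),
    bead_sigma = bead_sigma, axial_sigma_factor = axial_sigma_factor,
    peak = peak, background = background,
    noise_sd = noise_sd, poisson = isTRUE(poisson),
    jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "PhantomSpec")
}

# Add one separable Gaussian blob to a (z,y,x) array in place-ish.
# center/sigma in um; voxel (n,j,i) sits at (z0 + n*dz, j*dy, i*dx), 0-based.
add_blob <- function(vox, center, sigma, pitch, z0, peak, extent = 4.5) {
  d <- dim(vox)
  zs <- z0 + (seq_len(d[1]) - 1) * pitch[1]
  ys <- (seq_len(d[2]) - 1) * pitch[2]
  xs <- (seq_len(d[3]) - 1) * pitch[3]
  iz <- which(abs(zs - center[1]) <= extent * sigma[1])
  iy <- which(abs(ys - center[2]) <= extent * sigma[2])
  ix <- which(abs(xs - center[3]) <= extent * sigma[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(vox)
  gz <- exp(-(zs[iz] - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(ys[iy] - center[2])^2 / (2 * sigma[2]^2))
  gx <- exp(-(xs[ix] - center[3])^2 / (2 * sigma[3]^2))
  vox[iz, iy, ix] <- vox[iz, iy, ix] +
    peak * (gz %o% gy %o% gx)
  vox
}

# draw object centers with margins and a minimum pairwise Chebyshev-style
# exclusion; returns matrix (z_um, y_um, x_um) in reference coordinates
draw_centers <- function(n, lim_z, lim_y, lim_x, excl_z, excl_lat,
                         z_sampler = NULL, max_tries = 20000L) {
  if (lim_z[1] >= lim_z[2] || lim_y[1] >= lim_y[2] || lim_x[1] >= lim_x[2])
    stop("infeasible phantom spec: margins leave no room for objects")
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible phantom spec: cannot place ", n,
           " objects with the required separation")
    z <- if (is.null(z_sampler)) stats::runif(1, lim_z[1], lim_z[2])
         else z_sampler()
    y <- stats::runif(1, lim_y[1], lim_y[2])
    x <- stats::runif(1, lim_x[1], lim_x[2])
    # accept unless another object is close in z AND close laterally
    ok <- !nrow(centers) ||
      !any(abs(centers[, 1] - z) <= excl_z &
           abs(centers[, 2] - y) <= excl_lat &
           abs(centers[, 3] - x) <= excl_lat)
    if (ok) centers <- rbind(centers, c(z, y, x))
  }
  centers
}

phantom_margins <- function(spec) {
  sz <- spec$bead_sigma * spec$axial_sigma_factor
  zmax <- spec$z0 + (spec$shape[1] - 1) * spec$pitch[1]
  shift_extreme <- max(vapply(spec$channels, function(ch)
    max(abs(spec$slopes[ch] * c(spec$z0, zmax) + spec$intercepts[ch])),
    numeric(1)))
  list(
    lat = 3 * spec$bead_sigma +
      max(abs(c(spec$lateral_dx, spec$lateral_dy))) + max(spec$pitch[2:3]),
    z = 3 * sz + shift_extreme + 4 * spec$jitter_sd + spec$pitch[1],
    sigma_z = sz, shift_extreme = shift_extreme)
}

finish_channel <- function(vox, spec) {
  vox <- vox + spec$background
  if (spec$poisson)
    vox[] <- stats::rpois(length(vox), lambda = pmax(vox, 0))
  if (spec$noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sd)
  vox[] <- pmin(pmax(round(vox), 0), 65535)
  vox
}

#' Generate a synthetic multi-channel bead volume with ground truth
#'
#' Bead centres are drawn uniformly (seeded) inside the grid, subject to a
#' margin keeping every channel's shifted blob at least 3 sigma from the
#' border and a minimum pairwise separation keeping the proposed ROIs from
#' containing a second bead. For each channel `c` a bead at reference
#' position `(x, y, z)` is rendered at
#' `(x + dx_c, y + dy_c, z + a_c * z + b_c + eps)` with
#' `eps ~ N(0, jitter_sd^2)` drawn per bead per non-reference channel;
#' background, Gaussian read noise (and optionally Poisson noise) are added
#' and the volume is quantised to 16-bit.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (a `MultiChannelStack`), `truth` (data.frame:
#'   one row per bead x channel with the reference position, the exact
#'   injected `dx_um`, `dy_um`, `dz_um` and the jitter realisation `eps_um`)
#'   and `rois` (list of [bead_roi()] boxes, one per bead, spanning every
#'   channel's shifted content).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  with_phantom_seed(spec$seed, {
    mg <- phantom_margins(spec)
    lim <- phantom_limits(spec, mg)
    centers <- draw_centers(spec$n_objects, lim$z, lim$y, lim$x,
                            excl_z = 2 * (6 * mg$sigma_z +
                                          4 * spec$jitter_sd) +
                              2 * mg$shift_extreme + spec$pitch[1],
                            excl_lat = 2 * (6 * spec$bead_sigma +
                                            max(abs(c(spec$lateral_dx,
                                                      spec$lateral_dy)))))
    render_objects(spec, centers, mg, guide_star = FALSE,
                   neurite_length = 0)
  })
}

#' Generate a synthetic guide-star volume (tube-like objects)
#'
#' Guide stars are short neurite-like capsules (a line segment with Gaussian
#' cross-section), rendered at depths drawn only from the top and bottom
#' thirds of the usable z range — the two-cluster design that anchors a
#' linear depth regression — and shifted per channel exactly like beads.
#' Each capsule's centroid is its midpoint by symmetry, so the emitted
#' truth table and ROI list (spanning the full z extent of each object)
#' remain exact.
#'
#' @param spec a [phantom_spec()]; `n_objects` guide stars (default spec
#'   value; 16 matches a typical acquisition).
#' @param neurite_length capsule axis length in um.
#' @return as [generate_phantom()], with `source = "guide_star"` semantics.
#' @export
generate_guide_star_phantom <- function(spec, neurite_length = 10) {
  stopifnot(inherits(spec, "PhantomSpec"))
  with_phantom_seed(spec$seed, {
    mg <- phantom_margins(spec)
    mg$lat <- mg$lat + neurite_length / 2
    mg$z <- mg$z + neurite_length / 2
    lim <- phantom_limits(spec, mg)
    span <- lim$z[2] - lim$z[1]
    if (span <= 0) stop("infeasible phantom spec: z range too small")
    third <- span / 3
    z_sampler <- function() {
      if (stats::runif(1) < 0.5) stats::runif(1, lim$z[1], lim$z[1] + third)
      else stats::runif(1, lim$z[2] - third, lim$z[2])
    }
    centers <- draw_centers(spec$n_objects, lim$z, lim$y, lim$x,
                            excl_z = 2 * (6 * mg$sigma_z +
                                          4 * spec$jitter_sd) +
                              2 * mg$shift_extreme + neurite_length +
                              spec$pitch[1],
                            excl_lat = 2 * (6 * spec$bead_sigma) +
                              neurite_length,
                            z_sampler = z_sampler)
    render_objects(spec, centers, mg, guide_star = TRUE,
                   neurite_length = neurite_length)
  })
}

phantom_limits <- function(spec, mg) {
  zmax <- spec$z0 + (spec$shape[1] - 1) * spec$pitch[1]
  ymax <- (spec$shape[2] - 1) * spec$pitch[2]
  xmax <- (spec$shape[3] - 1) * spec$pitch[3]
  list(z = c(spec$z0 + mg$z, zmax - mg$z),
       y = c(mg$lat, ymax - mg$lat),
       x = c(mg$lat, xmax - mg$lat))
}

# seeded evaluation preserving the caller's RNG state
with_phantom_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

render_objects <- function(spec, centers, mg, guide_star, neurite_length) {
  n <- nrow(centers)
  sigma <- c(mg$sigma_z, spec$bead_sigma, spec$bead_sigma)
  # capsule axis directions (mostly lateral so the z extent stays compact)
  if (guide_star) {
    phi <- stats::runif(n, 0, 2 * pi)
    tilt <- stats::runif(n, -0.3, 0.3)
    axes <- cbind(z = tilt, y = sin(phi), x = cos(phi))
    axes <- axes / sqrt(rowSums(axes^2))
  }
  # jitter realisations: per object x channel, reference fixed at 0
  eps <- matrix(0, n, length(spec$channels),
                dimnames = list(NULL, spec$channels))
  for (ch in spec$channels[-1])
    eps[, ch] <- stats::rnorm(n, 0, spec$jitter_sd)

  d <- spec$shape
  truth <- list()
  channels <- list()
  for (ch in spec$channels) {
    vox <- array(0, dim = d)
    for (i in seq_len(n)) {
      z <- centers[i, 1]; y <- centers[i, 2]; x <- centers[i, 3]
      cz <- z + spec$slopes[ch] * z + spec$intercepts[ch] + eps[i, ch]
      cy <- y + spec$lateral_dy[ch]
      cx <- x + spec$lateral_dx[ch]
      if (!guide_star) {
        vox <- add_blob(vox, c(cz, cy, cx), sigma, spec$pitch, spec$z0,
                        spec$peak)
      } else {
        k <- max(9L, 2L * ceiling(neurite_length / spec$bead_sigma) + 1L)
        ts <- seq(-0.5, 0.5, length.out = k) * neurite_length
        for (t in ts)
          vox <- add_blob(vox, c(cz + t * axes[i, 1], cy + t * axes[i, 2],
                                 cx + t * axes[i, 3]),
                          sigma, spec$pitch, spec$z0, spec$peak / k)
      }
      if (ch == spec$channels[1]) next
      truth[[length(truth) + 1L]] <- data.frame(
        label = sprintf("obj_%03d", i),
        x_um = x, y_um = y, depth_um = z, channel = ch,
        dx_um = spec$lateral_dx[ch], dy_um = spec$lateral_dy[ch],
        dz_um = spec$slopes[ch] * z + spec$intercepts[ch] + eps[i, ch],
        eps_um = eps[i, ch], row.names = NULL)
    }
    vox <- finish_channel(vox, spec)
    channels[[ch]] <- channel_stack(vox, dx = spec$pitch[3],
                                    dy = spec$pitch[2], dz = spec$pitch[1],
                                    z0 = spec$z0, channel_id = ch)
  }
  truth_df <- do.call(rbind, truth)
  rois <- phantom_rois(spec, centers, mg, guide_star, neurite_length)
  list(stack = multi_channel_stack(channels, spec$reference_channel),
       truth = truth_df, rois = rois)
}

# one padded box per object, spanning every channel's shifted content.
# Padding is generous (6 sigma): the ROI-local mean + k*SD threshold gets
# more accurate as the ROI contains more background, mimicking manually
# traced boxes that include ample dark surround.
phantom_rois <- function(spec, centers, mg, guide_star, neurite_length) {
  half_lat <- 6 * spec$bead_sigma +
    max(abs(c(spec$lateral_dx, spec$lateral_dy))) +
    if (guide_star) neurite_length / 2 else 0
  d <- spec$shape
  lapply(seq_len(nrow(centers)), function(i) {
    z <- centers[i, 1]; y <- centers[i, 2]; x <- centers[i, 3]
    z_all <- vapply(spec$channels, function(ch)
      z + spec$slopes[ch] * z + spec$intercepts[ch], numeric(1))
    pad_z <- 6 * mg$sigma_z + 4 * spec$jitter_sd +
      if (guide_star) neurite_length / 2 else 0
    z_lo <- min(z_all) - pad_z; z_hi <- max(z_all) + pad_z
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    bead_roi(
      x_min = clamp(floor((x - half_lat) / spec$pitch[3]), 0, d[3] - 2),
      x_max = clamp(ceiling((x + half_lat) / spec$pitch[3]) + 1, 1, d[3]),
      y_min = clamp(floor((y - half_lat) / spec$pitch[2]), 0, d[2] - 2),
      y_max = clamp(ceiling((y + half_lat) / spec$pitch[2]) + 1, 1, d[2]),
      z_min = clamp(floor((z_lo - spec$z0) / spec$pitch[1]), 0, d[1] - 2),
      z_max = clamp(ceiling((z_hi - spec$z0) / spec$pitch[1]) + 1, 1, d[1]),
      label = sprintf("obj_%03d", i))
  })
}
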