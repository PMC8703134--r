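#' Parameters for automatic bead detection
#'
#' @param k_sigma threshold multiplier: voxels brighter than
#'   `mean + k_sigma * SD` of the whole stack are foreground. Default 10,
#'   the same statistic the centroid measurement uses.
#' @param min_voxels,max_voxels component size bounds in voxels; components
#'   outside the range are discarded (dust and merged bead clusters).
#' @param margin voxels of padding added around each component's bounding box
#'   in x, y and z. Should exceed the largest expected inter-channel shift in
#'   voxels so the shifted bead stays inside the shared ROI.
#' @return a `DetectionParams` list.
#' @export
detection_params <- function(k_sigma = 10, min_voxels = 5L,
                             max_voxels = 100000L, margin = 2L) {
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  if (min_voxels < 1L || min_voxels > max_voxels)
    stop("need 0 < min_voxels <= max_voxels")
  if (margin < 0L) stop("margin must be >= 0")
  structure(list(k_sigma = k_sigma, min_voxels = as.integer(min_voxels),
                 max_voxels = as.integer(max_voxels),
                 margin = as.integer(margin)),
            class = "DetectionParams")
}

# Label 26-connected components of a logical 3D mask. Returns an integer
# array of the same shape, 0 = background. Breadth-first flood fill with a
# vectorised frontier; fast when the foreground is sparse (bead stacks).
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]  # 26 neighbours
  fg <- which(mask)
  if (!length(fg)) return(labels)
  next_label <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label
    # seed coordinates from linear index (column-major: z fastest)
    frontier <- arrayInd(seed, d)
    while (nrow(frontier)) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), ,
             drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- unique(lin[mask[lin] & labels[lin] == 0L])
      labels[lin] <- next_label
      frontier <- arrayInd(lin, d)
    }
  }
  labels
}

#' Automatically propose single-bead ROIs from a calibration stack
#'
#' Binarises the stack at `mean + k_sigma * SD` of all voxel intensities,
#' labels 26-connected components in 3D, discards components outside the
#' size bounds, and returns each survivor's bounding box padded by `margin`
#' voxels as a [bead_roi()]. Two unattended-use safeguards are applied and
#' their counts reported via `message()`: ROIs whose padded box overlaps
#' another component are dropped (each ROI must hold exactly one bead), and
#' ROIs still touching the volume border after padding are dropped (a
#' truncated bead would bias its centroid).
#'
#' Detection is scale-free: a global affine intensity rescaling with positive
#' gain leaves the mean/SD threshold decision, and hence the result,
#' unchanged.
#'
#' @param stack a `ChannelStack` (conventionally the reference channel; the
#'   resulting ROI boxes are shared across channels, which is valid while
#'   aberration shifts stay well below the padding).
#' @param params a [detection_params()] object.
#' @return list of `BeadROI`, possibly empty.
#' @export
detect_beads <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "ChannelStack"),
            inherits(params, "DetectionParams"))
  v <- stack$voxels
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("all-constant stack: threshold undefined (SD = 0)")
  thr <- mean(v) + params$k_sigma * s
  mask <- v > thr
  labels <- label_components_3d(mask)
  n_comp <- max(labels)
  if (n_comp == 0L) {
    message("detect_beads: no above-threshold voxels; returning 0 ROIs")
    return(list())
  }
  d <- dim(v)
  sizes <- tabulate(labels[labels > 0L], nbins = n_comp)
  keep <- which(sizes >= params$min_voxels & sizes <= params$max_voxels)
  n_size_rej <- n_comp - length(keep)

  boxes <- lapply(keep, function(lb) {
    idx <- arrayInd(which(labels == lb), d)
    m <- params$margin
    # padded, 1-based inclusive
    c(z1 = min(idx[, 1]) - m, z2 = max(idx[, 1]) + m,
      y1 = min(idx[, 2]) - m, y2 = max(idx[, 2]) + m,
      x1 = min(idx[, 3]) - m, x2 = max(idx[, 3]) + m)
  })

  n_border <- 0L; n_overlap <- 0L
  rois <- list()
  for (i in seq_along(keep)) {
    b <- boxes[[i]]
    if (b["z1"] < 1 || b["y1"] < 1 || b["x1"] < 1 ||
        b["z2"] > d[1] || b["y2"] > d[2] || b["x2"] > d[3]) {
      n_border <- n_border + 1L
      next
    }
    sub <- labels[b["z1"]:b["z2"], b["y1"]:b["y2"], b["x1"]:b["x2"]]
    if (any(sub != 0L & sub != keep[i])) {
      n_overlap <- n_overlap + 1L
      next
    }
    rois[[length(rois) + 1L]] <- bead_roi(
      x_min = b["x1"] - 1L, x_max = b["x2"],
      y_min = b["y1"] - 1L, y_max = b["y2"],
      z_min = b["z1"] - 1L, z_max = b["z2"],
      label = sprintf("bead_%03d", keep[i]))
  }
  message(sprintf(
    "detect_beads: %d component(s); rejected %d by size, %d at border, %d overlapping; %d ROI(s)",
    n_comp, n_size_rej, n_border, n_overlap, length(rois)))
  rois
}
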