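#' Intensity-weighted centroid of one ROI in one channel
#'
#' Implements the centre-of-mass localisation used for both calibration beads
#' and in-sample guide stars:
#'
#' 1. extract the ROI voxels;
#' 2. remove shot noise with a length-3 median filter along z applied to each
#'    `(y, x)` column (edge frames use nearest-neighbour padding);
#' 3. compute mean `m` and standard deviation `s` of the filtered ROI voxels
#'    and keep voxels with intensity `> m + k_sigma * s` — only genuine label
#'    survives this cut;
#' 4. the centroid is the intensity-weighted mean position of the kept
#'    voxels, converted to physical micrometres (a voxel at 0-based index
#'    `(n, j, i)` sits at `(z0 + n*dz, j*dy, i*dx)`).
#'
#' If no voxel passes the cut (dim guide stars), `k_sigma` is halved
#' repeatedly — each step reported via `message()` — until at least one voxel
#' passes or `k_sigma` drops below 1, at which point the ROI is declared to
#' contain no object.
#'
#' Filtering precedes the mean/SD computation so that shot-noise spikes
#' cannot inflate `s`; set `threshold_before_filter = TRUE` to compute the
#' statistics on raw voxels instead.
#'
#' @param stack a `ChannelStack`.
#' @param roi a `BeadROI`; must span at least 3 frames (median support).
#' @param k_sigma initial threshold multiplier (default 10).
#' @param threshold_before_filter compute `m`, `s` on unfiltered voxels.
#' @return a `Centroid`: physical `x`, `y`, `z` (um), `channel_id`,
#'   `total_weight` (sum of kept intensities), and `flags` (character vector;
#'   may contain `"fallback_threshold"` and/or `"possibly_truncated"` when
#'   more than 1% of above-threshold mass lies in the first or last ROI
#'   frame, indicating the object may not be fully contained along z).
#' @export
compute_centroid <- function(stack, roi, k_sigma = 10,
                             threshold_before_filter = FALSE) {
  stopifnot(inherits(stack, "ChannelStack"), inherits(roi, "BeadROI"))
  ix <- roi_indices(roi, stack)
  if (length(ix$z) < 3L)
    stop("ROI '", roi$label, "' spans < 3 frames; median filter needs 3")
  sub <- stack$voxels[ix$z, ix$y, ix$x, drop = FALSE]
  filt <- median3_z(sub)
  stat_src <- if (threshold_before_filter) sub else filt
  m <- mean(stat_src); s <- stats::sd(stat_src)
  flags <- character()
  k <- k_sigma
  keep <- filt > m + k * s
  while (!any(keep)) {
    k <- k / 2
    if (k < 1) stop("no object in ROI '", roi$label,
                    "': threshold fallback exhausted")
    message(sprintf("compute_centroid: ROI '%s' ch %s: no voxel above m + %g*s, retrying with k = %g",
                    roi$label, stack$channel_id, k * 2, k))
    flags <- union(flags, "fallback_threshold")
    keep <- filt > m + k * s
  }
  w <- filt[keep]
  idx <- arrayInd(which(keep), dim(filt))  # local 1-based (z, y, x)
  tot <- sum(w)
  # truncation sanity check: mass piled on the first/last ROI frame
  edge_mass <- sum(w[idx[, 1] == 1L | idx[, 1] == dim(filt)[1]])
  if (edge_mass > 0.01 * tot) flags <- union(flags, "possibly_truncated")
  z_idx0 <- ix$z_min + (idx[, 1] - 1L)           # global 0-based frame
  y_idx0 <- roi$y_min + (idx[, 2] - 1L)
  x_idx0 <- roi$x_min + (idx[, 3] - 1L)
  structure(list(
    x = sum(w * x_idx0) / tot * stack$dx,
    y = sum(w * y_idx0) / tot * stack$dy,
    z = stack$z0 + sum(w * z_idx0) / tot * stack$dz,
    channel_id = stack$channel_id,
    total_weight = tot,
    flags = flags), class = "Centroid")
}

# Length-3 running median along the first (z) axis of a 3D array, nearest
# padding at the ends. median(a,b,c) == a+b+c - max - min, vectorised.
median3_z <- function(a) {
  nz <- dim(a)[1]
  if (nz < 2L) return(a)
  prev <- a[c(1L, seq_len(nz - 1L)), , , drop = FALSE]
  nxt <- a[c(seq_len(nz)[-1L], nz), , , drop = FALSE]
  out <- prev + a + nxt - pmax(prev, a, nxt) - pmin(prev, a, nxt)
  dim(out) <- dim(a)
  out
}

#' Per-channel aberration shifts of one object
#'
#' Computes the centroid of the ROI in every channel and expresses each
#' channel's position relative to the reference channel:
#' `(dx, dy, dz) = centroid(channel) - centroid(reference)`. The object's
#' depth covariate is the reference-channel centroid z — not the geometric
#' middle of the ROI.
#'
#' @param stack a `MultiChannelStack`.
#' @param roi a `BeadROI` containing exactly one object in every channel.
#' @param source `"bead"` or `"guide_star"` provenance tag.
#' @param k_sigma threshold multiplier passed to [compute_centroid()].
#' @return an `AberrationSample`: `label`, `depth` (um), `shifts` (named list
#'   of `c(dx, dy, dz)` per channel, reference identically zero), `source`,
#'   `weights`, `flags`.
#' @export
measure_sample <- function(stack, roi, source = c("bead", "guide_star"),
                           k_sigma = 10) {
  source <- match.arg(source)
  stopifnot(inherits(stack, "MultiChannelStack"))
  cents <- lapply(stack$channels, compute_centroid, roi = roi,
                  k_sigma = k_sigma)
  ref <- cents[[stack$reference_channel]]
  shifts <- lapply(cents, function(ct)
    c(dx = ct$x - ref$x, dy = ct$y - ref$y, dz = ct$z - ref$z))
  structure(list(
    label = roi$label,
    depth = ref$z,
    shifts = shifts,
    source = source,
    weights = vapply(cents, function(ct) ct$total_weight, numeric(1)),
    flags = lapply(cents, function(ct) ct$flags)), class = "AberrationSample")
}

#' Measure a batch of ROIs into a tidy shift table
#'
#' Maps [measure_sample()] over the ROIs. A ROI failing in any channel is
#' skipped — not fatal to the batch — and recorded in the `failures`
#' attribute of the result with its reason.
#'
#' @param stack a `MultiChannelStack`.
#' @param rois list of `BeadROI`.
#' @inheritParams measure_sample
#' @return data.frame with one row per sample x channel: `label`, `source`,
#'   `depth_um`, `channel`, `dx_um`, `dy_um`, `dz_um`, `total_weight`,
#'   `flags` (`;`-joined). Attribute `"failures"` is a data.frame of
#'   `label`, `reason` for rejected ROIs.
#' @export
measure_batch <- function(stack, rois, source = c("bead", "guide_star"),
                          k_sigma = 10) {
  source <- match.arg(source)
  rows <- list(); fails <- list()
  for (roi in rois) {
    smp <- tryCatch(measure_sample(stack, roi, source, k_sigma),
                    error = function(e)
                      structure(conditionMessage(e), class = "try-fail"))
    if (inherits(smp, "try-fail")) {
      fails[[length(fails) + 1L]] <-
        data.frame(label = roi$label, reason = unclass(smp))
      next
    }
    for (ch in names(smp$shifts)) {
      sh <- smp$shifts[[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = smp$label, source = smp$source, depth_um = smp$depth,
        channel = ch, dx_um = sh[["dx"]], dy_um = sh[["dy"]],
        dz_um = sh[["dz"]], total_weight = smp$weights[[ch]],
        flags = paste(smp$flags[[ch]], collapse = ";"))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), source = character(),
               depth_um = numeric(), channel = character(),
               dx_um = numeric(), dy_um = numeric(), dz_um = numeric(),
               total_weight = numeric(), flags = character())
  rownames(out) <- NULL
  if (!nrow(out)) message("measure_batch: no sample could be measured")
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(label = character(), reason = character())
  out
}
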