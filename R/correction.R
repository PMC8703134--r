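#' Corrected z position of a target-channel frame
#'
#' The calibration measures `dz(d) = a*d + b`: an object at reference depth
#' `d` appears in the target channel at stage position `z = d + a*d + b`.
#' The corrected position of a target frame acquired at stage position `z`
#' is therefore the reference depth whose content it actually holds — the
#' exact inverse `z_c = (z - b) / (1 + a)`. The first-order variant
#' `z_c = z - (a*z + b)` (difference `O(a^2 z)`, negligible at realistic
#' slopes) is available for comparison.
#'
#' @param z stage position(s) in um.
#' @param reg an `AxialRegression` (or any list with `slope`, `intercept`).
#' @param first_order use the first-order approximation instead of the exact
#'   inverse.
#' @return corrected position(s) in um.
#' @export
corrected_z <- function(z, reg, first_order = FALSE) {
  a <- reg$slope; b <- reg$intercept
  if (abs(1 + a) < 1e-6)
    stop("degenerate model: |1 + slope| < 1e-6, corrected z undefined")
  if (first_order) z - (a * z + b) else (z - b) / (1 + a)
}

#' Nearest-frame assignment between reference and corrected positions
#'
#' For each reference frame `n`, picks the target frame `m(n)` whose
#' corrected position is closest to the reference position, ties broken
#' toward the smaller index. This is the frame-reassignment step of the
#' correction: some target frames end up duplicated, others deleted.
#' Reference frames whose nearest corrected position is farther away than
#' one reference frame spacing are still assigned (clamped to the nearest
#' frame) but flagged as extrapolated.
#'
#' @param ref_positions reference frame positions (um), strictly monotone.
#' @param corrected_positions corrected target frame positions (um),
#'   strictly monotone.
#' @return a `FrameMap`: `assignment` (1-based source index per reference
#'   frame), `extrapolated` (logical per reference frame), `n_duplicated`,
#'   `n_deleted`.
#' @export
assign_frames <- function(ref_positions, corrected_positions) {
  if (!length(ref_positions) || !length(corrected_positions))
    stop("empty position list")
  if (length(ref_positions) > 1 &&
      !(all(diff(ref_positions) > 0) || all(diff(ref_positions) < 0)))
    stop("ref_positions must be strictly monotone")
  if (length(corrected_positions) > 1 &&
      !(all(diff(corrected_positions) > 0) ||
        all(diff(corrected_positions) < 0)))
    stop("corrected_positions must be strictly monotone")
  spacing <- if (length(ref_positions) > 1)
    stats::median(abs(diff(ref_positions))) else Inf
  dist <- abs(outer(ref_positions, corrected_positions, "-"))
  assignment <- apply(dist, 1, which.min)  # which.min: first (smaller) index
  mindist <- dist[cbind(seq_along(ref_positions), assignment)]
  used <- tabulate(assignment, nbins = length(corrected_positions))
  structure(list(
    assignment = as.integer(assignment),
    extrapolated = mindist > spacing,
    n_duplicated = sum(pmax(used - 1L, 0L)),
    n_deleted = sum(used == 0L)), class = "FrameMap")
}

#' @export
print.FrameMap <- function(x, ...) {
  cat(sprintf(
    "FrameMap: %d reference frame(s); %d source frame(s) duplicated, %d deleted, %d extrapolated\n",
    length(x$assignment), x$n_duplicated, x$n_deleted, sum(x$extrapolated)))
  invisible(x)
}

#' Apply axial chromatic-aberration correction to a stack
#'
#' Rebuilds every non-reference channel frame-by-frame: reference frame `n`
#' receives the target frame whose corrected z position (via [corrected_z()])
#' is nearest the reference position. The reference channel and all x-y
#' content are untouched — the correction is axial-only — and output
#' dimensions equal input dimensions for every channel.
#'
#' A model carrying an `insufficient_power` flag on any needed regression is
#' refused unless `force = TRUE`.
#'
#' @param stack a `MultiChannelStack`.
#' @param model a `CalibrationModel` with the same reference channel and a
#'   regression for every non-reference channel of the stack.
#' @param force apply even if the power gate failed.
#' @param first_order passed to [corrected_z()].
#' @return list with `stack` (corrected `MultiChannelStack`) and `report`
#'   (per target channel: slope, intercept, frames duplicated / deleted /
#'   extrapolated).
#' @export
apply_correction <- function(stack, model, force = FALSE,
                             first_order = FALSE) {
  stopifnot(inherits(stack, "MultiChannelStack"),
            inherits(model, "CalibrationModel"))
  if (stack$reference_channel != model$reference_channel)
    stop("stack reference channel ('", stack$reference_channel,
         "') differs from model reference ('", model$reference_channel, "')")
  targets <- setdiff(channel_ids(stack), stack$reference_channel)
  missing <- setdiff(targets, names(model$regressions))
  if (length(missing))
    stop("model has no regression for channel(s): ",
         paste(missing, collapse = ", "))
  for (tg in targets)
    if ("insufficient_power" %in% model$regressions[[tg]]$flags && !force)
      stop("regression for channel '", tg, "' failed the power gate ",
           "(power < ", model$power_threshold, "); pass force = TRUE ",
           "to apply anyway")
  out <- stack
  report <- list()
  ref_pos <- frame_positions(stack$channels[[stack$reference_channel]])
  for (tg in targets) {
    reg <- model$regressions[[tg]]
    src <- stack$channels[[tg]]
    zc <- corrected_z(frame_positions(src), reg, first_order = first_order)
    fmap <- assign_frames(ref_pos, zc)
    out$channels[[tg]]$voxels <-
      src$voxels[fmap$assignment, , , drop = FALSE]
    report[[tg]] <- list(
      slope = reg$slope, intercept = reg$intercept,
      n_duplicated = fmap$n_duplicated, n_deleted = fmap$n_deleted,
      n_extrapolated = sum(fmap$extrapolated),
      frame_map = fmap$assignment)
  }
  list(stack = out, report = report)
}
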