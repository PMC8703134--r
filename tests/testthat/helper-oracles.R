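# Independent brute-force oracles, kept deliberately naive (explicit loops)
# so they share no code path with the implementation they check.

# thresholded centre-of-mass: loops over every ROI voxel; replicates the
# measurement definition (z median filter, mean + k*SD cut, weighted mean)
oracle_centroid <- function(voxels, dx, dy, dz, z0, roi, k = 10) {
  zz <- (roi$z_min + 1):roi$z_max
  yy <- (roi$y_min + 1):roi$y_max
  xx <- (roi$x_min + 1):roi$x_max
  sub <- voxels[zz, yy, xx, drop = FALSE]
  nz <- length(zz)
  filt <- sub
  for (j in seq_along(yy)) for (i in seq_along(xx)) {
    col <- sub[, j, i]
    for (n in seq_len(nz)) {
      lo <- max(n - 1, 1); hi <- min(n + 1, nz)
      window <- col[c(lo, n, hi)]
      filt[n, j, i] <- sort(window)[2]
    }
  }
  # same halving ladder as the measurement definition
  repeat {
    thr <- mean(filt) + k * stats::sd(filt)
    if (any(filt > thr)) break
    k <- k / 2
    if (k < 1) return(NULL)
  }
  sw <- 0; sx <- 0; sy <- 0; sz <- 0
  for (n in seq_len(nz)) for (j in seq_along(yy)) for (i in seq_along(xx)) {
    w <- filt[n, j, i]
    if (w > thr) {
      sw <- sw + w
      sx <- sx + w * (xx[i] - 1) * dx
      sy <- sy + w * (yy[j] - 1) * dy
      sz <- sz + w * (z0 + (zz[n] - 1) * dz)
    }
  }
  if (sw == 0) return(NULL)
  c(x = sx / sw, y = sy / sw, z = sz / sw, weight = sw)
}

# exhaustive nearest-position assignment, ties to the smaller index
oracle_assign <- function(ref_pos, corr_pos) {
  out <- integer(length(ref_pos))
  for (n in seq_along(ref_pos)) {
    best <- 1L
    for (m in seq_along(corr_pos))
      if (abs(corr_pos[m] - ref_pos[n]) < abs(corr_pos[best] - ref_pos[n]))
        best <- m
    out[n] <- best
  }
  out
}

# naive 26-connected labelling by label propagation to a fixed point
oracle_label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    idx <- which(mask)
    co <- arrayInd(idx, d)
    for (r in seq_along(idx)) {
      z <- co[r, 1]; y <- co[r, 2]; x <- co[r, 3]
      for (ddz in -1:1) for (ddy in -1:1) for (ddx in -1:1) {
        z2 <- z + ddz; y2 <- y + ddy; x2 <- x + ddx
        if (z2 < 1 || y2 < 1 || x2 < 1 || z2 > d[1] || y2 > d[2] ||
            x2 > d[3]) next
        if (mask[z2, y2, x2] && lab[z2, y2, x2] < lab[z, y, x]) {
          lab[z, y, x] <- lab[z2, y2, x2]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# closed-form simple-regression coefficients
oracle_ols <- function(x, y) {
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = a, intercept = mean(y) - a * mean(x))
}

# a true-law calibration model, bypassing any fitting
true_model <- function(ref, targets, slopes, intercepts,
                       power_threshold = 0.7) {
  regs <- lapply(targets, function(tg)
    structure(list(ref_channel = ref, target_channel = tg,
                   slope = slopes[[tg]], intercept = intercepts[[tg]],
                   n = NA_integer_, r2 = 1, f2 = Inf, power = 1,
                   alpha = 0.05, slope_se = 0, intercept_se = 0, sigma = 0,
                   depth_mean = 0, depth_ssq = 1,
                   flags = "degenerate_fit"),
              class = "AxialRegression"))
  names(regs) <- targets
  structure(list(reference_channel = ref, regressions = regs,
                 lateral_summary = NULL, power_threshold = power_threshold,
                 provenance = list(source = "truth")),
            class = "CalibrationModel")
}
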