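#' Cohen's f-squared from a coefficient of determination
#'
#' Effect size for the aberration-versus-depth regression,
#' `f2 = r2 / (1 - r2)`. An exact fit (`r2 = 1`, which only occurs on
#' noiseless synthetic data) returns `Inf` rather than an error so the
#' degenerate case stays representable.
#'
#' @param r2 coefficient of determination in `[0, 1]`.
#' @return numeric effect size, `Inf` when `r2 == 1`.
#' @export
cohens_f2 <- function(r2) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1)
    stop("r2 must lie in [0, 1]")
  if (r2 == 1) return(Inf)
  r2 / (1 - r2)
}

#' Achieved power of the depth regression's F-test
#'
#' Power of the test that the single-predictor regression explains no
#' variance (R-squared deviation from zero, fixed-effects convention):
#' noncentral F with `df1 = 1`, `df2 = n - 2` and noncentrality
#' `lambda = f2 * n`;
#' `power = P(F' > qf(1 - alpha; 1, n - 2))`. As `f2 -> 0` the power tends
#' to `alpha`; `f2 = Inf` (exact fit) gives power 1.
#'
#' @param f2 Cohen's f-squared effect size, `> 0` (or `Inf`).
#' @param n sample count, `>= 3`.
#' @param alpha significance level in `(0, 1)`, default 0.05.
#' @return power in `[0, 1]`.
#' @export
regression_power <- function(f2, n, alpha = 0.05) {
  if (length(f2) != 1 || is.na(f2) || f2 < 0) stop("f2 must be >= 0")
  if (n != round(n) || n < 3) stop("n must be an integer >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.infinite(f2)) return(1)
  df2 <- n - 2
  fcrit <- stats::qf(1 - alpha, 1, df2)
  stats::pf(fcrit, 1, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' Smallest sample count reaching a target power
#'
#' Scans `n = 3, 4, ...` for the first n with
#' `regression_power(f2, n, alpha) >= target_power`. Power is strictly
#' increasing in n for fixed `f2 > 0`, so the scan is exact.
#'
#' @inheritParams regression_power
#' @param target_power required power in `(0, 1)`.
#' @param n_max search cap (error if exceeded).
#' @return integer sample count `>= 3`.
#' @export
required_n <- function(f2, target_power, alpha = 0.05, n_max = 10000L) {
  if (length(f2) != 1 || is.na(f2) || f2 <= 0) stop("f2 must be > 0")
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)")
  for (n in 3:n_max)
    if (regression_power(f2, n, alpha) >= target_power) return(as.integer(n))
  stop("required_n: no n <= ", n_max, " reaches power ", target_power)
}

#' Fit the depth-dependent axial-shift regression for one channel pair
#'
#' Ordinary least squares of the axial shift on the reference depth,
#' `dz = a * depth + b`, over samples measured for `target` relative to
#' `ref`. Reports the slope `a` (um shift per um depth, dimensionless), the
#' intercept `b` (um), `r2`, Cohen's `f2 = r2/(1 - r2)` and the achieved
#' power of the fit's F-test at `alpha`.
#'
#' A perfect fit (`r2 == 1` within numerical tolerance; noiseless synthetic
#' data) is not an error: `f2 = Inf`, `power = 1` and the regression is
#' flagged `degenerate_fit`.
#'
#' @param samples tidy shift table from [measure_batch()] (columns
#'   `depth_um`, `channel`, `dz_um`), or any data.frame with those columns.
#' @param ref reference channel id (samples' shifts must already be relative
#'   to it; rows with `channel == ref` are ignored by the fit).
#' @param target target channel id to regress.
#' @param alpha significance level for the power computation.
#' @return an `AxialRegression`: `ref_channel`, `target_channel`, `slope`,
#'   `intercept`, `n`, `r2`, `f2`, `power`, `alpha`, `flags`.
#' @export
fit_axial <- function(samples, ref, target, alpha = 0.05) {
  rows <- samples[samples$channel == as.character(target), , drop = FALSE]
  n <- nrow(rows)
  if (n < 3) stop("need >= 3 samples for channel '", target, "', got ", n)
  d <- rows$depth_um
  if (stats::sd(d) == 0)
    stop("all samples at identical depth: regression rank-deficient")
  fit <- stats::lm(dz_um ~ depth_um, data = rows)
  # degenerate (noiseless) fits are supported and flagged below; silence
  # summary.lm's perfect-fit warning for them
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  r2 <- sm$r.squared
  flags <- character()
  if (!is.finite(r2)) {        # constant response (e.g. reference vs itself)
    r2 <- 0; flags <- "constant_response"
  } else if (r2 > 1 - 1e-12) { # noiseless synthetic data
    r2 <- 1; flags <- "degenerate_fit"
  }
  f2 <- cohens_f2(r2)
  structure(list(
    ref_channel = as.character(ref), target_channel = as.character(target),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = n, r2 = r2, f2 = f2,
    power = if (is.infinite(f2)) 1 else regression_power(f2, n, alpha),
    alpha = alpha,
    slope_se = sm$coefficients[2, 2],
    intercept_se = sm$coefficients[1, 2],
    sigma = sm$sigma,
    depth_mean = mean(d), depth_ssq = sum((d - mean(d))^2),
    flags = flags), class = "AxialRegression")
}

#' @export
print.AxialRegression <- function(x, ...) {
  cat(sprintf(
    "AxialRegression %s -> %s: dz = %.6g * depth + %.4g um  (n = %d, r2 = %.4g, f2 = %.4g, power = %.4g)\n",
    x$ref_channel, x$target_channel, x$slope, x$intercept, x$n, x$r2, x$f2,
    x$power))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Standard error of the fitted mean shift at a given depth
#'
#' SE of the regression line's prediction at depth `d`:
#' `sigma * sqrt(1/n + (d - mean(depth))^2 / SS_depth)`. Used to bound the
#' residual shift achievable when correcting with a noisy fitted model.
#'
#' @param reg an `AxialRegression`.
#' @param depth depth(s) in um.
#' @return numeric vector of standard errors (um); 0 for a degenerate fit.
#' @export
fit_se_at_depth <- function(reg, depth) {
  stopifnot(inherits(reg, "AxialRegression"))
  if ("degenerate_fit" %in% reg$flags) return(rep(0, length(depth)))
  reg$sigma * sqrt(1 / reg$n + (depth - reg$depth_mean)^2 / reg$depth_ssq)
}

#' Build a calibration model from measured samples
#'
#' Fits [fit_axial()] for every non-reference channel present in the sample
#' table, computes the lateral-shift summary (mean and max of `|dx|`, `|dy|`
#' per channel — reported only, never corrected), and applies the power
#' gate: a regression whose achieved power falls below `power_threshold` is
#' flagged `insufficient_power`. The model is still emitted so it can be
#' inspected, but [apply_correction()] refuses it unless forced.
#'
#' @param samples tidy table from [measure_batch()].
#' @param ref reference channel id.
#' @param alpha significance level.
#' @param power_threshold minimum acceptable achieved power (default 0.7).
#' @param lateral_warn_pitch optional voxel pitch in um; when given, a
#'   warning is emitted if any channel's mean `|dx|` or `|dy|` exceeds it.
#' @return a `CalibrationModel`: `reference_channel`, `regressions` (named
#'   list of `AxialRegression`), `lateral_summary` (data.frame), `provenance`.
#' @export
build_model <- function(samples, ref, alpha = 0.05, power_threshold = 0.7,
                        lateral_warn_pitch = NULL) {
  ref <- as.character(ref)
  targets <- setdiff(unique(samples$channel), ref)
  if (!length(targets)) stop("no non-reference channel in samples")
  regs <- list()
  lat <- list()
  for (tg in targets) {
    reg <- fit_axial(samples, ref, tg, alpha)
    if (reg$power < power_threshold)
      reg$flags <- union(reg$flags, "insufficient_power")
    regs[[tg]] <- reg
    rows <- samples[samples$channel == tg, ]
    lat[[tg]] <- data.frame(
      channel = tg,
      mean_abs_dx = mean(abs(rows$dx_um)), max_abs_dx = max(abs(rows$dx_um)),
      mean_abs_dy = mean(abs(rows$dy_um)), max_abs_dy = max(abs(rows$dy_um)))
  }
  lateral <- do.call(rbind, lat); rownames(lateral) <- NULL
  if (!is.null(lateral_warn_pitch) &&
      any(lateral$mean_abs_dx > lateral_warn_pitch |
          lateral$mean_abs_dy > lateral_warn_pitch))
    warning("mean lateral shift exceeds one voxel pitch for some channel; ",
            "lateral aberration is reported but not corrected")
  structure(list(
    reference_channel = ref,
    regressions = regs,
    lateral_summary = lateral,
    power_threshold = power_threshold,
    provenance = list(
      source = unique(as.character(samples$source)),
      n_samples = length(unique(samples$label)),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      tool = paste0("chromaxial ",
                    as.character(utils::packageVersion("chromaxial"))))),
    class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf("CalibrationModel (reference '%s', %d target channel(s)):\n",
              x$reference_channel, length(x$regressions)))
  for (reg in x$regressions) print(reg)
  invisible(x)
}

#' Serialize / load a calibration model as JSON
#'
#' `write_model()` writes the regressions, lateral summary and provenance to
#' a JSON file; `read_model()` restores the `CalibrationModel`. `Inf`
#' effect sizes (degenerate noiseless fits) survive the round trip as the
#' string `"Inf"`.
#'
#' @param model a `CalibrationModel`.
#' @param path JSON file path.
#' @return `read_model()`: a `CalibrationModel`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "CalibrationModel"))
  obj <- list(
    reference_channel = model$reference_channel,
    regressions = lapply(model$regressions, function(r) {
      r <- unclass(r)
      r$f2 <- if (is.infinite(r$f2)) "Inf" else r$f2
      r
    }),
    lateral_summary = model$lateral_summary,
    power_threshold = model$power_threshold,
    provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  regs <- lapply(obj$regressions, function(r) {
    r$f2 <- if (identical(r$f2, "Inf")) Inf else as.numeric(r$f2)
    r$flags <- as.character(unlist(r$flags))
    structure(r, class = "AxialRegression")
  })
  structure(list(
    reference_channel = obj$reference_channel,
    regressions = regs,
    lateral_summary = as.data.frame(obj$lateral_summary),
    power_threshold = obj$power_threshold,
    provenance = obj$provenance), class = "CalibrationModel")
}
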