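# helper: assemble a tidy sample table like measure_batch() emits
sample_table <- function(depth, dz, channel = "559", ref = "473",
                         dx = 0, dy = 0) {
  rbind(
    data.frame(label = sprintf("s%02d", seq_along(depth)), source = "bead",
               depth_um = depth, channel = ref, dx_um = 0, dy_um = 0,
               dz_um = 0, total_weight = 1, flags = ""),
    data.frame(label = sprintf("s%02d", seq_along(depth)), source = "bead",
               depth_um = depth, channel = channel, dx_um = dx, dy_um = dy,
               dz_um = dz, total_weight = 1, flags = ""))
}

test_that("noiseless lines are fitted exactly and flagged degenerate", {
  d <- seq(100, 1900, length.out = 12)
  fit <- fit_axial(sample_table(d, 0.004 * d - 18), "473", "559")
  expect_equal(fit$slope, 0.004, tolerance = 1e-12)
  expect_equal(fit$intercept, -18, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_true(is.infinite(fit$f2))
  expect_equal(fit$power, 1)
  expect_true("degenerate_fit" %in% fit$flags)

  # closed-form three-point check: (0,1), (100,2), (200,3)
  fit3 <- fit_axial(sample_table(c(0, 100, 200), c(1, 2, 3)), "473", "559")
  expect_equal(fit3$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit3$intercept, 1, tolerance = 1e-12)
  expect_equal(fit3$r2, 1)

  expect_error(fit_axial(sample_table(rep(5, 4), 1:4), "473", "559"),
               "identical depth")
  expect_error(fit_axial(sample_table(c(0, 1), c(0, 1)), "473", "559"),
               ">= 3 samples")
})

test_that("noisy fits agree with closed-form OLS and recover parameters", {
  set.seed(17)
  for (n in c(10, 100, 1000)) {
    d <- runif(n, 0, 2000)
    dz <- 0.004 * d - 18 + rnorm(n, 0, 0.5)
    fit <- fit_axial(sample_table(d, dz), "473", "559")
    want <- oracle_ols(d, dz)
    expect_equal(fit$slope, want[["slope"]], tolerance = 1e-10)
    expect_equal(fit$intercept, want[["intercept"]], tolerance = 1e-10)
    # parameter recovery within 3 standard errors
    expect_lt(abs(fit$slope - 0.004), 3 * fit$slope_se)
    expect_lt(abs(fit$intercept + 18), 3 * fit$intercept_se)
  }
})

test_that("Cohen's f2 matches its definition and edge cases", {
  expect_equal(cohens_f2(0.5), 1)
  expect_equal(cohens_f2(0), 0)
  expect_equal(cohens_f2(0.757), 0.757 / 0.243, tolerance = 1e-12)
  expect_true(is.infinite(cohens_f2(1)))
  expect_error(cohens_f2(-0.1), "\\[0, 1\\]")
  expect_error(cohens_f2(1.2), "\\[0, 1\\]")
})

test_that("power is alpha at the null and monotone in n and f2", {
  expect_equal(regression_power(0, 10, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(regression_power(1e-12, 10, 0.1), 0.1, tolerance = 1e-6)
  f2s <- c(0.05, 0.2, 1, 3)
  for (f2 in f2s) {
    p <- vapply(3:40, function(n) regression_power(f2, n), numeric(1))
    # strictly increasing until the power saturates in double precision
    expect_true(all(diff(p) > 0 | p[-1] > 1 - 1e-12))
  }
  for (n in c(5, 10, 30)) {
    p <- vapply(f2s, function(f2) regression_power(f2, n), numeric(1))
    expect_true(all(diff(p) > 0 | p[-1] > 1 - 1e-12))
  }
  expect_equal(regression_power(Inf, 5), 1)
})

test_that("required_n matches an exhaustive scan and is monotone", {
  f2 <- cohens_f2(0.757)
  expect_equal(required_n(f2, 0.95), 7L)
  expect_equal(required_n(f2, 0.051), 3L)  # minimum allowed n
  for (target in c(0.5, 0.8, 0.95)) {
    for (f2i in c(0.15, 0.5, 2)) {
      got <- required_n(f2i, target)
      scan <- 3:200
      ok <- vapply(scan, function(n) regression_power(f2i, n) >= target,
                   logical(1))
      expect_equal(got, scan[which(ok)[1]])
    }
  }
  # non-increasing in f2, non-decreasing in target power
  expect_true(!is.unsorted(-vapply(c(0.1, 0.3, 1, 3), required_n,
                                   integer(1), target_power = 0.8)))
  expect_true(!is.unsorted(vapply(c(0.5, 0.8, 0.9, 0.99), function(tp)
    required_n(0.3, tp), integer(1))))
})

test_that("reference-vs-reference fits are exactly zero", {
  d <- seq(0, 1000, length.out = 10)
  tab <- sample_table(d, 0.002 * d + 3)
  fit <- fit_axial(tab, "473", "473")  # reference rows: dz identically 0
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 0)
})

test_that("slopes are transitive across reference choices on noiseless data", {
  d <- seq(100, 1900, length.out = 20)
  aB <- 5e-4; bB <- -4; aC <- 1e-3; bC <- -9
  tabA <- rbind(sample_table(d, aB * d + bB, channel = "488"),
                sample_table(d, aC * d + bC, channel = "552"))
  sAB <- fit_axial(tabA, "473", "488")$slope
  sAC <- fit_axial(tabA, "473", "552")$slope
  # with B as reference: depth covariate is B's absolute position
  dB <- d + aB * d + bB
  dzBC <- (aC * d + bC) - (aB * d + bB)
  sBC <- fit_axial(sample_table(dB, dzBC, channel = "552", ref = "488"),
                   "488", "552")$slope
  expect_lt(abs(sAC - (sAB + sBC)), 1e-6)
})

test_that("build_model fits all pairs, gates power, and round-trips JSON", {
  d <- seq(100, 1900, length.out = 30)
  set.seed(4)
  tab <- rbind(
    sample_table(d, 0.004 * d - 18 + rnorm(30, 0, 0.5), channel = "488",
                 dx = rnorm(30, 0, 0.2)),
    sample_table(d, 0.006 * d - 25 + rnorm(30, 0, 0.5), channel = "552"),
    sample_table(d, rnorm(30, 0, 10), channel = "638"))  # no depth signal
  model <- build_model(tab, "473")
  expect_setequal(names(model$regressions), c("488", "552", "638"))
  expect_false("insufficient_power" %in% model$regressions[["488"]]$flags)
  expect_true("insufficient_power" %in% model$regressions[["638"]]$flags)
  expect_equal(nrow(model$lateral_summary), 3)
  expect_lt(model$lateral_summary$mean_abs_dx[
    model$lateral_summary$channel == "552"], 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  write_model(model, js)
  back <- read_model(js)
  expect_equal(back$reference_channel, "473")
  for (ch in names(model$regressions)) {
    expect_equal(back$regressions[[ch]]$slope,
                 model$regressions[[ch]]$slope, tolerance = 1e-12)
    expect_equal(back$regressions[[ch]]$power,
                 model$regressions[[ch]]$power, tolerance = 1e-12)
    expect_identical(back$regressions[[ch]]$flags,
                     model$regressions[[ch]]$flags)
  }
  # degenerate Inf f2 survives serialisation
  model2 <- build_model(sample_table(d, 0.001 * d + 1), "473")
  write_model(model2, js)
  expect_true(is.infinite(read_model(js)$regressions[["559"]]$f2))
})
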