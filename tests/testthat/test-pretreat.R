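test_that("cubic-spline alignment is exact on cubics and the identity", {
  x <- seq(0, 10, by = 0.5)
  y <- 2 * x^3 - x^2 + 3 * x - 7
  sp <- new_spectrum(x, y, "c13_cpmas")

  same <- interpolate_to_axis(sp, x)
  expect_lt(max(abs(same$intensity - y)), 1e-12)

  target <- seq(0.25, 9.75, by = 0.25)
  out <- interpolate_to_axis(sp, target)
  expect_lt(max(abs(out$intensity - (2 * target^3 - target^2 + 3 * target - 7))), 1e-9)
  expect_true("spline_align" %in% out$lineage)

  expect_error(interpolate_to_axis(sp, seq(-1, 5, 1)), "beyond")
  expect_error(interpolate_to_axis(new_spectrum(1:3, 1:3, "ftir"), 1:2), "4 source points")
})

test_that("two spectra aligned to one axis share that axis exactly", {
  target <- seq(-100, 100, by = 2)
  a <- interpolate_to_axis(new_spectrum(seq(-130, 130, 1), rnorm(261), "h1_wideline"), target)
  b <- interpolate_to_axis(new_spectrum(seq(-120, 120, 0.8), rnorm(301), "h1_wideline"), target)
  expect_identical(a$axis, b$axis)
})

test_that("SG second derivative is exact for cubics and tracks -sin on sine input", {
  x <- seq(0, 5, by = 0.01)
  a <- 1.7; y <- a * x^2 - 3 * x + 2
  d2 <- sg_second_derivative(new_spectrum(x, y, "ftir"), 11)
  expect_lt(max(abs(d2$intensity - 2 * a)), 1e-9)
  expect_identical(d2$derivative_order, 2L)
  expect_true("sg2der(w=11)" %in% d2$lineage)

  # degree-3 polynomial: interior output equals the analytic second derivative
  y3 <- 0.5 * x^3 + a * x^2 - x
  d3 <- sg_second_derivative(new_spectrum(x, y3, "ftir"), 11)
  expect_lt(max(abs(d3$intensity - (3 * x[6:(length(x) - 5)] + 2 * a))), 1e-8)

  # sine input: compare against a central finite-difference oracle and bound
  # the SG error by the window-scale truncation error
  ys <- sin(x)
  ds <- sg_second_derivative(new_spectrum(x, ys, "ftir"), 11)
  fd <- (sin(ds$axis + 0.01) - 2 * sin(ds$axis) + sin(ds$axis - 0.01)) / 0.01^2
  # window-scale truncation bound: half-width 5 points -> (5 h)^2 * max|f''''|
  bound <- (5 * 0.01)^2 * 1
  expect_lt(max(abs(ds$intensity - fd)), bound)
  expect_lt(max(abs(ds$intensity + sin(ds$axis))), bound)

  expect_error(sg_second_derivative(new_spectrum(x, ys, "ftir"), 10), "odd")
  expect_error(sg_second_derivative(new_spectrum(x, ys, "ftir"), 3), "odd")
  expect_error(sg_second_derivative(ds, 11), "already differentiated")
})

test_that("truncation keeps exactly the in-range points", {
  x <- seq(-130, 130, by = 1)
  sp <- new_spectrum(x, rnorm(length(x)), "h1_wideline")
  tr <- truncate_spectrum(sp, -102, 102)
  expect_true(all(tr$axis >= -102 & tr$axis <= 102))
  expect_equal(length(tr$axis), sum(x >= -102 & x <= 102))

  full <- truncate_spectrum(sp, min(x), max(x))
  expect_equal(full$intensity, sp$intensity)
  expect_error(truncate_spectrum(sp, 200, 300), "removed every point")
  expect_error(truncate_spectrum(sp, 5, 5), "lo must be")
})

test_that("region exclusion removes interference windows and nothing else", {
  x <- seq(650, 4000, by = 2)
  sp <- new_spectrum(x, rnorm(length(x)), "ftir")
  regions <- list(c(1711, 2669), c(3400, 4000))
  ex <- exclude_regions(sp, regions)
  expect_false(any(ex$axis >= 1711 & ex$axis <= 2669))
  expect_false(any(ex$axis >= 3400 & ex$axis <= 4000))
  keep <- !((x >= 1711 & x <= 2669) | (x >= 3400 & x <= 4000))
  expect_equal(length(ex$axis), sum(keep))
  expect_true(all(diff(ex$axis) > 0))

  expect_equal(exclude_regions(sp, list())$intensity, sp$intensity)
  expect_error(exclude_regions(sp, list(c(0, 5000))), "every point")
})

test_that("total-area normalisation yields unit absolute area, scale-invariantly and idempotently", {
  x <- seq(0, 10, 0.05)
  y <- sin(3 * x) * exp(-x / 5)          # signed profile
  sp <- new_spectrum(x, y, "ftir", derivative_order = 0L)
  nm <- normalize_total_area(sp)
  area <- sum((abs(nm$intensity)[-1] + abs(nm$intensity)[-length(x)]) / 2 * diff(x))
  expect_equal(area, 1, tolerance = 1e-10)

  sp7 <- sp; sp7$intensity <- 7 * sp7$intensity
  expect_equal(normalize_total_area(sp7)$intensity, nm$intensity, tolerance = 1e-12)
  expect_equal(normalize_total_area(nm)$intensity, nm$intensity, tolerance = 1e-12)
  expect_error(normalize_total_area(new_spectrum(x, rep(0, length(x)), "ftir")), "zero")
})

test_that("DTG preparation produces 454 one-degree weight-normalised bins", {
  x <- seq(40, 500, by = 0.5)
  w <- 18.5
  sp <- new_spectrum(x, rep(3, length(x)), "dtg", sample_weight = w)
  out <- dtg_prepare(sp)
  expect_equal(length(out$axis), 454)
  expect_equal(out$axis[1], 44)
  expect_equal(out$axis[454], 497)
  expect_equal(unname(out$intensity), rep(3 / w, 454), tolerance = 1e-12)

  # bin means equal a brute-force group-by on left-closed intervals
  y <- sin(x / 20) + x / 100
  sp2 <- new_spectrum(x, y, "dtg", sample_weight = w)
  out2 <- dtg_prepare(sp2)
  oracle <- sapply(44:497, function(T) mean(y[x >= T & x < T + 1]) / w)
  expect_equal(unname(out2$intensity), oracle, tolerance = 1e-12)

  expect_error(dtg_prepare(new_spectrum(x, y, "dtg")), "weight")
  expect_error(dtg_prepare(new_spectrum(seq(50, 500, 0.5), rnorm(901), "dtg",
                                        sample_weight = 10)), "cover")
})

test_that("TD normalisation makes the fitted model equal one at t = 0", {
  set.seed(2)
  pd <- planted_decay(0.4, snr = 500)
  fit <- fit_td3(pd$decay)
  nm <- td_normalize(pd$decay, fit)
  expect_equal(td_fit_eval(fit, 0) / sum(fit$amplitudes), 1, tolerance = 1e-9)
  expect_equal(nm$intensity, pd$decay$intensity / sum(fit$amplitudes))
})

test_that("replicate averaging is the pointwise mean and rejects mismatched axes", {
  x <- seq(0, 1, 0.1)
  a <- new_spectrum(x, rep(0, 11), "ftir", replicate = 1L)
  b <- new_spectrum(x, rep(2, 11), "ftir", replicate = 2L)
  avg <- average_replicates(list(a, b))
  expect_equal(unname(avg$intensity), rep(1, 11))
  expect_true(is.na(avg$replicate))

  expect_equal(average_replicates(list(a, a))$intensity, a$intensity)

  set.seed(1)
  mats <- lapply(1:4, function(i) new_spectrum(x, rnorm(11), "ftir", replicate = i))
  avg4 <- average_replicates(mats)
  oracle <- colMeans(do.call(rbind, lapply(mats, `[[`, "intensity")))
  expect_equal(unname(avg4$intensity), unname(oracle))

  cc <- new_spectrum(x + 0.5, rep(1, 11), "ftir")
  expect_error(average_replicates(list(a, cc)), "axis mismatch")
})

test_that("baseline subtraction removes offsets and linear drift", {
  x <- seq(0, 100, 0.5)
  peak <- 5 * exp(-0.5 * ((x - 50) / 3)^2)
  sp0 <- new_spectrum(x, peak + 2, "ftir")
  out0 <- subtract_baseline(sp0, degree = 0)
  expect_lt(abs(median(out0$intensity[x < 30])), 0.05)

  sp1 <- new_spectrum(x, peak + 0.03 * x - 1, "ftir")
  out1 <- subtract_baseline(sp1, degree = 1)
  expect_lt(max(abs(out1$intensity[x < 30 | x > 70])), 0.1)
  expect_gt(max(out1$intensity), 4.5)
  expect_true(any(grepl("baseline", out1$lineage)))
})
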