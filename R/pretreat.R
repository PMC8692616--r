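#' Align a spectrum onto a common axis by cubic-spline interpolation
#'
#' Replicate curves from different acquisitions are re-sampled onto one shared
#' chemical-shift (or wavenumber/temperature) axis so they can be averaged and
#' binned consistently. Interpolation only; the target axis must lie inside
#' the source span.
#'
#' @param spectrum a `spectrum`.
#' @param target_axis strictly increasing numeric axis within the source span.
#' @return interpolated `spectrum`.
#' @export
interpolate_to_axis <- function(spectrum, target_axis) {
  if (length(spectrum$axis) < 4) stop("need at least 4 source points for a cubic spline")
  if (min(target_axis) < min(spectrum$axis) || max(target_axis) > max(spectrum$axis))
    stop("target axis extends beyond source span (no extrapolation)")
  f <- stats::splinefun(spectrum$axis, spectrum$intensity, method = "fmm")
  sp <- spectrum
  sp$axis <- as.numeric(target_axis)
  sp$intensity <- f(sp$axis)
  append_lineage(sp, "spline_align")
}

#' Savitzky-Golay second derivative (third-order polynomial)
#'
#' Second-order differentiation with a cubic Savitzky-Golay filter, the step
#' that sharpens overlapped bands and cancels constant/linear baseline drift.
#' The derivative is taken with respect to the axis units (the axis step is
#' honoured), so a profile in intensity vs ppm comes back in intensity/ppm^2.
#' Requires a uniform axis. The `(window_pts-1)/2` points at each edge, where
#' the fit window is incomplete, are dropped.
#'
#' @param spectrum a `spectrum` with `derivative_order` 0.
#' @param window_pts odd window length, >= 5 and < number of points.
#' @return differentiated `spectrum` (`derivative_order` 2).
#' @export
sg_second_derivative <- function(spectrum, window_pts = 11L) {
  n <- length(spectrum$axis)
  if (window_pts %% 2 == 0 || window_pts < 5) stop("window_pts must be odd and >= 5")
  if (window_pts >= n) stop("window_pts must be smaller than the spectrum length")
  if (spectrum$derivative_order != 0L) stop("spectrum already differentiated")
  h <- diff(spectrum$axis)
  if (max(h) - min(h) > 1e-8 * mean(h)) stop("SG differentiation needs a uniform axis")
  d2 <- signal::sgolayfilt(spectrum$intensity, p = 3, n = window_pts, m = 2,
                           ts = mean(h))
  half <- (window_pts - 1L) / 2L
  keep <- (half + 1L):(n - half)
  sp <- spectrum
  sp$axis <- sp$axis[keep]
  sp$intensity <- d2[keep]
  sp$derivative_order <- 2L
  append_lineage(sp, sprintf("sg2der(w=%d)", window_pts))
}

#' Truncate a spectrum to an informative axis region
#'
#' @param spectrum a `spectrum`.
#' @param lo,hi region bounds in axis units, `lo < hi`; points with
#'   `lo <= axis <= hi` are retained.
#' @return truncated `spectrum`.
#' @export
truncate_spectrum <- function(spectrum, lo, hi) {
  if (!(lo < hi)) stop("lo must be < hi")
  keep <- spectrum$axis >= lo & spectrum$axis <= hi
  if (!any(keep)) stop("truncation removed every point")
  sp <- spectrum
  sp$axis <- sp$axis[keep]
  sp$intensity <- sp$intensity[keep]
  append_lineage(sp, sprintf("truncate[%g,%g]", lo, hi))
}

#' Remove axis regions (e.g. ATR crystal interference windows)
#'
#' Points falling inside any `[lo, hi]` region are dropped; the axis stays
#' monotone with gaps, which downstream binning and integration tolerate.
#'
#' @param spectrum a `spectrum`.
#' @param regions list of numeric `c(lo, hi)` pairs.
#' @return `spectrum` with the regions excised.
#' @export
exclude_regions <- function(spectrum, regions) {
  if (length(regions) == 0) return(spectrum)
  drop <- rep(FALSE, length(spectrum$axis))
  for (r in regions) {
    if (length(r) != 2 || !(r[1] < r[2])) stop("each region must be c(lo, hi) with lo < hi")
    drop <- drop | (spectrum$axis >= r[1] & spectrum$axis <= r[2])
  }
  if (all(drop)) stop("exclusion removed every point")
  sp <- spectrum
  sp$axis <- sp$axis[!drop]
  sp$intensity <- sp$intensity[!drop]
  append_lineage(sp, sprintf("exclude(%s)", paste(
    vapply(regions, function(r) sprintf("[%g,%g]", r[1], r[2]), ""), collapse = ",")))
}

#' Normalise a profile to unit total area
#'
#' Total area is the trapezoidal integral of the absolute intensity. The
#' absolute value matters for second-derivative profiles, whose signed area is
#' near zero by construction and would make the scale ill-conditioned.
#'
#' @param spectrum a `spectrum`.
#' @param signed if TRUE use the signed trapezoidal area instead (must be
#'   nonzero); kept for comparison with conventions that integrate raw values.
#' @return area-normalised `spectrum`.
#' @export
normalize_total_area <- function(spectrum, signed = FALSE) {
  a <- if (signed) trapz_int(spectrum$axis, spectrum$intensity)
       else trapz_int(spectrum$axis, abs(spectrum$intensity))
  if (!is.finite(a) || abs(a) < .Machine$double.eps * length(spectrum$axis))
    stop("zero or non-finite total area; cannot normalize")
  sp <- spectrum
  sp$intensity <- sp$intensity / a
  append_lineage(sp, if (signed) "norm_area(signed)" else "norm_area")
}

#' Prepare a DTG curve: 1-degree binning and sample-weight normalisation
#'
#' Mass-loss-rate curves are rebinned to one-degree bins from 44 to 497 C
#' (left-closed intervals `[T, T+1)`, 454 bins, bin value = mean intensity)
#' and divided by the sample mass in mg, putting all samples on a common
#' percent-per-minute-like scale.
#'
#' @param spectrum a `spectrum` of modality `dtg` whose axis covers 44–497 C
#'   and with `sample_weight` set (mg).
#' @param lo,hi bin range in degrees C.
#' @return rebinned, weight-normalised `spectrum` (axis = bin left edges).
#' @export
dtg_prepare <- function(spectrum, lo = 44, hi = 497) {
  if (spectrum$modality != "dtg") stop("dtg_prepare expects a DTG curve")
  if (!is.finite(spectrum$sample_weight) || spectrum$sample_weight <= 0)
    stop("sample weight (mg) missing; cannot normalize DTG intensities")
  if (min(spectrum$axis) > lo || max(spectrum$axis) < hi)
    stop(sprintf("DTG axis must cover [%g, %g] degC", lo, hi))
  edges <- seq(lo, hi + 1, by = 1)          # left-closed [T, T+1)
  idx <- findInterval(spectrum$axis, edges, left.open = FALSE)
  ok <- idx >= 1 & idx <= (length(edges) - 1L)
  means <- tapply(spectrum$intensity[ok], factor(idx[ok], levels = seq_len(length(edges) - 1L)), mean)
  if (anyNA(means)) stop("empty 1-degree DTG bin; raw sampling is too coarse")
  sp <- spectrum
  sp$axis <- edges[-length(edges)]
  sp$intensity <- as.numeric(means) / spectrum$sample_weight
  append_lineage(sp, sprintf("dtg_bin1C[%g,%g]+weight_norm", lo, hi))
}

#' Normalise a TD-NMR decay by its fitted t=0 intensity
#'
#' The decay is divided by the sum of the fitted component amplitudes, so the
#' fitted model evaluates to one at t = 0. Requires the fit obtained on this
#' decay (see [fit_td3()]).
#'
#' @param decay a `spectrum` of modality `tdnmr`.
#' @param fit a `td_fit` from [fit_td3()].
#' @return normalised `spectrum`.
#' @export
td_normalize <- function(decay, fit) {
  if (decay$modality != "tdnmr") stop("td_normalize expects a TD-NMR decay")
  a0 <- sum(fit$amplitudes)
  if (!is.finite(a0) || a0 <= 0) stop("fitted amplitude sum at t=0 is not positive")
  sp <- decay
  sp$intensity <- sp$intensity / a0
  append_lineage(sp, "td_norm(t0=1)")
}

#' Optional polynomial baseline subtraction
#'
#' Fits a low-order polynomial (degree at most 2) to the baseline points —
#' taken as the points whose intensity lies below the given quantile — and
#' subtracts it. Off by default throughout the pipeline: instrument-side
#' baseline/phase handling is assumed done, and the synthetic data are
#' baseline-clean; the hook exists for curves that are not.
#'
#' @param spectrum a `spectrum`.
#' @param degree polynomial degree, 0..2.
#' @param quantile fraction of lowest-intensity points used as baseline
#'   support (default 0.3).
#' @return baseline-subtracted `spectrum`.
#' @export
subtract_baseline <- function(spectrum, degree = 1L, quantile = 0.3) {
  stopifnot(degree %in% 0:2, quantile > 0, quantile <= 1)
  keep <- spectrum$intensity <= stats::quantile(spectrum$intensity, quantile)
  if (sum(keep) <= degree + 1) stop("too few baseline support points")
  base <- if (degree == 0) {
    rep(mean(spectrum$intensity[keep]), length(spectrum$axis))
  } else {
    fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE),
                     data = data.frame(x = spectrum$axis[keep],
                                       y = spectrum$intensity[keep]))
    stats::predict(fit, newdata = data.frame(x = spectrum$axis))
  }
  sp <- spectrum
  sp$intensity <- sp$intensity - as.numeric(base)
  append_lineage(sp, sprintf("baseline(deg=%d)", degree))
}

#' Pointwise average of replicate spectra
#'
#' @param spectra list of `spectrum` objects sharing modality, sample and axis.
#' @return aggregate `spectrum` (replicate = NA).
#' @export
average_replicates <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  ref <- spectra[[1]]
  for (sp in spectra[-1]) {
    if (sp$modality != ref$modality) stop("modality mismatch among replicates")
    if (length(sp$axis) != length(ref$axis) ||
        max(abs(sp$axis - ref$axis)) > 1e-9)
      stop("axis mismatch among replicates; align first")
  }
  out <- ref
  out$intensity <- rowMeans(vapply(spectra, `[[`, numeric(length(ref$axis)), "intensity"))
  out$replicate <- NA_integer_
  append_lineage(out, sprintf("avg(n=%d)", length(spectra)))
}
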