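.mdselect_env <- new.env(parent = emptyenv())

# Weideman (1994) rational-approximation coefficients, computed once.
weideman_coef <- function(N = 36L) {
  key <- paste0("wcoef", N)
  if (!is.null(.mdselect_env[[key]])) return(.mdselect_env[[key]])
  M <- 2L * N
  k <- seq(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  tt <- L * tan(theta / 2)
  f <- c(0, exp(-tt^2) * (L^2 + tt^2))
  n <- length(f)
  fs <- c(f[(n / 2 + 1):n], f[1:(n / 2)])
  a <- Re(stats::fft(fs)) / (2 * M)
  .mdselect_env[[key]] <- list(a = rev(a[2:(N + 1)]), L = L)
  .mdselect_env[[key]]
}

#' Faddeeva function w(z) for Im(z) >= 0
#'
#' Scaled complex complementary error function, w(z) = exp(-z^2) erfc(-iz),
#' whose real part gives the Voigt profile. Evaluated by Weideman's
#' rational approximation (36 terms, near machine precision over the upper
#' half-plane), which is fast enough to sit inside least-squares fits.
#'
#' @param z complex vector with nonnegative imaginary part.
#' @return complex vector w(z).
#' @keywords internal
faddeeva_w <- function(z) {
  stopifnot(all(Im(z) >= -1e-15))
  cf <- weideman_coef()
  L <- cf$L
  Z <- (L + 1i * z) / (L - 1i * z)
  p <- 0
  for (c0 in cf$a) p <- p * Z + c0
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

#' Voigt line-shape profile
#'
#' Convolution of a Gaussian (width `sigma`) and a Lorentzian (half width at
#' half maximum `gamma`), scaled so the profile integrates to `amplitude`
#' over the real line. The pure limits are evaluated in closed form.
#'
#' @param x axis positions (ppm).
#' @param center peak centre (ppm).
#' @param sigma Gaussian standard deviation, >= 0.
#' @param gamma Lorentzian HWHM, >= 0 (not both zero).
#' @param amplitude integrated area, >= 0.
#' @return intensity values at `x`.
#' @export
voigt_profile <- function(x, center = 0, sigma = 1, gamma = 1, amplitude = 1) {
  if (sigma < 0 || gamma < 0) stop("sigma and gamma must be nonnegative")
  if (sigma == 0 && gamma == 0) stop("sigma and gamma cannot both be zero")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (gamma == 0) return(amplitude * stats::dnorm(x, center, sigma))
  if (sigma == 0) return(amplitude * gamma / (pi * ((x - center)^2 + gamma^2)))
  z <- ((x - center) + 1i * gamma) / (sigma * sqrt(2))
  amplitude * Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

#' Olivero-Longbothum approximation to the Voigt FWHM
#'
#' @param sigma Gaussian sd; @param gamma Lorentzian HWHM.
#' @return approximate FWHM.
#' @export
voigt_fwhm_approx <- function(sigma, gamma) {
  fG <- 2 * sqrt(2 * log(2)) * sigma
  fL <- 2 * gamma
  0.5346 * fL + sqrt(0.2166 * fL^2 + fG^2)
}

#' Exact Voigt FWHM by bracketed root finding
#'
#' Solves profile(x) = max/2 on the profile itself (the approximation is used
#' only to seed the bracket), so the result is exact to the root tolerance in
#' all mixing regimes including the pure Gaussian/Lorentzian limits.
#'
#' @param sigma Gaussian sd; @param gamma Lorentzian HWHM (not both zero).
#' @return full width at half maximum.
#' @export
voigt_fwhm <- function(sigma, gamma) {
  if (sigma == 0 && gamma == 0) stop("sigma and gamma cannot both be zero")
  half <- voigt_profile(0, 0, sigma, gamma, 1) / 2
  guess <- voigt_fwhm_approx(sigma, gamma) / 2
  hi <- guess
  while (voigt_profile(hi, 0, sigma, gamma, 1) > half) hi <- hi * 1.5
  r <- stats::uniroot(function(u) voigt_profile(u, 0, sigma, gamma, 1) - half,
                      lower = guess * 0.5, upper = hi, tol = 1e-13 * max(1, guess))
  2 * r$root
}

voigt3_model <- function(par, x) {
  voigt_profile(x, par[1], par[2], par[3], par[4]) +
    voigt_profile(x, par[5], par[6], par[7], par[8]) +
    voigt_profile(x, par[9], par[10], par[11], par[12])
}

#' Decompose a wide-line 1H spectrum into three Voigt peaks
#'
#' Least-squares fit of a sum of three Voigt profiles, the deconvolution used
#' to separate the broad rigid-proton envelope from the narrow mobile-proton
#' peak in static solid-state 1H spectra. Initial centres come from the three
#' largest local maxima of a lightly smoothed copy of the spectrum (ties
#' broken toward lower ppm); if `init` is not given, a fixed grid of width
#' combinations is tried and the best residual kept, so the fit is
#' deterministic.
#'
#' @param spectrum a `spectrum` (modality `h1_wideline`, nonderivative).
#' @param init optional 3x4 matrix of starting values
#'   (columns center, sigma, gamma, amplitude).
#' @return `voigt_fit`: list with `peaks` (3x4 matrix), `area_proportions`,
#'   `fwhm`, `residual_rms`, `fitted` (model values on the input axis).
#' @export
fit_voigt3 <- function(spectrum, init = NULL) {
  x <- spectrum$axis; y <- spectrum$intensity
  span <- diff(range(x))
  total <- trapz_int(x, abs(y))
  lower <- rep(c(min(x), span * 1e-5, 0, total * 1e-6), 3)
  upper <- rep(c(max(x), span, span, Inf), 3)
  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- as.numeric(t(init))
  } else {
    sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- y[is.na(sm)]
    loc <- which(diff(sign(diff(sm))) < 0) + 1L
    loc <- loc[order(-sm[loc], x[loc])]
    centers <- x[loc]
    if (length(centers) < 3)
      centers <- c(centers, rep(x[which.max(y)], 3 - length(centers)))
    centers <- centers[1:3]
    # peak stripping: fit the broad envelope alone, then seed the remaining
    # two peaks from the residual's dominant features
    s1 <- c(centers[1], span / 6, span / 12, total)
    f1 <- try(minpack.lm::nls.lm(
      par = s1, lower = lower[1:4], upper = upper[1:4],
      fn = function(p) voigt_profile(x, p[1], p[2], p[3], p[4]) - y,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (!inherits(f1, "try-error")) {
      res <- y - voigt_profile(x, f1$par[1], f1$par[2], f1$par[3], f1$par[4])
      c2 <- x[which.max(res)]
      res_amp <- max(trapz_int(x, pmax(res, 0)), total * 0.01)
      for (wfrac in c(0.05, 0.02, 0.1)) {
        w2 <- wfrac * span
        starts[[length(starts) + 1]] <- c(
          f1$par[1], f1$par[2], f1$par[3], f1$par[4] * 0.9,
          c2, w2 / 2, w2 / 4, res_amp * 0.6,
          c2, w2 / 8, w2 / 16, res_amp * 0.4)
      }
    }
    width_grid <- list(c(0.25, 0.05, 0.01), c(0.35, 0.1, 0.02),
                       c(0.15, 0.03, 0.005), c(0.3, 0.02, 0.08),
                       c(0.2, 0.1, 0.05), c(0.4, 0.05, 0.005))
    for (wg in width_grid) {
      s <- numeric(0)
      amps <- c(0.6, 0.25, 0.15) * total
      for (k in 1:3) {
        w <- wg[k] * span
        s <- c(s, centers[k], w / 2, w / 4, amps[k])
      }
      starts[[length(starts) + 1]] <- s
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(s, lower), upper),
      lower = lower, upper = upper,
      fn = function(p) voigt3_model(p, x) - y,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    # a fit at the numerical noise floor cannot be improved by more starts
    if (best$rss < 1e-6 * sum(y^2)) break
  }
  if (is.null(best)) stop("Voigt-3 fit failed to converge from any start")
  p <- best$fit$par
  peaks <- matrix(p, nrow = 3, byrow = TRUE,
                  dimnames = list(NULL, c("center", "sigma", "gamma", "amplitude")))
  peaks <- peaks[order(-voigt_fwhm_vec(peaks[, "sigma"], peaks[, "gamma"])), , drop = FALSE]
  amps <- peaks[, "amplitude"]
  if (sum(amps) <= 0) stop("degenerate Voigt-3 fit: zero total amplitude")
  structure(list(
    peaks = peaks,
    area_proportions = amps / sum(amps),
    fwhm = voigt_fwhm_vec(peaks[, "sigma"], peaks[, "gamma"]),
    residual_rms = sqrt(best$rss / length(x)),
    fitted = voigt3_model(as.numeric(t(peaks)), x)), class = "voigt_fit")
}

voigt_fwhm_vec <- function(sigma, gamma) {
  mapply(function(s, g) if (s == 0 && g == 0) NA_real_ else voigt_fwhm(s, g),
         sigma, gamma)
}

#' @export
print.voigt_fit <- function(x, ...) {
  cat("<voigt_fit>\n")
  print(cbind(x$peaks, proportion = x$area_proportions, fwhm = x$fwhm))
  cat("residual rms:", x$residual_rms, "\n")
  invisible(x)
}
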