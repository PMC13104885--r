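#' Raman spectrum
#'
#' Intensities I(nu) on a strictly increasing wavenumber grid (cm^-1), with a
#' record of the processing steps already applied.
#'
#' @param wavenumbers numeric, strictly increasing, cm^-1.
#' @param intensities numeric, same length, arbitrary units.
#' @param processing character vector of transforms applied so far.
#' @return an object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, processing = character()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (anyNA(wavenumbers) || anyNA(intensities))
    stop("NA in spectrum")
  if (length(wavenumbers) >= 2 && any(diff(wavenumbers) <= 0))
    stop("wavenumber grid must be strictly increasing")
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 processing = processing),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("raman_spectrum: %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$processing))
    cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    all(abs(a$wavenumbers - b$wavenumbers) < tol)
}

#' Regrid a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto `seq(min, max, by = step)`. The start endpoint
#' is always preserved; the end endpoint is preserved when the input span is
#' a multiple of the step.
#'
#' @param spectrum a [raman_spectrum()].
#' @param step grid step in cm^-1 (default 1).
#' @return regridded `raman_spectrum`.
#' @export
regrid <- function(spectrum, step = 1) {
  stopifnot(inherits(spectrum, "raman_spectrum"), step > 0)
  w <- spectrum$wavenumbers
  if (length(w) < 2) stop("need at least 2 samples to regrid")
  grid <- seq(w[1], w[length(w)], by = step)
  y <- stats::approx(w, spectrum$intensities, xout = grid)$y
  raman_spectrum(grid, y, c(spectrum$processing, sprintf("regrid(%g)", step)))
}

#' Subtract a background spectrum point-wise
#'
#' Both spectra must be on identical grids (regrid first otherwise).
#'
#' @param spectrum,background [raman_spectrum()] objects on the same grid.
#' @return background-subtracted `raman_spectrum`.
#' @export
subtract_background <- function(spectrum, background) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(background, "raman_spectrum"))
  if (!same_grid(spectrum, background))
    stop("spectrum and background are on different wavenumber grids")
  raman_spectrum(spectrum$wavenumbers,
                 spectrum$intensities - background$intensities,
                 c(spectrum$processing, "subtract_background"))
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline by iteratively reweighted penalized least
#' squares (second-difference penalty `lambda`, asymmetry `p`: points above
#' the current baseline get weight `p`, points below get `1 - p`) and
#' subtracts it, preserving positive peaks.
#'
#' @param spectrum a [raman_spectrum()] (regrid first).
#' @param lambda smoothness penalty (> 0), default 1e5.
#' @param p asymmetry parameter in (0, 1), default 0.01.
#' @param n_iter number of reweighting iterations, default 10.
#' @return baseline-corrected `raman_spectrum`; the estimated baseline is
#'   attached as attribute `"baseline"`.
#' @export
baseline_correct <- function(spectrum, lambda = 1e5, p = 0.01, n_iter = 10) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (lambda <= 0) stop("lambda must be positive")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  y <- spectrum$intensities
  n <- length(y)
  if (n < 3) stop("need at least 3 points for baseline correction")
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  out <- raman_spectrum(spectrum$wavenumbers, y - z,
                        c(spectrum$processing, "baseline_correct"))
  attr(out, "baseline") <- z
  out
}

#' Vector-normalize a spectrum to unit Euclidean norm
#'
#' @param spectrum a [raman_spectrum()] with non-zero intensity vector.
#' @return normalized `raman_spectrum` (Euclidean norm 1).
#' @export
vector_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  nrm <- sqrt(sum(spectrum$intensities^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
  raman_spectrum(spectrum$wavenumbers, spectrum$intensities / nrm,
                 c(spectrum$processing, "vector_normalize"))
}

#' Point-wise mean of spectra on a common grid
#'
#' @param spectra non-empty list of [raman_spectrum()] objects, all on the
#'   same grid.
#' @return mean `raman_spectrum`.
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0)
    stop("spectra must be a non-empty list")
  ref <- spectra[[1]]
  for (s in spectra) {
    stopifnot(inherits(s, "raman_spectrum"))
    if (!same_grid(ref, s)) stop("spectra are on different wavenumber grids")
  }
  ys <- vapply(spectra, function(s) s$intensities,
               numeric(length(ref$intensities)))
  m <- if (is.matrix(ys)) rowMeans(ys) else ys
  raman_spectrum(ref$wavenumbers, m,
                 c(ref$processing, sprintf("average(%d)", length(spectra))))
}

#' Mean band intensity over a wavenumber window
#'
#' Mean intensity over `[center - halfwidth, center + halfwidth]`. Ratios in
#' this package are computed on regridded, background-subtracted but
#' otherwise unprocessed spectra.
#'
#' @param spectrum a [raman_spectrum()].
#' @param center band center, cm^-1.
#' @param halfwidth half-window, cm^-1 (default 2).
#' @return mean intensity in the window (a.u.).
#' @export
band_intensity <- function(spectrum, center, halfwidth = 2) {
  stopifnot(inherits(spectrum, "raman_spectrum"), halfwidth >= 0)
  w <- spectrum$wavenumbers
  if (center - halfwidth < min(w) || center + halfwidth > max(w))
    stop(sprintf("window %g +/- %g cm^-1 is outside the grid [%g, %g]",
                 center, halfwidth, min(w), max(w)))
  sel <- w >= center - halfwidth & w <= center + halfwidth
  mean(spectrum$intensities[sel])
}

#' Band intensity ratio between two centers
#'
#' Realizes the ratio metrics CD/CH 2140/2850, D-lipid 2176/2850,
#' unsaturation 3012/2850 and lipid/protein 2850/2935 as
#' `band_intensity(numerator) / band_intensity(denominator)`.
#'
#' @param spectrum a [raman_spectrum()].
#' @param numerator_center,denominator_center band centers, cm^-1.
#' @param halfwidth half-window, cm^-1 (default 2).
#' @return dimensionless ratio.
#' @export
band_ratio <- function(spectrum, numerator_center, denominator_center,
                       halfwidth = 2) {
  den <- band_intensity(spectrum, denominator_center, halfwidth)
  if (den <= 0)
    stop(sprintf("denominator band at %g cm^-1 has non-positive intensity (%g)",
                 denominator_center, den))
  band_intensity(spectrum, numerator_center, halfwidth) / den
}

gaussian_sum <- function(x, amp, center, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  y <- numeric(length(x))
  for (i in seq_along(amp))
    y <- y + amp[i] * exp(-(x - center[i])^2 / (2 * sig[i]^2))
  y
}

#' Fit a sum of Gaussian peaks in a window
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt): one Gaussian per
#' initial center, centers constrained to +/- 8 cm^-1 of their initials,
#' amplitudes >= 0, widths > 0.
#'
#' @param spectrum a [raman_spectrum()].
#' @param window numeric length-2, fitting window (lo, hi) in cm^-1.
#' @param initial_centers initial peak centers inside the window.
#' @param center_tol allowed center shift from initials, cm^-1 (default 8).
#' @param max_iter maximum optimizer iterations (default 200).
#' @return data.frame with one row per peak: `center`, `amplitude`, `fwhm`,
#'   `area` (amplitude * sigma * sqrt(2*pi)).
#' @export
fit_peaks <- function(spectrum, window, initial_centers, center_tol = 8,
                      max_iter = 200) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            length(window) == 2, window[1] < window[2],
            length(initial_centers) >= 1)
  w <- spectrum$wavenumbers
  if (window[1] < min(w) || window[2] > max(w))
    stop("fitting window is outside the grid")
  if (any(initial_centers < window[1] | initial_centers > window[2]))
    stop("all initial centers must lie inside the window")
  sel <- w >= window[1] & w <= window[2]
  x <- w[sel]; y <- spectrum$intensities[sel]
  k <- length(initial_centers)
  amp0 <- vapply(initial_centers, function(c0) {
    max(y[abs(x - c0) <= 5], 0)
  }, 1)
  amp0[amp0 <= 0] <- 1e-3
  par0 <- c(amp0, initial_centers, rep(15, k))
  lower <- c(rep(0, k), initial_centers - center_tol, rep(1, k))
  upper <- c(rep(Inf, k), initial_centers + center_tol, rep(200, k))
  resid_fn <- function(par) {
    gaussian_sum(x, par[1:k], par[(k + 1):(2 * k)], par[(2 * k + 1):(3 * k)]) - y
  }
  fit <- minpack.lm::nls.lm(par0, lower, upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter))
  if (!(fit$info %in% 1:4))
    stop(sprintf("peak fit did not converge (info %d, residual norm %.4g)",
                 fit$info, sqrt(fit$deviance)))
  par <- fit$par
  sig <- par[(2 * k + 1):(3 * k)] / (2 * sqrt(2 * log(2)))
  out <- data.frame(center = par[(k + 1):(2 * k)],
                    amplitude = par[1:k],
                    fwhm = par[(2 * k + 1):(3 * k)],
                    area = par[1:k] * sig * sqrt(2 * pi))
  out[order(out$center), , drop = FALSE]
}

#' Lipid-ordering area ratio A2885/A2850
#'
#' Joint five-Gaussian decomposition of the CH stretching region
#' (2,800-3,050 cm^-1, initial centers 2850, 2871, 2885, 2927, 2958 cm^-1);
#' returns area(2885 band) / area(2850 band). The 2885 band is enhanced by
#' ordered acyl-chain packing while 2850 is insensitive to it, so the ratio
#' increases with lipid ordering.
#'
#' @param spectrum a [raman_spectrum()] whose grid covers 2,800-3,050 cm^-1.
#' @param min_amplitude amplitudes below this raise an error naming the
#'   missing band (default 1e-6).
#' @return dimensionless area ratio.
#' @export
area_ratio_2885_2850 <- function(spectrum, min_amplitude = 1e-6) {
  peaks <- fit_peaks(spectrum, c(2800, 3050),
                     initial_centers = c(2850, 2871, 2885, 2927, 2958))
  p2850 <- peaks[which.min(abs(peaks$center - 2850)), ]
  p2885 <- peaks[which.min(abs(peaks$center - 2885)), ]
  if (p2850$amplitude < min_amplitude)
    stop("no detectable band at 2,850 cm^-1")
  if (p2885$amplitude < min_amplitude)
    stop("no detectable band at 2,885 cm^-1")
  p2885$area / p2850$area
}

#' Half-height bandwidth (FWHM) of a local peak
#'
#' Finds the local maximum nearest `center` within `center +/-
#' search_halfwidth`, estimates a local linear baseline anchored at the mean
#' (wavenumber, intensity) of the flanking bands `[center +
#' 2*search_halfwidth, center + 3*search_halfwidth]` and its mirror (clamped
#' to the grid) — band means are unbiased under noise, exact for linear
#' local baselines, and far enough out that peak tails are negligible — and
#' returns the full width at half the baseline-corrected apex height. The
#' apex is refined by a parabola through the three top grid points;
#' half-height crossings are located by linear interpolation between
#' adjacent grid points.
#'
#' @param spectrum a [raman_spectrum()].
#' @param center expected peak position, cm^-1 (e.g. 1295 for the (CH2)n
#'   in-phase twisting band).
#' @param search_halfwidth half-width of the peak search window, cm^-1
#'   (default 15).
#' @return FWHM in cm^-1.
#' @export
half_height_bandwidth <- function(spectrum, center, search_halfwidth = 15) {
  stopifnot(inherits(spectrum, "raman_spectrum"), search_halfwidth > 0)
  w <- spectrum$wavenumbers
  y <- spectrum$intensities
  in_win <- which(w >= center - search_halfwidth & w <= center + search_halfwidth)
  if (length(in_win) < 3) stop("search window contains too few grid points")
  yw <- y[in_win]
  # local maxima: strictly above both neighbours (window-interior points)
  loc <- in_win[which(diff(sign(diff(yw))) == -2) + 1L]
  if (length(loc) == 0)
    stop(sprintf("no local maximum within %g +/- %g cm^-1",
                 center, search_halfwidth))
  peak <- loc[which.min(abs(w[loc] - center))]
  # baseline anchors: minima over flanking bands clear of the peak core
  lo_band <- which(w >= center - 3 * search_halfwidth &
                     w <= center - 2 * search_halfwidth)
  hi_band <- which(w >= center + 2 * search_halfwidth &
                     w <= center + 3 * search_halfwidth)
  if (length(lo_band) == 0) lo_band <- 1L
  if (length(hi_band) == 0) hi_band <- length(w)
  # anchor each side at the flank band's mean (wavenumber, intensity):
  # unbiased under noise and exact for linear local baselines
  wl <- mean(w[lo_band]); yl <- mean(y[lo_band])
  wr <- mean(w[hi_band]); yr <- mean(y[hi_band])
  slope <- (yr - yl) / (wr - wl)
  net <- y - (yl + slope * (w - wl))
  # apex height from a parabola through the three top points: unbiased under
  # noise, exact for a grid-centered symmetric peak
  y0 <- net[peak]
  height <- if (peak > 1 && peak < length(w)) {
    ym <- net[peak - 1]; yp <- net[peak + 1]
    denom <- 2 * y0 - ym - yp
    if (denom > 0) y0 + (yp - ym)^2 / (8 * denom) else y0
  } else y0
  if (height <= 0) stop("peak has non-positive height above local baseline")
  half <- height / 2
  cross <- function(dir) {
    i <- peak
    repeat {
      j <- i + dir
      if (j < 1 || j > length(w))
        stop("half-height crossing falls outside the grid")
      if (net[j] <= half) {
        # linear interpolation between grid points i and j
        frac <- (net[i] - half) / (net[i] - net[j])
        return(w[i] + frac * (w[j] - w[i]))
      }
      i <- j
    }
  }
  cross(+1L) - cross(-1L)
}
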