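gauss <- function(x, amp, center, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  amp * exp(-(x - center)^2 / (2 * sig^2))
}

test_that("regrid interpolates exactly for affine signals and is idempotent", {
  w <- c(100, 101.3, 103, 104.2, 107, 110)
  s <- raman_spectrum(w, 2 * w + 1)
  rg <- regrid(s, step = 1)
  expect_equal(rg$wavenumbers, seq(100, 110, by = 1))
  expect_equal(rg$intensities, 2 * rg$wavenumbers + 1)
  u <- raman_spectrum(seq(100, 110, 1), rnorm(11))
  expect_equal(regrid(u, 1)$intensities, u$intensities)
  expect_error(raman_spectrum(c(1, 3, 2), c(0, 0, 0)), "increasing")
})

test_that("regrid to 1 cm-1 shifts a Gaussian peak maximum by < 1 cm-1", {
  w <- seq(2800, 2900, by = 0.5)
  s <- raman_spectrum(w, gauss(w, 1, 2850.3, 20))
  rg <- regrid(s, step = 1)
  expect_lt(abs(rg$wavenumbers[which.max(rg$intensities)] - 2850.3), 1)
})

test_that("background subtraction is an exact pointwise difference", {
  w <- seq(1000, 1100, 1)
  sig <- raman_spectrum(w, gauss(w, 1, 1050, 10))
  expect_true(all(subtract_background(sig, sig)$intensities == 0))
  bg <- raman_spectrum(w, rep(5, length(w)))
  shifted <- raman_spectrum(w, sig$intensities + 5)
  expect_equal(subtract_background(shifted, bg)$intensities, sig$intensities)
  other <- raman_spectrum(w + 0.5, sig$intensities)
  expect_error(subtract_background(sig, other), "grid")
})

test_that("subtracting the true background leaves zero-mean residual noise", {
  noise_sd <- 0.05
  d <- spectrum_design(baseline_coeffs = c(3), noise_sd = noise_sd,
                       grid = c(1000, 1999, 1), seed = 3)
  s <- generate_spectrum(d)$spectrum
  bg <- raman_spectrum(s$wavenumbers, rep(3, length(s$wavenumbers)))
  res <- subtract_background(s, bg)$intensities
  expect_lt(abs(mean(res)), 2 * noise_sd / sqrt(length(res)))
})

test_that("asymmetric least squares baseline removal preserves peaks", {
  w <- seq(1000, 1600, 1)
  flat <- raman_spectrum(w, rep(4, length(w)))
  expect_true(all(abs(baseline_correct(flat)$intensities) < 1e-6 * 4))
  zero <- raman_spectrum(w, rep(0, length(w)))
  expect_true(all(baseline_correct(zero)$intensities == 0))
  sloped <- raman_spectrum(w, gauss(w, 1, 1295, 15) + 0.001 * w)
  corrected <- baseline_correct(sloped)
  amp <- max(corrected$intensities)
  expect_lt(abs(amp - 1), 0.03)
  expect_error(baseline_correct(flat, lambda = -1), "lambda")
  expect_error(baseline_correct(flat, p = 0), "p must")
})

test_that("vector normalization yields unit norm and is scale invariant", {
  s <- raman_spectrum(c(1, 2), c(3, 4))
  expect_equal(vector_normalize(s)$intensities, c(0.6, 0.8))
  w <- seq(1, 100, 1)
  set.seed(7)
  r <- raman_spectrum(w, abs(rnorm(100)) + 0.1)
  r10 <- raman_spectrum(w, r$intensities * 10)
  expect_equal(vector_normalize(r)$intensities,
               vector_normalize(r10)$intensities)
  expect_lt(abs(sqrt(sum(vector_normalize(r)$intensities^2)) - 1), 1e-12)
  # idempotence: normalizing twice equals once
  expect_equal(vector_normalize(vector_normalize(r))$intensities,
               vector_normalize(r)$intensities)
  expect_error(vector_normalize(raman_spectrum(w, rep(0, 100))), "zero")
})

test_that("group averaging reduces noise at the 1/sqrt(n) rate", {
  d <- spectrum_design(peaks = data.frame(center = 1295, amplitude = 1,
                                          fwhm = 14),
                       grid = c(1200, 1400, 1))
  truth <- generate_spectrum(d)$spectrum
  reps <- lapply(1:100, function(s) {
    dn <- spectrum_design(peaks = d$peaks, noise_sd = 0.1,
                          grid = c(1200, 1400, 1), seed = s)
    generate_spectrum(dn)$spectrum
  })
  avg <- average_spectra(reps)
  rms <- sqrt(mean((avg$intensities - truth$intensities)^2))
  expect_lt(rms, 0.02)
  expect_equal(average_spectra(list(truth))$intensities, truth$intensities)
  neg <- raman_spectrum(truth$wavenumbers, -truth$intensities)
  expect_true(all(average_spectra(list(truth, neg))$intensities == 0))
  expect_error(average_spectra(list()), "non-empty")
})

test_that("band intensity is a windowed mean with explicit range checks", {
  w <- seq(2000, 3000, 1)
  const <- raman_spectrum(w, rep(2.5, length(w)))
  expect_equal(band_intensity(const, 2500, 2), 2.5)
  expect_error(band_intensity(const, 2001, 5), "outside")
  g <- raman_spectrum(w, gauss(w, 1, 2850, 20))
  # oracle: direct evaluation of the Gaussian at the five window grid points
  expected <- mean(gauss(2848:2852, 1, 2850, 20))
  expect_equal(band_intensity(g, 2850, 2), expected, tolerance = 1e-12)
  far <- band_intensity(g, 2200, 2)
  expect_lt(abs(far), 1e-12)
})

test_that("band ratios follow amplitude ratios and are scale invariant", {
  w <- seq(2000, 3000, 1)
  y <- gauss(w, 0.5, 2140, 20) + gauss(w, 1.0, 2850, 20)
  s <- raman_spectrum(w, y)
  expect_equal(band_ratio(s, 2140, 2850), 0.5, tolerance = 1e-9)
  sk <- raman_spectrum(w, y * 17.3)
  expect_lt(abs(band_ratio(s, 2140, 2850) - band_ratio(sk, 2140, 2850)),
            1e-12)
  expect_error(band_ratio(raman_spectrum(w, -y), 2140, 2850), "non-positive")
})

test_that("noisy band ratios concentrate around the design ratio", {
  ratios <- vapply(1:50, function(s) {
    d <- spectrum_design(
      peaks = data.frame(center = c(2140, 2850), amplitude = c(0.5, 1),
                         fwhm = c(20, 20)),
      noise_sd = 0.01, grid = c(2000, 3000, 1), seed = s)
    band_ratio(generate_spectrum(d)$spectrum, 2140, 2850)
  }, 1)
  expect_lt(abs(mean(ratios) - 0.5), 0.02)
})

test_that("ratios computed before and after vector normalization agree", {
  w <- seq(2000, 3050, 1)
  s <- raman_spectrum(w, gauss(w, 0.5, 2140, 20) + gauss(w, 1, 2850, 20) +
                        gauss(w, 0.8, 2935, 18))
  for (num in c(2140, 2935))
    expect_lt(abs(band_ratio(s, num, 2850) -
                    band_ratio(vector_normalize(s), num, 2850)), 1e-12)
})

test_that("peak fitting recovers noiseless Gaussian parameters to < 0.1%", {
  d <- spectrum_design(peaks = data.frame(center = 2885, amplitude = 0.8,
                                          fwhm = 18),
                       grid = c(2800, 2970, 1))
  s <- generate_spectrum(d)
  pk <- fit_peaks(s$spectrum, c(2810, 2960), 2885)
  expect_lt(abs(pk$center - 2885) / 2885, 0.001)
  expect_lt(abs(pk$amplitude - 0.8) / 0.8, 0.001)
  expect_lt(abs(pk$fwhm - 18) / 18, 0.001)
  expect_lt(abs(pk$area - s$truth$area) / s$truth$area, 0.001)
})

test_that("overlapping Gaussians are decomposed to within 2% in area", {
  d <- spectrum_design(
    peaks = data.frame(center = c(2850, 2885), amplitude = c(1.0, 0.8),
                       fwhm = c(20, 20)),
    noise_sd = 0.005, grid = c(2780, 2960, 1), seed = 2)
  s <- generate_spectrum(d)
  pk <- fit_peaks(s$spectrum, c(2790, 2950), c(2850, 2885))
  for (i in 1:2)
    expect_lt(abs(pk$area[i] - s$truth$area[i]) / s$truth$area[i], 0.02)
})

test_that("fitting a flat zero window returns negligible amplitudes", {
  w <- seq(2800, 3000, 1)
  s <- raman_spectrum(w, rep(0, length(w)))
  pk <- fit_peaks(s, c(2810, 2990), c(2850, 2935))
  expect_true(all(pk$amplitude < 1e-6))
})

test_that("A2885/A2850 equals the analytic area ratio in clean designs", {
  mk <- function(a2850, a2885, f2850 = 20, f2885 = 20) {
    spectrum_design(
      peaks = data.frame(center = c(2850, 2871, 2885, 2927, 2958),
                         amplitude = c(a2850, 0.4, a2885, 0.7, 0.3),
                         fwhm = c(f2850, 18, f2885, 22, 18)),
      grid = c(2700, 3100, 1))
  }
  s1 <- generate_spectrum(mk(1.0, 0.8))
  expect_lt(abs(area_ratio_2885_2850(s1$spectrum) - 0.8), 0.01)
  s2 <- generate_spectrum(mk(1.0, 1.0, f2850 = 20, f2885 = 16))
  expect_lt(abs(area_ratio_2885_2850(s2$spectrum) - 0.8), 0.01)
  # missing band is a named error
  no2885 <- spectrum_design(
    peaks = data.frame(center = c(2850, 2927), amplitude = c(1, 0.5),
                       fwhm = c(20, 20)),
    grid = c(2700, 3100, 1))
  expect_error(area_ratio_2885_2850(generate_spectrum(no2885)$spectrum),
               "2,885")
})

test_that("half-height bandwidth matches construction for both line shapes", {
  g14 <- generate_spectrum(spectrum_design(
    peaks = data.frame(center = 1295, amplitude = 1, fwhm = 14),
    grid = c(1200, 1400, 1)))$spectrum
  expect_lt(abs(half_height_bandwidth(g14, 1295) - 14), 0.1)
  l10 <- generate_spectrum(spectrum_design(
    peaks = data.frame(center = 1295, amplitude = 1, fwhm = 10,
                       shape = "lorentzian"),
    grid = c(1200, 1400, 1)))$spectrum
  expect_lt(abs(half_height_bandwidth(l10, 1295) - 10), 0.2)
  flat <- raman_spectrum(seq(1200, 1400, 1), rep(1, 201))
  expect_error(half_height_bandwidth(flat, 1295), "local maximum")
})

test_that("bandwidth is robust to sloped baselines and mild noise", {
  widths <- vapply(1:20, function(s) {
    d <- spectrum_design(
      peaks = data.frame(center = 1295, amplitude = 1, fwhm = 14),
      baseline_coeffs = c(0, 0.0005), noise_sd = 0.002,
      grid = c(1200, 1400, 1), seed = s)
    half_height_bandwidth(generate_spectrum(d)$spectrum, 1295)
  }, 1)
  expect_true(all(abs(widths - 14) / 14 < 0.05))
})
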