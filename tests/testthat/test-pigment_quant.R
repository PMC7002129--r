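single_gaussian_chrom <- function(area = 100, mu = 10, sigma = 0.5,
                                  times = seq(0, 20, by = 0.02),
                                  baseline = c(0, 0), noise = 0,
                                  wavelength = 665) {
  A <- area / (sigma * sqrt(2 * pi))
  y <- baseline[1] + baseline[2] * times +
    A * exp(-(times - mu)^2 / (2 * sigma^2))
  if (noise > 0) y <- y + rnorm(length(y), sd = noise)
  chromatogram(times, y, wavelength)
}

test_that("chromatogram construction validates its invariants", {
  expect_error(chromatogram(c(1, 1, 2), c(0, 0, 0), 665), "increasing")
  expect_error(chromatogram(c(1, 2, 4), c(0, 0, 0), 665), "uniformly")
  expect_error(chromatogram(1:5, rep(0, 5), 665, flow_rate_ml_min = 0),
               "flow rate")
  expect_warning(chromatogram(1:11, rep(0, 11), 665, dilution = 2),
                 "dilution")
})

test_that("peak detection finds clean Gaussians and rejects flat traces", {
  ch <- single_gaussian_chrom()
  pk <- detect_peaks(ch)
  expect_identical(nrow(pk), 1L)
  expect_lte(abs(pk$mu - 10), 0.02)
  flat <- chromatogram(seq(0, 20, 0.02),
                       rep(1, length(seq(0, 20, 0.02))), 665)
  expect_error(detect_peaks(flat), "no peaks")
  two <- single_gaussian_chrom()
  y2 <- two$absorbance_mOD +
    50 * exp(-(two$time_min - 15)^2 / (2 * 0.4^2))
  two2 <- chromatogram(two$time_min, y2, 665)
  expect_identical(nrow(detect_peaks(two2)), 2L)
})

test_that("Gaussian fitting recovers exact areas from noiseless traces", {
  ch <- single_gaussian_chrom(area = 100, baseline = c(2, 0.1))
  fit <- fit_gaussians(ch)
  expect_identical(nrow(fit$peaks), 1L)
  expect_lte(abs(fit$peaks$area - 100), 1e-6)
  expect_equal(fit$baseline[["intercept"]], 2, tolerance = 1e-6)
  # area/amplitude/sigma consistency
  expect_equal(fit$peaks$area,
               fit$peaks$amplitude * fit$peaks$sigma * sqrt(2 * pi),
               tolerance = 1e-9)
})

test_that("deconvolution separates peaks merged at 1.5 sigma", {
  t <- seq(0, 20, by = 0.02)
  s <- 0.8
  a1 <- 120 / (s * sqrt(2 * pi)); a2 <- 60 / (s * sqrt(2 * pi))
  y <- a1 * exp(-(t - 10)^2 / (2 * s^2)) +
       a2 * exp(-(t - 10 - 1.5 * s)^2 / (2 * s^2))
  ch <- chromatogram(t, y, 453)
  fit <- fit_gaussians(ch, guesses = data.frame(
    mu = c(10, 10 + 1.5 * s), amplitude = c(a1, a2), sigma = c(s, s)))
  expect_equal(fit$peaks$area, c(120, 60), tolerance = 1e-3)
})

test_that("flat traces forced to carry peaks fail rather than fit junk", {
  t <- seq(0, 20, by = 0.02)
  flat <- chromatogram(t, rep(3, length(t)), 270)
  expect_error(
    fit_gaussians(flat, guesses = data.frame(mu = c(5, 15),
                                             amplitude = c(1, 1),
                                             sigma = c(0.5, 0.5))),
    "fit")
})

test_that("Beer-Lambert conversion follows the internal-standard equation", {
  expect_equal(quantify(1000, 0.5, 70540, 0.98), 0.0072328,
               tolerance = 1e-4)
  expect_identical(quantify(0, 0.5, 70540, 0.98), 0)
  expect_equal(quantify(2000, 0.5, 70540, 0.98),
               2 * quantify(1000, 0.5, 70540, 0.98), tolerance = 1e-12)
  # inverse-linear in extinction coefficient and path length
  expect_equal(quantify(1000, 0.5, 2 * 70540, 0.98),
               quantify(1000, 0.5, 70540, 0.98) / 2, tolerance = 1e-12)
  expect_equal(quantify(1000, 0.5, 70540, 2 * 0.98),
               quantify(1000, 0.5, 70540, 0.98) / 2, tolerance = 1e-12)
  expect_error(quantify(100, -0.5, 70540), "positive")
  expect_error(quantify(-1, 0.5, 70540), ">= 0")
})

test_that("internal-standard normalization scales to phylloquinone = 2", {
  rep1 <- normalize_to_internal_standard(c(phylloquinone = 0.010,
                                           chl_f = 0.0355))
  expect_equal(rep1$copies[["chl_f"]], 7.10, tolerance = 1e-12)
  expect_equal(rep1$copies[["phylloquinone"]], 2)
  rep2 <- normalize_to_internal_standard(c(phylloquinone = 0.123,
                                           chl_a = 0.123))
  expect_equal(rep2$copies[["chl_a"]], 2)
  expect_error(normalize_to_internal_standard(c(chl_a = 1)), "standard")
  expect_error(normalize_to_internal_standard(c(phylloquinone = 0,
                                                chl_a = 1)), "standard")
})

test_that("renormalizing to an assumed chlorophyll total", {
  cp <- c(chl_a = 89.1, chl_f = 7.1, phylloquinone = 2)
  exp90 <- renormalize_total(cp, 90)
  expect_equal(exp90[["chl_f"]], 90 * 7.1 / 96.2, tolerance = 1e-12)
  expect_equal(exp90[["chl_f"]], 6.64, tolerance = 0.005)
  expect_equal(sum(exp90), 90, tolerance = 1e-9)
  # already summing to the total -> unchanged
  expect_equal(renormalize_total(c(chl_a = 83, chl_f = 7), 90),
               c(chl_a = 83, chl_f = 7), tolerance = 1e-12)
  expect_equal(renormalize_total(c(chl_a = 50), 90)[["chl_a"]], 90)
  expect_error(renormalize_total(c(chl_a = 0), 90), "positive")
})

test_that("stoichiometry is invariant to injection scale, flow and dilution", {
  base <- chromatogram_spec()
  variants <- list(
    chromatogram_spec(psi_amount_umol = 3e-4),
    chromatogram_spec(flow_rate_ml_min = 1.0),
    chromatogram_spec(dilution = 3))
  ref <- recover_stoichiometry(base)$copies
  for (v in variants) {
    cp <- recover_stoichiometry(v)$copies
    expect_equal(cp[names(ref)], ref, tolerance = 1e-6)
  }
})

test_that("chromatogram CSVs round-trip with their header metadata", {
  ch <- single_gaussian_chrom(baseline = c(1, 0.02))
  f <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram_csv(ch, f)
  ch2 <- read_chromatogram_csv(f)
  expect_identical(ch2$wavelength_nm, 665)
  expect_identical(ch2$flow_rate_ml_min, 0.5)
  expect_identical(ch2$path_length_cm, 0.98)
  expect_equal(ch2$absorbance_mOD, ch$absorbance_mOD, tolerance = 1e-4)
})

test_that("trapezoid integration matches Gaussian areas on clean peaks", {
  ch <- single_gaussian_chrom(area = 80)
  expect_equal(integrate_trapezoid(ch, 5, 15), 80, tolerance = 1e-3)
})
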